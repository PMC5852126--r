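test_that("gating kinetics evaluate their closed forms, including the removable singularities", {
  # analytic limits at the singular voltages
  expect_identical(gating_rates(-35)$alpha_m, 1)
  expect_identical(gating_rates(-34)$alpha_n, 0.1)
  # Boltzmann midpoint of H_inf and the cosh minimum of tau_H
  expect_identical(gating_rates(-80)$H_inf, 0.5)
  expect_identical(gating_rates(-70)$tau_H, 105)

  Vg <- seq(-120, 40, by = 0.05)
  g <- gating_rates(Vg)
  for (nm in c("alpha_m", "beta_m", "alpha_h", "beta_h", "alpha_n", "beta_n"))
    expect_true(all(g[[nm]] >= 0), info = nm)
  for (nm in c("m_inf", "h_inf", "n_inf", "H_inf"))
    expect_true(all(g[[nm]] >= 0 & g[[nm]] <= 1), info = nm)
  expect_true(all(g$tau_H >= 5))
  # continuity across the singular points
  expect_lt(abs(gating_rates(-35 + 1e-9)$alpha_m - 1), 1e-8)
  expect_lt(abs(gating_rates(-34 - 1e-9)$alpha_n - 0.1), 1e-8)

  expect_error(gating_rates(NaN), "finite")
})

test_that("ionic currents match an independent hand evaluation of the formulas", {
  p <- ih_params(Iapp = 0, gh = 0.02)
  s <- ih_state(V = -60, h = 0.5, n = 0.3, H = 0.2)
  cur <- ionic_currents(s, p)

  # oracle: the printed expressions written out directly
  am <- -0.1 * (-60 + 35) / (exp(-0.1 * (-60 + 35)) - 1)
  bm <- 4 * exp(-(-60 + 60) / 18)
  minf <- am / (am + bm)
  expect_equal(unname(cur[["I_Na"]]), 35 * minf^3 * 0.5 * (-60 - 55),
               tolerance = 1e-12)
  expect_equal(unname(cur[["I_K"]]), 9 * 0.3^4 * (-60 + 90), tolerance = 1e-12)
  expect_equal(unname(cur[["I_h"]]), 0.02 * 0.2 * (-60 + 30), tolerance = 1e-12)
  expect_equal(unname(cur[["I_L"]]), 0.1 * (-60 + 65), tolerance = 1e-12)

  # structural zeros
  p0 <- ih_params(gh = 0)
  expect_identical(ionic_currents(s, p0)[["I_h"]], 0)
  sK <- ih_state(V = -90, h = 0.5, n = 0.7, H = 0.1)
  expect_identical(ionic_currents(sK, p)[["I_K"]], 0)
})

test_that("the vector field vanishes at equilibria and keeps gates inside [0, 1]", {
  p <- ih_params(Iapp = 0.08, gh = 0.02)
  eq <- find_equilibria(p)[[1]]
  expect_lt(sqrt(sum(ih_rhs(eq$state, p)^2)), 1e-10)

  # at h = 1 the h-flux points inward for any V
  s <- ih_state(V = -30, h = 1, n = 0.3, H = 0.2)
  expect_lte(ih_rhs(s, p)[["h"]], 0)
})

test_that("analytic Jacobian agrees with central finite differences on random states", {
  set.seed(42)
  p <- ih_params(Iapp = 0.05, gh = 0.03)
  worst <- 0
  for (k in 1:100) {
    s <- ih_state(V = stats::runif(1, -90, 0), h = stats::runif(1),
                  n = stats::runif(1), H = stats::runif(1))
    J <- ih_jacobian(s, p)
    Jfd <- fd_jacobian(s, p)
    # floor the denominator at 1e-3: below that the central-difference
    # quotient itself carries ~1e-9 rounding noise, swamping the comparison
    rel <- abs(J - Jfd) / pmax(abs(Jfd), 1e-3)
    worst <- max(worst, max(rel))
  }
  expect_lt(worst, 1e-5)
})

test_that("Jacobian structure: the H row couples only to V and H, and gh enters linearly", {
  p <- ih_params(Iapp = -0.05, gh = 0.05)
  s <- ih_state(V = -55, h = 0.4, n = 0.2, H = 0.3)
  J <- ih_jacobian(s, p)
  expect_identical(unname(J["H", c("h", "n")]), c(0, 0))

  p0 <- ih_params(Iapp = -0.05, gh = 0)
  J0 <- ih_jacobian(s, p0)
  # with gh = 0 only the V-row entries carrying gh change
  expect_equal(J0[c("h", "n", "H"), ], J[c("h", "n", "H"), ],
               tolerance = 1e-14)
  expect_identical(unname(J0["V", "H"]), 0)
})

test_that("parameter and state constructors validate their invariants", {
  expect_error(ih_params(C = 0), "positive")
  expect_error(ih_params(gh = -0.1), "non-negative")
  expect_error(ih_state(V = -60, h = 1.5, n = 0.3, H = 0.2), "\\[0, 1\\]")
  d <- ih_params()
  expect_equal(unname(unclass(d)[c("C", "gNa", "ENa", "gK", "EK", "gL",
                                   "EL", "Eh", "phi")]),
               c(1, 35, 55, 9, -90, 0.1, -65, -30, 5))
})
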