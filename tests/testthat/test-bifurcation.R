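test_that("equilibrium finding returns classified roots that a finer scan confirms", {
  p <- ih_params(Iapp = 0.08, gh = 0.02)
  eqs <- find_equilibria(p)
  expect_length(eqs, 3)
  expect_identical(eqs[[1]]$etype, "stable_focus")
  expect_identical(eqs[[2]]$etype, "saddle")
  for (e in eqs)
    expect_lt(sqrt(sum(ih_rhs(e$state, p)^2)), 1e-9)

  # refined-scan oracle: 10x finer grid finds the same root set
  eqs_fine <- find_equilibria(p, V_step = 0.001)
  expect_length(eqs_fine, 3)
  expect_equal(vapply(eqs, function(e) e$state[["V"]], 0),
               vapply(eqs_fine, function(e) e$state[["V"]], 0),
               tolerance = 1e-9)

  # past the SNIC fold the resting branch is gone
  p2 <- ih_params(Iapp = 0.08, gh = 0.03)
  expect_false(any(vapply(find_equilibria(p2), function(e) e$stable, TRUE)))
  # and below the node-focus transition the resting state is a node
  p3 <- ih_params(Iapp = 0.08, gh = 0.01)
  expect_identical(find_equilibria(p3)[[1]]$etype, "stable_node")
})

test_that("eigenvalue classification is stable under a finite-difference Jacobian", {
  set.seed(7)
  for (k in 1:30) {
    p <- ih_params(Iapp = stats::runif(1, -0.3, 0), gh = stats::runif(1, 0, 0.04))
    eq <- find_equilibria(p)[[1]]
    ev_fd <- eigen(fd_jacobian(eq$state, p), only.values = TRUE)$values
    expect_identical(ihdyn:::classify_eigenvalues(ev_fd), eq$etype)
  }
})

test_that("one-parameter sweeps detect the printed fold, Hopf, and node-focus events", {
  sw <- sweep_1d(p_fire_snic, gh_range = c(0, 0.03), n_grid = 61)
  fold <- sw$points$gh[sw$points$kind == "fold"]
  nf <- sw$points$gh[sw$points$kind == "nf"]
  expect_true(agrees_sf(fold, 0.0229919, 4))
  expect_equal(nf, 0.0169329, tolerance = 1e-3)
  expect_false("hopf" %in% sw$points$kind)

  sw2 <- sweep_1d(p_fire_hopf, gh_range = c(0.04, 0.07), n_grid = 61)
  expect_true(agrees_sf(sw2$points$gh[sw2$points$kind == "hopf"],
                        0.0620557, 4))
  expect_true(agrees_sf(sw2$points$gh[sw2$points$kind == "fold"],
                        0.0623686, 4))
  expect_equal(sw2$points$gh[sw2$points$kind == "nf"], 0.0454454,
               tolerance = 1e-3)

  # defining-condition residuals at the detected points (at the fold the two
  # merging roots are tangent, so evaluate at the fold's own V coordinate)
  pf <- p_fire_snic
  pf[["gh"]] <- fold
  folds <- find_folds(p_fire_snic)
  evf <- ihdyn:::equilibrium_at(folds$V[1], pf)$eigenvalues
  expect_lt(min(abs(evf)), 1e-7)          # zero eigenvalue at the fold
  ph <- p_fire_hopf
  ph[["gh"]] <- sw2$points$gh[sw2$points$kind == "hopf"]
  evh <- find_equilibria(ph)[[1]]$eigenvalues
  expect_lt(abs(max(Re(evh))), 1e-7)      # pure-imaginary pair at the Hopf
})

test_that("fold character and Hopf criticality match the study scenarios", {
  f1 <- find_folds(p_fire_snic)
  expect_identical(classify_fold_global(p_fire_snic, f1$gh[1], window = 4000),
                   "SNIC")
  f2 <- find_folds(p_fire_hopf)
  expect_identical(classify_fold_global(p_fire_hopf, f2$gh[1], window = 4000),
                   "SN")
  expect_identical(classify_hopf(p_fire_hopf, 0.0620557), "sub")

  # bistability just below the subcritical Hopf: rest and firing coexist
  pb <- p_fire_hopf
  pb[["gh"]] <- 0.0615
  rest <- settle_to_equilibrium(pb)
  from_rest <- run_spike_train(pb, x0 = rest, t_end = 1500, dt = 0.002)
  expect_length(from_rest$spikes, 0)
  pf_up <- p_fire_hopf
  pf_up[["gh"]] <- 0.065
  st <- ihdyn:::firing_state(pf_up, dt = 0.002)
  from_cycle <- run_spike_train(pb, x0 = st, t_end = 3000, dt = 0.002)
  expect_gt(length(from_cycle$spikes), 5)
})

test_that("the cycle-disappearance boundary reproduces the big-homoclinic value", {
  b <- locate_cycle_boundary(p_fire_hopf, c(0.055, 0.07))
  expect_equal(b, 0.0610595, tolerance = 2e-3)
  # the SNIC case: onset coincides with the fold
  f1 <- find_folds(p_fire_snic)$gh[1]
  b_snic <- locate_cycle_boundary(p_fire_snic, c(f1 - 5e-3, f1 + 1e-3),
                                  window = 4000)
  expect_lt(abs(b_snic - f1), 1e-4)
})

test_that("two-parameter curves agree with one-parameter detections and slope downward", {
  sn <- trace_curve_2d(ih_params(), "SN", iapp_range = c(0.08, 0.06),
                       gh_seed = 0.023, step = 0.01)
  expect_true(all(diff(sn$gh) * diff(sn$Iapp) < 0))   # negative slope
  # cross-validation: the 1-parameter fold at Iapp = 0.07 lies on the curve
  f07 <- find_folds(ih_params(Iapp = 0.07))$gh[1]
  expect_lt(abs(sn$gh[sn$Iapp == 0.07] - f07), 1e-5)

  ho <- trace_curve_2d(ih_params(), "Hopf", iapp_range = c(-0.05, -0.09),
                       gh_seed = 0.062, step = 0.02)
  expect_true(all(diff(ho$gh) * diff(ho$Iapp) < 0))
  nf <- trace_curve_2d(ih_params(), "NF", iapp_range = c(-0.05, 0.01),
                       gh_seed = 0.0454, step = 0.03)
  expect_true(all(diff(nf$gh) * diff(nf$Iapp) < 0))
})

test_that("the Bogdanov-Takens point carries a double zero eigenvalue where fold and Hopf meet", {
  bt <- locate_codim2(ih_params(), "BT")
  expect_true(agrees_sf(bt$gh, 0.03413, 4))
  pbt <- ih_params(Iapp = bt$Iapp, gh = bt$gh)
  ev <- ihdyn:::equilibrium_at(bt$V, pbt)$eigenvalues
  expect_lt(sort(abs(ev))[2], 1e-6)       # two eigenvalues at zero

  # the Hopf curve terminates onto the fold curve at BT: just left of BT a
  # Hopf exists, just right it does not
  expect_false(is.null(ihdyn:::codim1_gh_at(ih_params(), bt$Iapp - 0.01,
                                            "Hopf", bt$gh, 0.01)))
  expect_null(ihdyn:::codim1_gh_at(ih_params(), bt$Iapp + 0.015,
                                   "Hopf", bt$gh, 0.01))
})

test_that("the stable-behavior partition is ordered node, focus, coexistence, firing", {
  part <- stable_behavior_partition(
    ih_params(), iapp_grid = -0.05,
    gh_grid = c(0.01, 0.05, 0.0615, 0.065), window = 1500, dt = 0.002)
  expect_identical(as.vector(part$labels),
                   c("stable_node", "stable_focus", "coexistence", "firing"))

  part2 <- stable_behavior_partition(
    ih_params(), iapp_grid = 0.08, gh_grid = c(0.01, 0.02),
    window = 1000, dt = 0.002)
  expect_identical(as.vector(part2$labels), c("stable_node", "stable_focus"))
})

test_that("simulation agrees with the analysis across the firing border", {
  # SNIC side
  f <- find_folds(p_fire_snic)$gh[1]
  p_out <- p_fire_snic
  p_out[["gh"]] <- f + 2e-3
  run_out <- run_spike_train(p_out, x0 = c(V = -60, h = 0.7, n = 0.1, H = 0.2),
                             t_end = 3000, dt = 0.002)
  expect_gt(length(run_out$spikes), 2)
  p_in <- p_fire_snic
  p_in[["gh"]] <- f - 2e-3
  run_in <- run_spike_train(p_in, x0 = settle_to_equilibrium(p_in),
                            t_end = 3000, dt = 0.002)
  expect_length(run_in$spikes, 0)

  # Hopf side
  p_out2 <- p_fire_hopf
  p_out2[["gh"]] <- 0.064
  run_out2 <- run_spike_train(p_out2, x0 = c(V = -60, h = 0.7, n = 0.1, H = 0.2),
                              t_end = 3000, dt = 0.002)
  expect_gt(length(run_out2$spikes), 2)
  p_in2 <- p_fire_hopf
  p_in2[["gh"]] <- 0.060
  run_in2 <- run_spike_train(p_in2, x0 = settle_to_equilibrium(p_in2),
                             t_end = 3000, dt = 0.002)
  expect_length(run_in2$spikes, 0)
})
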