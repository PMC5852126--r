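test_that("integration from an equilibrium stays at the equilibrium", {
  x0 <- settle_to_equilibrium(p_rest_focus)
  tr <- integrate_model(p_rest_focus, x0 = x0, t_end = 500, dt = 0.005,
                        thin = 100L)
  expect_lt(max(abs(tr$V - x0[["V"]])), 1e-6)
  expect_lt(max(abs(tr$H - x0[["H"]])), 1e-9)
})

test_that("deterministic firing at Iapp = 0.17 is period-1", {
  p <- ih_params(Iapp = 0.17, gh = 0.02)
  x0 <- c(V = -64, h = 0.78, n = 0.09, H = 0.2)
  run <- run_spike_train(p, x0 = x0, t_end = 3000, dt = 0.001,
                         t_discard = 2000)
  isis <- diff(run$spikes)
  expect_gte(length(isis), 5)
  expect_lt(max(isis) - min(isis), 2 * 0.001)
  # CV of a period-1 train is 0 (to integration accuracy)
  expect_lt(stats::sd(isis) / mean(isis), 1e-4)
})

test_that("the Euler scheme converges at first order on subthreshold runs", {
  proto <- stim_protocol("square_pulse", amplitude = -0.2, onset = 20,
                         duration = 50)
  x0 <- settle_to_equilibrium(p_rest_focus)
  v_end <- function(dt) {
    tr <- integrate_model(p_rest_focus, proto, x0 = x0, t_end = 100, dt = dt,
                          thin = as.integer(100 / dt))
    tr$V[length(tr$V)]
  }
  expect_lt(abs(v_end(0.002) - v_end(0.001)), 1e-3)
})

test_that("gating variables stay in [0, 1] and noisy runs are seed-reproducible", {
  p <- ih_params(Iapp = 0.17, gh = 0.02)
  x0 <- c(V = -64, h = 0.78, n = 0.09, H = 0.2)
  tr1 <- integrate_model(p, x0 = x0, t_end = 300, dt = 0.005,
                         noise = noise_spec(0.5, seed = 3), thin = 10L)
  expect_true(all(tr1$h >= 0 & tr1$h <= 1))
  expect_true(all(tr1$n >= 0 & tr1$n <= 1))
  expect_true(all(tr1$H >= 0 & tr1$H <= 1))
  tr2 <- integrate_model(p, x0 = x0, t_end = 300, dt = 0.005,
                         noise = noise_spec(0.5, seed = 3), thin = 10L)
  expect_identical(tr1$V, tr2$V)    # bit-identical rerun
})

test_that("spike detection interpolates crossings and respects the refractory gap", {
  # constant subthreshold trace: no spikes
  x0 <- settle_to_equilibrium(p_rest_node)
  tr0 <- integrate_model(p_rest_node, x0 = x0, t_end = 200, dt = 0.01,
                         thin = 10L)
  expect_length(detect_spikes(tr0)$spike_times, 0)

  # a single constructed action-potential waveform crossing 0 mV once
  tt <- seq(0, 50, by = 0.1)
  fake <- list(t = tt, V = -65 + 95 * exp(-((tt - 25) / 2)^2))
  st <- detect_spikes(fake)
  expect_length(st$spike_times, 1)
  expect_lt(abs(st$spike_times - (25 - 2 * sqrt(log(95 / 65)))), 0.1)

  # threshold insensitivity across [-20, 10] mV on a real firing run
  p <- ih_params(Iapp = 0.17, gh = 0.02)
  trf <- integrate_model(p, x0 = c(V = -64, h = 0.78, n = 0.09, H = 0.2),
                         t_end = 800, dt = 0.001, thin = 10L)
  counts <- vapply(c(-20, -10, 0, 10),
                   function(th) length(detect_spikes(trf, th)$spike_times), 0L)
  expect_true(all(counts == counts[1]))
})

test_that("settling finds the stable equilibrium and fails in the firing-only region", {
  x0 <- settle_to_equilibrium(p_rest_focus)
  expect_lt(sqrt(sum(ih_rhs(x0, p_rest_focus)^2)), 1e-9)
  eq <- Filter(function(e) e$stable, find_equilibria(p_rest_focus))[[1]]
  expect_lt(abs(x0[["V"]] - eq$state[["V"]]), 1e-8)
  expect_equal(eq$etype, "stable_focus")   # resonant reference point

  expect_error(settle_to_equilibrium(ih_params(Iapp = 0.3, gh = 0.05)),
               "firing")
})

test_that("damped-oscillation frequency matches the eigenvalue oracle for a focus and is NA for a node", {
  # constructed damped cosine of known frequency
  tt <- seq(0, 2000, by = 0.1)
  fake <- list(t = tt, V = -60 + 3 * exp(-tt / 300) * cos(2 * pi * 2.5 * tt / 1000))
  expect_equal(damped_frequency(fake), 2.5, tolerance = 0.02)

  eq <- Filter(function(e) e$stable, find_equilibria(p_rest_focus))[[1]]
  x0 <- eq$state
  x0[["V"]] <- x0[["V"]] + 1
  tr <- integrate_model(p_rest_focus, x0 = x0, t_end = 4000, dt = 0.01,
                        thin = 5L)
  f_eig <- abs(Im(eq$eigenvalues[1])) / (2 * pi) * 1000
  expect_equal(damped_frequency(tr), f_eig, tolerance = 0.05)

  x1 <- settle_to_equilibrium(p_rest_node)
  x1[["V"]] <- x1[["V"]] + 1
  trn <- integrate_model(p_rest_node, x0 = x1, t_end = 4000, dt = 0.01,
                         thin = 5L)
  expect_true(is.na(damped_frequency(trn)))
})

test_that("trajectories round-trip through the CSV writer", {
  x0 <- settle_to_equilibrium(p_rest_node)
  tr <- integrate_model(p_rest_node, x0 = x0, t_end = 10, dt = 0.01,
                        thin = 100L)
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  d <- utils::read.csv(path)
  expect_identical(names(d), c("t_ms", "V_mV", "h", "n", "H", "I_uA_cm2"))
  expect_equal(d$V_mV, tr$V)
})
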