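# Shared fixtures for the test suite. All data are generated in code.

# reference parameter points used across files
p_rest_focus <- ih_params(Iapp = -0.05, gh = 0.05)   # stable focus, resonant
p_rest_node <- ih_params(Iapp = -0.05, gh = 0.01)    # stable node
p_fire_snic <- ih_params(Iapp = 0.08)                # SNIC scenario in gh
p_fire_hopf <- ih_params(Iapp = -0.05)               # subcritical-Hopf scenario

# a deterministic ZAP run and its impedance profile, reused by several tests
zap_run <- function(p, t_end = 20000, dt = 0.001, thin = 1000L,
                    zap = zap_spec()) {
  x0 <- settle_to_equilibrium(p)
  integrate_model(p, stim_protocol("zap", zap = zap), x0 = x0,
                  t_end = t_end, dt = dt, thin = thin)
}

# finite-difference Jacobian (independent oracle for the analytic one)
fd_jacobian <- function(state, p, h = 1e-6) {
  J <- matrix(0, 4, 4)
  for (j in 1:4) {
    sp <- state; sm <- state
    sp[j] <- sp[j] + h
    sm[j] <- sm[j] - h
    J[, j] <- (ih_rhs(sp, p) - ih_rhs(sm, p)) / (2 * h)
  }
  J
}

# relative agreement to n significant figures (half a unit in the n-th digit)
agrees_sf <- function(x, ref, n) abs(x - ref) / abs(ref) < 0.5 * 10^(1 - n)
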