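#' Model parameters for the interneuron model with I_h
#'
#' Constructs the parameter set of a four-variable conductance-based
#' hippocampal GABAergic interneuron model (fast Na+, delayed-rectifier K+,
#' leak, and the hyperpolarization-activated cation current I_h). Defaults
#' are the reference set used throughout: \code{C = 1} uF/cm2,
#' \code{gNa = 35}, \code{gK = 9}, \code{gL = 0.1} mS/cm2, \code{ENa = 55},
#' \code{EK = -90}, \code{EL = -65}, \code{Eh = -30} mV, \code{phi = 5}.
#' The two control parameters of the study, \code{Iapp} (applied current,
#' uA/cm2) and \code{gh} (maximal I_h conductance, mS/cm2), default to 0.
#'
#' Note the membrane capacitance is in uF/cm2 (the only unit that makes the
#' voltage equation dimensionally consistent on the mV/ms scale), and the
#' leak current is \code{gL * (V - EL)}.
#'
#' @param Iapp applied current (uA/cm2)
#' @param gh maximal conductance of I_h (mS/cm2)
#' @param C membrane capacitance (uF/cm2)
#' @param gNa,gK,gL maximal conductances (mS/cm2)
#' @param ENa,EK,EL,Eh reversal potentials (mV)
#' @param phi dimensionless temperature-like rate factor on h and n kinetics
#' @return a named numeric vector of class \code{"ih_params"}
#' @export
#' @examples
#' p <- ih_params(Iapp = -0.05, gh = 0.05)
ih_params <- function(Iapp = 0, gh = 0, C = 1, gNa = 35, ENa = 55,
                      gK = 9, EK = -90, gL = 0.1, EL = -65, Eh = -30,
                      phi = 5) {
  p <- c(C = C, gNa = gNa, ENa = ENa, gK = gK, EK = EK, gL = gL, EL = EL,
         gh = gh, Eh = Eh, phi = phi, Iapp = Iapp)
  if (any(!is.finite(p)))
    stop("all model parameters must be finite")
  if (p[["C"]] <= 0) stop("capacitance C must be positive")
  if (any(p[c("gNa", "gK", "gL", "gh")] < 0))
    stop("conductances must be non-negative")
  class(p) <- "ih_params"
  p
}

#' @export
print.ih_params <- function(x, ...) {
  cat("Interneuron model parameters (I_h model):\n")
  print(unclass(x))
  invisible(x)
}

#' State vector of the model
#'
#' @param V membrane potential (mV)
#' @param h Na+ inactivation gate in [0, 1]
#' @param n K+ activation gate in [0, 1]
#' @param H I_h activation gate in [0, 1]
#' @return named numeric vector (V, h, n, H)
#' @export
ih_state <- function(V, h, n, H) {
  s <- c(V = V, h = h, n = n, H = H)
  if (any(!is.finite(s))) stop("state components must be finite")
  if (any(s[c("h", "n", "H")] < -1e-12) || any(s[c("h", "n", "H")] > 1 + 1e-12))
    stop("gating variables h, n, H must lie in [0, 1]")
  s
}

# y / (1 - exp(-y)) with the removable singularity at y = 0 filled by its
# series, so alpha_m and alpha_n are C^1 at V = -35 and V = -34 mV.
sratio <- function(y) {
  out <- ifelse(abs(y) < 1e-7,
                1 + y / 2 + y^2 / 12,
                y / (-expm1(-y)))
  out
}

# d/dy of sratio
sratio_d <- function(y) {
  small <- abs(y) < 1e-5
  e <- -expm1(-y)                       # 1 - exp(-y)
  out <- ifelse(small,
                0.5 + y / 6,
                (e - y * exp(-y)) / (e * e))
  out
}

#' Gating rates, steady states, and the I_h time constant
#'
#' Evaluates the voltage-dependent kinetics of the model: the alpha/beta
#' rates of the Na+ activation (m) and inactivation (h) and K+ activation
#' (n) gates, their steady-state values, and the steady state and time
#' constant of the I_h gate H. Rates are in 1/ms, \code{tau_H} in ms.
#' The removable singularities of \code{alpha_m} (V = -35 mV) and
#' \code{alpha_n} (V = -34 mV) are replaced by their analytic limits.
#' \code{H_inf(V) = 1 / (1 + exp((V + 80) / 10))} (Boltzmann with
#' half-activation -80 mV, 10 mV slope, activated by hyperpolarization) and
#' \code{tau_H(V) = 200 / (exp((V+70)/20) + exp(-(V+70)/20)) + 5}, so
#' \code{tau_H >= 5} ms everywhere with maximum 105 ms at -70 mV.
#'
#' @param V membrane potential (mV), vectorized
#' @return a list with components \code{alpha_m, beta_m, alpha_h, beta_h,
#'   alpha_n, beta_n, m_inf, h_inf, n_inf, H_inf, tau_H}
#' @export
#' @examples
#' gating_rates(-35)$alpha_m  # exactly 1 (analytic limit)
gating_rates <- function(V) {
  if (any(!is.finite(V))) stop("V must be finite")
  alpha_m <- sratio(0.1 * (V + 35))
  beta_m <- 4 * exp(-(V + 60) / 18)
  alpha_h <- 0.07 * exp(-(V + 58) / 20)
  beta_h <- 1 / (exp(-0.1 * (V + 28)) + 1)
  alpha_n <- 0.1 * sratio(0.1 * (V + 34))
  beta_n <- 0.125 * exp(-(V + 44) / 80)
  w <- (V + 70) / 20
  list(alpha_m = alpha_m, beta_m = beta_m,
       alpha_h = alpha_h, beta_h = beta_h,
       alpha_n = alpha_n, beta_n = beta_n,
       m_inf = alpha_m / (alpha_m + beta_m),
       h_inf = alpha_h / (alpha_h + beta_h),
       n_inf = alpha_n / (alpha_n + beta_n),
       H_inf = 1 / (1 + exp((V + 80) / 10)),
       tau_H = 200 / (exp(w) + exp(-w)) + 5)
}

# Voltage derivatives of the gating quantities (internal; used by the
# analytic Jacobian and by the scalar-reduced bifurcation conditions).
gating_rates_d <- function(V) {
  g <- gating_rates(V)
  d_alpha_m <- 0.1 * sratio_d(0.1 * (V + 35))
  d_beta_m <- -g$beta_m / 18
  d_alpha_h <- -g$alpha_h / 20
  d_beta_h <- 0.1 * g$beta_h * (1 - g$beta_h)
  d_alpha_n <- 0.01 * sratio_d(0.1 * (V + 34))
  d_beta_n <- -g$beta_n / 80
  sm <- g$alpha_m + g$beta_m
  sh <- g$alpha_h + g$beta_h
  sn <- g$alpha_n + g$beta_n
  w <- (V + 70) / 20
  list(g = g,
       d_alpha_m = d_alpha_m, d_beta_m = d_beta_m,
       d_alpha_h = d_alpha_h, d_beta_h = d_beta_h,
       d_alpha_n = d_alpha_n, d_beta_n = d_beta_n,
       d_m_inf = (d_alpha_m * g$beta_m - g$alpha_m * d_beta_m) / sm^2,
       d_h_inf = (d_alpha_h * g$beta_h - g$alpha_h * d_beta_h) / sh^2,
       d_n_inf = (d_alpha_n * g$beta_n - g$alpha_n * d_beta_n) / sn^2,
       d_H_inf = -0.1 * g$H_inf * (1 - g$H_inf),
       # tau_H = 100 / cosh(w) + 5, w = (V + 70) / 20
       d_tau_H = -5 * sinh(w) / cosh(w)^2)
}

#' Ionic currents at a state
#'
#' Returns the four membrane currents with the sign convention of the
#' voltage equation (these are the currents subtracted from the applied
#' current): \code{I_Na = gNa m_inf(V)^3 h (V - ENa)},
#' \code{I_K = gK n^4 (V - EK)}, \code{I_h = gh H (V - Eh)},
#' \code{I_L = gL (V - EL)}, all in uA/cm2.
#'
#' @param state named state vector from [ih_state()]
#' @param p parameters from [ih_params()]
#' @return named numeric vector (I_Na, I_K, I_h, I_L)
#' @export
ionic_currents <- function(state, p) {
  V <- state[["V"]]
  g <- gating_rates(V)
  c(I_Na = p[["gNa"]] * g$m_inf^3 * state[["h"]] * (V - p[["ENa"]]),
    I_K = p[["gK"]] * state[["n"]]^4 * (V - p[["EK"]]),
    I_h = p[["gh"]] * state[["H"]] * (V - p[["Eh"]]),
    I_L = p[["gL"]] * (V - p[["EL"]]))
}

#' Right-hand side of the model equations
#'
#' Time derivatives of (V, h, n, H): the voltage equation balances the four
#' ionic currents against the applied and external currents, the h and n
#' gates follow first-order alpha/beta kinetics accelerated by \code{phi},
#' and H relaxes to \code{H_inf(V)} with time constant \code{tau_H(V)}.
#'
#' @param state named state vector
#' @param p parameters
#' @param I_ext additional external (stimulus) current, uA/cm2
#' @return named numeric derivative vector (units per ms)
#' @export
ih_rhs <- function(state, p, I_ext = 0) {
  cur <- ionic_currents(state, p)
  g <- gating_rates(state[["V"]])
  c(V = (-sum(cur) + p[["Iapp"]] + I_ext) / p[["C"]],
    h = p[["phi"]] * (g$alpha_h * (1 - state[["h"]]) - g$beta_h * state[["h"]]),
    n = p[["phi"]] * (g$alpha_n * (1 - state[["n"]]) - g$beta_n * state[["n"]]),
    H = (g$H_inf - state[["H"]]) / g$tau_H)
}

#' Analytic Jacobian of the model
#'
#' The 4x4 matrix of partial derivatives of [ih_rhs()] with respect to
#' (V, h, n, H), evaluated analytically (1/ms). The H row has nonzero
#' entries only in the V and H columns.
#'
#' @inheritParams ih_rhs
#' @return a 4x4 numeric matrix with dimnames (V, h, n, H)
#' @export
ih_jacobian <- function(state, p) {
  V <- state[["V"]]; h <- state[["h"]]; n <- state[["n"]]; H <- state[["H"]]
  gd <- gating_rates_d(V)
  g <- gd$g
  J <- matrix(0, 4, 4, dimnames = list(c("V", "h", "n", "H"),
                                       c("V", "h", "n", "H")))
  m3 <- g$m_inf^3
  J["V", "V"] <- (-p[["gNa"]] * h *
                    (3 * g$m_inf^2 * gd$d_m_inf * (V - p[["ENa"]]) + m3) -
                    p[["gK"]] * n^4 - p[["gh"]] * H - p[["gL"]]) / p[["C"]]
  J["V", "h"] <- -p[["gNa"]] * m3 * (V - p[["ENa"]]) / p[["C"]]
  J["V", "n"] <- -4 * p[["gK"]] * n^3 * (V - p[["EK"]]) / p[["C"]]
  J["V", "H"] <- -p[["gh"]] * (V - p[["Eh"]]) / p[["C"]]
  J["h", "V"] <- p[["phi"]] * (gd$d_alpha_h * (1 - h) - gd$d_beta_h * h)
  J["h", "h"] <- -p[["phi"]] * (g$alpha_h + g$beta_h)
  J["n", "V"] <- p[["phi"]] * (gd$d_alpha_n * (1 - n) - gd$d_beta_n * n)
  J["n", "n"] <- -p[["phi"]] * (g$alpha_n + g$beta_n)
  J["H", "V"] <- gd$d_H_inf / g$tau_H -
    (g$H_inf - H) * gd$d_tau_H / g$tau_H^2
  J["H", "H"] <- -1 / g$tau_H
  J
}
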