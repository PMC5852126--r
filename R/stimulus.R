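#' ZAP chirp specification
#'
#' A sinusoidal current of constant amplitude whose nominal frequency sweeps
#' linearly from \code{fmin} to \code{fmax} over \code{T} seconds:
#' \code{I(t) = Istim * sin(2 * pi * f(t) * t)} with
#' \code{f(t) = fmin + (fmax - fmin) * t / T}. The literal phase
#' \code{2 pi f(t) t} is used (the instantaneous frequency of such a chirp is
#' \code{f(t) + t f'(t)}; since the impedance is computed as an FFT ratio the
#' frequency axis of the analysis is unaffected by the convention).
#'
#' @param Istim amplitude (uA/cm2)
#' @param fmin,fmax swept frequency bounds (Hz)
#' @param T sweep duration (s)
#' @return list of class \code{"zap_spec"}
#' @export
zap_spec <- function(Istim = 0.01, fmin = 0, fmax = 20, T = 20) {
  if (Istim < 0) stop("Istim must be >= 0")
  if (!(fmin >= 0 && fmin < fmax)) stop("need 0 <= fmin < fmax")
  if (T <= 0) stop("T must be positive")
  structure(list(Istim = Istim, fmin = fmin, fmax = fmax, T = T),
            class = "zap_spec")
}

#' ZAP current waveform
#'
#' @param t time (ms), vectorized; 0 is returned outside [0, 1000 * T]
#' @param z a [zap_spec()]
#' @return current (uA/cm2)
#' @export
zap_current <- function(t, z = zap_spec()) {
  ts <- t / 1000
  f <- z$fmin + (z$fmax - z$fmin) * ts / z$T
  out <- z$Istim * sin(2 * pi * f * ts)
  out[ts < 0 | ts > z$T] <- 0
  out
}

#' Linear current ramp
#'
#' Zero before \code{onset}, then rising at \code{rate} uA/cm2 per ms,
#' uncapped (in the first-spike protocols a spike occurs long before the
#' ramp could saturate). The reference "fast" ramp is 1 uA per 100 ms
#' (\code{rate = 0.01}) and the "slow" ramp 0.3 uA per 100 ms
#' (\code{rate = 0.003}).
#'
#' @param t time (ms), vectorized
#' @param rate slope (uA/cm2 per ms), positive
#' @param onset ramp start (ms)
#' @return current (uA/cm2)
#' @export
ramp_current <- function(t, rate, onset = 0) {
  if (rate <= 0) stop("ramp rate must be positive")
  ifelse(t >= onset, rate * (t - onset), 0)
}

#' Square current pulse
#'
#' \code{amplitude} on the half-open window [onset, onset + duration),
#' 0 elsewhere. Hyperpolarizing pulses have negative amplitude.
#'
#' @param t time (ms), vectorized
#' @param amplitude pulse amplitude (uA/cm2)
#' @param onset pulse start (ms)
#' @param duration pulse length (ms), positive
#' @return current (uA/cm2)
#' @export
square_pulse <- function(t, amplitude, onset, duration) {
  if (duration <= 0) stop("duration must be positive")
  ifelse(t >= onset & t < onset + duration, amplitude, 0)
}

#' White-noise current specification
#'
#' Additive Gaussian white-noise current of intensity \code{D} entering the
#' voltage equation; discretized by Euler-Maruyama so each step adds
#' \code{(D / C) * sqrt(dt) * xi}, \code{xi ~ N(0, 1)}, to V. With C = 1
#' this makes \code{D} numerically the intensity as quoted with the
#' reference protocols.
#'
#' @param D noise intensity (uA * ms^(1/2) / cm2), >= 0
#' @param seed integer RNG seed or NULL
#' @return list of class \code{"noise_spec"}
#' @export
noise_spec <- function(D = 0, seed = NULL) {
  if (D < 0) stop("noise intensity D must be >= 0")
  structure(list(D = D, seed = seed), class = "noise_spec")
}

#' Euler-Maruyama noise increments for the voltage equation
#'
#' Draws the per-step stochastic increments added to V: \code{(D / C) *
#' sqrt(dt) * xi}. Exposed mainly so the discretization convention is a
#' single replaceable function; the compiled integrator applies the same
#' rule inline.
#'
#' @param ns a [noise_spec()]
#' @param dt step (ms), positive
#' @param n number of increments
#' @param C membrane capacitance (uF/cm2)
#' @return numeric vector of n increments (mV)
#' @export
noise_increment <- function(ns, dt, n = 1, C = 1) {
  if (dt <= 0) stop("dt must be positive")
  if (ns$D == 0) return(numeric(n))
  if (!is.null(ns$seed)) set.seed(ns$seed)
  (ns$D / C) * sqrt(dt) * stats::rnorm(n)
}

#' Stimulation protocol
#'
#' A deterministic stimulus waveform used by the integrator. Kinds:
#' \describe{
#'   \item{constant}{\code{amplitude} for all t (use 0 for no stimulus)}
#'   \item{square_pulse}{\code{amplitude} on [onset, onset + duration)}
#'   \item{ramp}{\code{rate * (t - onset)} after onset}
#'   \item{zap}{chirp from a [zap_spec()]}
#'   \item{sine}{\code{amplitude * sin(2 pi f1 (t - onset) / 1000)}}
#' }
#'
#' @param kind one of "constant", "square_pulse", "ramp", "zap", "sine"
#' @param amplitude amplitude (uA/cm2) for constant/square_pulse/sine
#' @param onset onset (ms)
#' @param duration duration (ms) for square_pulse
#' @param rate ramp slope (uA/cm2 per ms)
#' @param f1 sine frequency (Hz)
#' @param zap a [zap_spec()] for kind "zap"
#' @return list of class \code{"stim_protocol"}
#' @export
stim_protocol <- function(kind = c("constant", "square_pulse", "ramp",
                                   "zap", "sine"),
                          amplitude = 0, onset = 0, duration = NULL,
                          rate = NULL, f1 = NULL, zap = NULL) {
  kind <- match.arg(kind)
  proto <- switch(kind,
    constant = list(code = 0L, par = c(amplitude)),
    square_pulse = {
      if (is.null(duration) || duration <= 0)
        stop("square_pulse needs a positive duration")
      list(code = 1L, par = c(amplitude, onset, duration))
    },
    ramp = {
      if (is.null(rate) || rate <= 0) stop("ramp needs a positive rate")
      list(code = 2L, par = c(rate, onset))
    },
    zap = {
      if (is.null(zap)) zap <- zap_spec()
      list(code = 3L, par = c(zap$Istim, zap$fmin, zap$fmax, zap$T))
    },
    sine = {
      if (is.null(f1) || f1 <= 0) stop("sine needs a positive frequency f1")
      list(code = 4L, par = c(amplitude, f1, onset))
    })
  structure(c(proto, list(kind = kind)), class = "stim_protocol")
}

#' Evaluate a protocol waveform
#'
#' @param proto a [stim_protocol()]
#' @param t times (ms)
#' @return current (uA/cm2) at each t
#' @export
protocol_current <- function(proto, t) {
  stopifnot(inherits(proto, "stim_protocol"))
  sp <- proto$par
  switch(proto$kind,
    constant = rep(sp[1], length(t)),
    square_pulse = square_pulse(t, sp[1], sp[2], sp[3]),
    ramp = ramp_current(t, sp[1], sp[2]),
    zap = zap_current(t, zap_spec(sp[1], sp[2], sp[3], sp[4])),
    sine = ifelse(t >= sp[3],
                  sp[1] * sin(2 * pi * sp[2] * (t - sp[3]) / 1000), 0))
}

#' Write a protocol waveform to CSV
#'
#' Two columns, \code{t_ms} and \code{I_uA_cm2}, on a uniform grid.
#'
#' @param proto a [stim_protocol()]
#' @param path output CSV path
#' @param t_end end time (ms)
#' @param dt grid step (ms)
#' @return the path, invisibly
#' @export
write_protocol_csv <- function(proto, path, t_end, dt = 1) {
  t <- seq(0, t_end, by = dt)
  utils::write.csv(data.frame(t_ms = t, I_uA_cm2 = protocol_current(proto, t)),
                   path, row.names = FALSE)
  invisible(path)
}
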