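#' Interspike-interval statistics
#'
#' Mean, sample standard deviation (n - 1 denominator), and coefficient of
#' variation CV = STD/mean of the first \code{n_target} ISIs of a spike
#' train. The reference protocols use N = 2000 ISIs.
#'
#' @param st a \code{spike_train} from [detect_spikes()], or a numeric
#'   vector of spike times (ms)
#' @param n_target number of ISIs to use; NULL uses all
#' @return list of class \code{"isi_stats"}: \code{n}, \code{mean},
#'   \code{std}, \code{cv} (ms, ms, dimensionless)
#' @export
#' @examples
#' isi_stats(c(0, 10, 30))  # ISIs 10, 20 ms
isi_stats <- function(st, n_target = NULL) {
  times <- if (inherits(st, "spike_train")) st$spike_times else st
  isis <- diff(times)
  if (!is.null(n_target)) {
    if (length(isis) < n_target)
      stop(sprintf("insufficient data: %d ISIs available, %d requested",
                   length(isis), n_target))
    isis <- isis[seq_len(n_target)]
  }
  if (length(isis) < 2)
    stop("insufficient data: need at least 2 ISIs")
  m <- mean(isis)
  s <- stats::sd(isis)
  structure(list(n = length(isis), mean = m, std = s, cv = s / m,
                 isis = isis),
            class = "isi_stats")
}

#' @export
print.isi_stats <- function(x, ...) {
  cat(sprintf("ISI stats (n = %d): mean %.2f ms, STD %.2f ms, CV %.3f\n",
              x$n, x$mean, x$std, x$cv))
  invisible(x)
}

#' ISI statistics of noisy firing at given parameters
#'
#' Convenience driver: settles onto the firing attractor, discards an
#' initial transient, collects \code{n_isi} interspike intervals under
#' additive white-noise current, and returns their statistics.
#'
#' @param p parameters (must lie in the firing regime)
#' @param D noise intensity
#' @param n_isi number of ISIs to collect
#' @param seed RNG seed
#' @param dt integration step (ms)
#' @param t_discard transient to discard (ms)
#' @param threshold,refractory spike criterion
#' @return an \code{isi_stats} object
#' @export
noisy_isi_stats <- function(p, D, n_isi = 2000, seed = 1, dt = 0.001,
                            t_discard = 500, threshold = 0, refractory = 2) {
  x0 <- c(V = -64, h = 0.78, n = 0.09, H = 0.2)
  # generous cap: mean ISI in the studied window is below ~300 ms
  t_end <- t_discard + 400 * (n_isi + 2)
  run <- run_spike_train(p, stim_protocol("constant"), x0, t_end = t_end,
                         dt = dt, noise = noise_spec(D, seed),
                         threshold = threshold, refractory = refractory,
                         t_discard = t_discard,
                         max_spikes = n_isi + 1L)
  isi_stats(run$spikes, n_target = n_isi)
}

#' First-spike timing across noisy ramp trials
#'
#' Runs \code{n_trials} independent noisy trials from the stable resting
#' state, each driven by a current ramp, and records the first
#' threshold-crossing time measured from ramp onset. Trial i uses seed
#' \code{seed + i}, so the ensemble is reproducible and trials are
#' independent. Trials with no spike inside the run window are counted and
#' excluded from the statistics.
#'
#' @param p parameters (resting at ramp start)
#' @param rate ramp slope (uA/cm2 per ms); the reference fast and slow ramps
#'   are 0.01 and 0.003
#' @param D noise intensity
#' @param n_trials number of trials
#' @param seed base RNG seed
#' @param t_max run window per trial (ms)
#' @param dt integration step (ms)
#' @param threshold,refractory spike criterion
#' @return list of class \code{"first_spike_ensemble"}: \code{times} (ms
#'   from ramp onset), \code{n_trials}, \code{n_no_spike}, \code{mean},
#'   \code{std}
#' @export
first_spike_ensemble <- function(p, rate, D, n_trials = 1000, seed = 1,
                                 t_max = 1000, dt = 0.001,
                                 threshold = 0, refractory = 2) {
  x0 <- settle_to_equilibrium(p)
  proto <- stim_protocol("ramp", rate = rate, onset = 0)
  times <- rep(NA_real_, n_trials)
  for (i in seq_len(n_trials)) {
    run <- run_spike_train(p, proto, x0, t_end = t_max, dt = dt,
                           noise = noise_spec(D, seed + i),
                           threshold = threshold, refractory = refractory,
                           max_spikes = 1L)
    if (length(run$spikes)) times[i] <- run$spikes[1]
  }
  ok <- !is.na(times)
  structure(list(times = times[ok], n_trials = n_trials,
                 n_no_spike = sum(!ok), mean = mean(times[ok]),
                 std = stats::sd(times[ok])),
            class = "first_spike_ensemble")
}

#' @export
print.first_spike_ensemble <- function(x, ...) {
  cat(sprintf(
    "first-spike ensemble: %d/%d trials spiked; mean %.2f ms, STD %.2f ms\n",
    length(x$times), x$n_trials, x$mean, x$std))
  invisible(x)
}

#' Histogram of interspike intervals
#'
#' @param isis ISI values (ms), or an \code{isi_stats} object
#' @param bin_width bin width (ms)
#' @return data.frame with \code{bin_left_ms} and \code{count}
#' @export
isi_histogram <- function(isis, bin_width = 5) {
  if (inherits(isis, "isi_stats")) isis <- isis$isis
  if (!length(isis)) stop("no ISIs supplied")
  breaks <- seq(0, max(isis) + bin_width, by = bin_width)
  h <- graphics::hist(isis, breaks = breaks, plot = FALSE)
  data.frame(bin_left_ms = h$breaks[-length(h$breaks)], count = h$counts)
}

#' Maps of resting potential, firing frequency, or ISI variability over the
#' (Iapp, gh) plane
#'
#' Per grid cell: resting membrane potential from the stable equilibrium
#' (masked NA where only firing exists); deterministic firing frequency
#' 1000 / mean ISI (masked where the cell rests); or the CV of ISIs of a
#' stochastic run (masked where the cell rests). Grid resolution, ISI
#' counts, and the step size are exposed so coarse maps stay cheap.
#'
#' @param p base parameters
#' @param kind "resting_V", "firing_freq", or "cv"
#' @param iapp_grid,gh_grid grid vectors
#' @param D noise intensity (kind = "cv")
#' @param n_isi ISIs per cell for kind "cv"
#' @param seed base seed for kind "cv"
#' @param dt integration step (ms)
#' @return list of class \code{"param_map"}: grids plus a value matrix
#'   (rows = Iapp, cols = gh) with NA at masked cells
#' @export
param_map <- function(p, kind = c("resting_V", "firing_freq", "cv"),
                      iapp_grid, gh_grid, D = 0.2, n_isi = 200, seed = 1,
                      dt = 0.001) {
  kind <- match.arg(kind)
  val <- matrix(NA_real_, length(iapp_grid), length(gh_grid))
  for (i in seq_along(iapp_grid)) {
    for (j in seq_along(gh_grid)) {
      pij <- p
      pij[["Iapp"]] <- iapp_grid[i]
      pij[["gh"]] <- gh_grid[j]
      eqs <- find_equilibria(pij)
      has_rest <- any(vapply(eqs, function(e) e$stable, TRUE))
      if (kind == "resting_V") {
        if (has_rest)
          val[i, j] <- Filter(function(e) e$stable, eqs)[[1]]$state[["V"]]
      } else if (!has_rest) {
        if (kind == "firing_freq") {
          st <- firing_state(pij, dt = dt)
          run <- run_spike_train(pij, stim_protocol("constant"), st,
                                 t_end = 5000, dt = dt, max_spikes = 21L)
          if (length(run$spikes) >= 3)
            val[i, j] <- 1000 / mean(diff(run$spikes))
        } else {
          s <- noisy_isi_stats(pij, D = D, n_isi = n_isi,
                               seed = seed + 1000 * i + j, dt = dt)
          val[i, j] <- s$cv
        }
      }
    }
  }
  structure(list(Iapp = iapp_grid, gh = gh_grid, kind = kind, value = val),
            class = "param_map")
}
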