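#' Sag and post-inhibitory rebound assay
#'
#' From the stable resting state, applies hyperpolarizing square pulses of
#' the given amplitudes and classifies the response after pulse offset:
#' \code{"rebound_spike"} if a spike occurs within \code{post_window} ms of
#' offset, \code{"rebound"} if V overshoots rest by more than
#' \code{overshoot_mV} without spiking, else \code{"no_rebound"}. The sag
#' depth is the recovery of V during the pulse: V at pulse end minus the
#' early minimum (>= 0; zero means no sag). The reference protocol uses
#' amplitudes -0.4, -0.8, -1.2 uA/cm2 with a 100 ms pulse.
#'
#' @param p parameters (resting region)
#' @param amplitudes pulse amplitudes (uA/cm2, negative)
#' @param duration pulse length (ms)
#' @param onset pulse onset (ms)
#' @param post_window window after offset in which a spike counts as a
#'   rebound spike (ms)
#' @param overshoot_mV overshoot above rest that counts as a rebound (mV)
#' @param dt integration step (ms)
#' @return data.frame with one row per amplitude: \code{amplitude},
#'   \code{outcome}, \code{sag_mV}, \code{rebound_spike_latency_ms} (NA if
#'   no spike)
#' @export
#' @examples
#' \dontrun{
#' rebound_assay(ih_params(Iapp = -0.05, gh = 0.05))
#' }
rebound_assay <- function(p, amplitudes = c(-0.4, -0.8, -1.2),
                          duration = 100, onset = 100, post_window = 200,
                          overshoot_mV = 1, dt = 0.001) {
  x0 <- settle_to_equilibrium(p)
  v_rest <- x0[["V"]]
  t_end <- onset + duration + post_window + 100
  out <- lapply(amplitudes, function(a) {
    proto <- stim_protocol("square_pulse", amplitude = a, onset = onset,
                           duration = duration)
    tr <- integrate_model(p, proto, x0 = x0, t_end = t_end, dt = dt,
                          thin = max(1L, as.integer(0.05 / dt)))
    inpulse <- tr$t >= onset & tr$t < onset + duration
    v_min_early <- min(tr$V[inpulse])
    v_end <- tr$V[max(which(inpulse))]
    sag <- max(0, v_end - v_min_early)
    post <- tr$t >= onset + duration & tr$t <= onset + duration + post_window
    sp <- detect_spikes(tr)
    sp_post <- sp$spike_times[sp$spike_times >= onset + duration &
                                sp$spike_times <= onset + duration +
                                  post_window]
    outcome <- if (length(sp_post)) "rebound_spike"
      else if (max(tr$V[post]) > v_rest + overshoot_mV) "rebound"
      else "no_rebound"
    data.frame(amplitude = a, outcome = outcome, sag_mV = sag,
               rebound_spike_latency_ms =
                 if (length(sp_post)) sp_post[1] - (onset + duration)
                 else NA_real_)
  })
  do.call(rbind, out)
}

#' Run a named experiment
#'
#' Config-driven driver reproducing the study's figure-level experiments.
#' \code{cfg} is a list with at least \code{experiment} (one of
#' \code{"rebound"}, \code{"first_spike"}, \code{"isi_stats"}, \code{"zap"},
#' \code{"sweep_1d"}, \code{"partition"}, \code{"custom"}), plus
#' \code{params} (arguments to [ih_params()]), \code{seed}, optional
#' experiment-specific fields, and optionally \code{out_dir} to write CSV /
#' JSON-free summaries. Unknown top-level keys are rejected. Every run
#' returns (and, with \code{out_dir}, writes) a manifest with the fully
#' resolved configuration, package version, and seed, so reruns from the
#' manifest are reproducible.
#'
#' @param cfg configuration list
#' @return list with \code{summary} (experiment output), \code{manifest}
#' @export
run_experiment <- function(cfg) {
  known <- c("experiment", "params", "seed", "out_dir", "rate", "D",
             "n_trials", "n_isi", "amplitudes", "duration", "gh_range",
             "n_grid", "iapp_grid", "gh_grid", "t_end", "dt", "thin", "fun")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (is.null(cfg$experiment)) stop("config needs an 'experiment' field")
  p <- do.call(ih_params, as.list(cfg$params %||% list()))
  seed <- cfg$seed %||% 1L
  dt <- cfg$dt %||% 0.001

  summary <- switch(cfg$experiment,
    rebound = rebound_assay(p,
      amplitudes = cfg$amplitudes %||% c(-0.4, -0.8, -1.2),
      duration = cfg$duration %||% 100, dt = dt),
    first_spike = {
      fe <- first_spike_ensemble(p, rate = cfg$rate %||% 0.01,
                                 D = cfg$D %||% 0.2,
                                 n_trials = cfg$n_trials %||% 1000,
                                 seed = seed, dt = dt)
      list(mean_ms = fe$mean, std_ms = fe$std, n_no_spike = fe$n_no_spike)
    },
    isi_stats = {
      s <- noisy_isi_stats(p, D = cfg$D %||% 0.2,
                           n_isi = cfg$n_isi %||% 2000, seed = seed, dt = dt)
      list(n = s$n, mean_ms = s$mean, std_ms = s$std, cv = s$cv)
    },
    zap = {
      x0 <- settle_to_equilibrium(p)
      tr <- integrate_model(p, stim_protocol("zap"), x0 = x0,
                            t_end = cfg$t_end %||% 20000, dt = dt,
                            thin = cfg$thin %||% as.integer(1 / dt))
      ip <- impedance_profile(tr)
      list(f_peak_Hz = ip$f_peak, Z_peak = ip$Z_peak,
           class = ip$resonance_class, envelope_mV = zap_envelope(tr))
    },
    sweep_1d = sweep_1d(p, gh_range = cfg$gh_range %||% c(0, 0.1),
                        n_grid = cfg$n_grid %||% 201)$points,
    partition = stable_behavior_partition(
      p, cfg$iapp_grid %||% seq(-0.2, 0.2, length.out = 9),
      cfg$gh_grid %||% seq(0, 0.14, length.out = 8), dt = cfg$dt %||% 0.005),
    custom = {
      if (is.null(cfg$fun) || !is.function(cfg$fun))
        stop("custom experiment needs a 'fun' field")
      cfg$fun(p, cfg)
    },
    stop("unknown experiment id: ", cfg$experiment))

  manifest <- list(
    experiment = cfg$experiment,
    resolved_params = unclass(p),
    seed = seed,
    dt = dt,
    package_version = as.character(utils::packageVersion("ihdyn")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (is.data.frame(summary))
      utils::write.csv(summary, file.path(cfg$out_dir, "summary.csv"),
                       row.names = FALSE)
    mf <- file.path(cfg$out_dir, "manifest.dcf")
    write.dcf(data.frame(lapply(manifest, function(x)
      paste(deparse(x), collapse = ""))), mf)
  }
  list(summary = summary, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
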