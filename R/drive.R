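#' Noisy current drive configuration
#'
#' Input-layer neurons are driven by i.i.d. uniform current on
#' `[lo_frac * i_th, hi_frac * i_th]`, redrawn every 1 ms step; a blocked
#' drive emits exactly zero current.  The default threshold-current scale
#' `i_th = 5.81` model units is calibrated (see [calibrate_i_th()]) so that
#' the driven regular-spiking neuron fires at a mean rate of 15 Hz, the
#' operating point of the corticospinal model; the analytic [rheobase()] of
#' 4.0 under-drives the discrete-time map and is not used as the default.
#'
#' @param i_th Threshold current scale (model units).
#' @param lo_frac,hi_frac Lower/upper interval fractions (defaults 0.6, 1.7).
#' @param mode `"active"` or `"blocked"`.
#' @param seed Integer seed of this drive's random stream.
#' @return An object of class `drive_config`.
#' @export
drive_config <- function(i_th = 5.81, lo_frac = 0.6, hi_frac = 1.7,
                         mode = c("active", "blocked"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(i_th > 0, 0 < lo_frac, lo_frac < hi_frac)
  structure(list(i_th = i_th, lo_frac = lo_frac, hi_frac = hi_frac,
                 mode = mode, seed = as.integer(seed)),
            class = "drive_config")
}

#' Sample the drive current at given steps
#'
#' Reproducible from `(seed, step)`: the k-th step always receives the k-th
#' draw of the stream, matching the engine's consumption order for a single
#' input neuron.
#'
#' @param cfg A [drive_config()].
#' @param steps Integer step indices (1-based).
#' @return Currents in model units (all zero for a blocked drive).
#' @export
sample_current <- function(cfg, steps) {
  stopifnot(all(steps >= 1))
  if (cfg$mode == "blocked") return(numeric(length(steps)))
  u <- unif_stream(cfg$seed, stream = 0L, n = max(steps))[steps]
  cfg$i_th * (cfg$lo_frac + (cfg$hi_frac - cfg$lo_frac) * u)
}

#' Firing statistics of one noise-driven neuron
#'
#' Simulates a single regular-spiking neuron under the uniform noise drive
#' for `duration_s` seconds of 1-ms steps, discards a warm-up transient, and
#' returns the firing rate and ISI summary.
#'
#' @param cfg A [drive_config()].
#' @param params An [izhikevich_params()].
#' @param duration_s Simulated duration in seconds (>= 60 s recommended for
#'   stable statistics).
#' @param warmup_s Warm-up transient discarded from the analysis window.
#' @return List with `rate_hz`, `isi_mean_ms`, `isi_sd_ms`, `isi_cv`,
#'   `n_spikes`, and the retained `spikes_ms`.
#' @export
drive_statistics <- function(cfg = drive_config(),
                             params = izhikevich_params(), duration_s = 600,
                             warmup_s = 5) {
  stopifnot(duration_s > warmup_s)
  res <- cpp_simulate_network(
    nrn = unlist(params, use.names = FALSE),
    ker = unlist(stdp_kernel(), use.names = FALSE),
    tau_scd_ms = 15, eta = 0, g_scale = 0, g_min = 0, g_max = 1,
    syn_pre = integer(0), syn_post = integer(0), g0 = numeric(0),
    tau_swd_ms = numeric(0), n_in = 1L, n_out = 0L,
    stage_active = matrix(if (cfg$mode == "active") 1L else 0L, 1, 1),
    stage_dur_ms = duration_s * 1000,
    pred_contra = integer(0), pred_ipsi = integer(0),
    pred_margin = 0, pred_cap_ms = 0,
    i_lo = cfg$lo_frac * cfg$i_th, i_hi = cfg$hi_frac * cfg$i_th,
    seed = cfg$seed, record_every_ms = 1e6L, record_spikes = TRUE)
  sp <- res$spikes[[1]]
  sp <- sp[sp >= warmup_s * 1000]
  if (length(sp) < 2) {
    stop("fewer than two spikes after warm-up: drive misconfigured")
  }
  st <- isi_stats(sp)
  list(rate_hz = length(sp) / (duration_s - warmup_s),
       isi_mean_ms = st$mean_ms, isi_sd_ms = st$sd_ms, isi_cv = st$cv,
       n_spikes = length(sp), spikes_ms = sp)
}

#' Calibrate the threshold current scale against a target firing rate
#'
#' Bisects `i_th` so that the mean firing rate of the noise-driven RS neuron
#' matches `target_rate_hz`.  The rate is averaged over several seeds to tame
#' sampling error.  With the defaults this reproduces the frozen package
#' default `i_th = 5.81`.
#'
#' @param target_rate_hz Target mean firing rate (Hz).
#' @param params An [izhikevich_params()].
#' @param duration_s Simulated seconds per evaluation.
#' @param seeds Seeds averaged per evaluation.
#' @param lower,upper Bisection bracket for `i_th`.
#' @param tol Bracket width at which to stop (model units).
#' @return Calibrated `i_th` (model units).
#' @export
calibrate_i_th <- function(target_rate_hz = 15, params = izhikevich_params(),
                           duration_s = 300, seeds = 1:2, lower = 3,
                           upper = 10, tol = 0.005) {
  rate_at <- function(i_th) {
    mean(vapply(seeds, function(s) {
      drive_statistics(drive_config(i_th = i_th, seed = s), params,
                       duration_s = duration_s)$rate_hz
    }, numeric(1)))
  }
  lo <- lower
  hi <- upper
  if (rate_at(lo) > target_rate_hz || rate_at(hi) < target_rate_hz) {
    stop("calibration bracket does not contain the target rate")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (rate_at(mid) < target_rate_hz) lo <- mid else hi <- mid
  }
  round((lo + hi) / 2, 2)
}
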