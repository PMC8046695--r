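#' STDP kernel
#'
#' Asymmetric exponential spike-timing-dependent plasticity kernel.  For a
#' pre/post spike pair with lag `dt = t_post - t_pre` (ms) the weight change
#' contribution is `a_plus * exp(-dt / tau_plus_ms)` when `dt > 0` (LTP) and
#' `a_minus * exp(-|dt| / tau_minus_ms)` when `dt < 0` (LTD); pairs farther
#' apart than `window_ms` contribute nothing, and simultaneous spikes
#' (`dt = 0`) are excluded by convention.  Defaults follow rat visual-cortex
#' pairing data: `A+ = 1.03`, `A- = -0.51`, `tau+ = 14` ms, `tau- = 34` ms,
#' with a 64 ms pairing window.
#'
#' @param a_plus LTP amplitude (fraction of the additive step `eta`).
#' @param a_minus LTD amplitude (negative fraction).
#' @param tau_plus_ms LTP time constant (ms).
#' @param tau_minus_ms LTD time constant (ms).
#' @param window_ms Maximum pre/post pairing lag (ms); a lag exactly equal to
#'   the window is still counted.
#' @return An object of class `stdp_kernel`.
#' @export
stdp_kernel <- function(a_plus = 1.03, a_minus = -0.51, tau_plus_ms = 14,
                        tau_minus_ms = 34, window_ms = 64) {
  stopifnot(a_plus > 0, a_minus < 0, tau_plus_ms > 0, tau_minus_ms > 0,
            window_ms > 0)
  structure(list(a_plus = a_plus, a_minus = a_minus,
                 tau_plus_ms = tau_plus_ms, tau_minus_ms = tau_minus_ms,
                 window_ms = window_ms),
            class = "stdp_kernel")
}

#' Evaluate the STDP kernel at signed lags
#'
#' @param kernel An [stdp_kernel()].
#' @param delta_t_ms Signed lag(s) `t_post - t_pre` in ms; vectorised.
#' @return Weight-change contribution(s) in kernel units (multiples of the
#'   additive step `eta`).  Zero at `delta_t = 0` and beyond the window.
#' @export
evaluate_kernel <- function(kernel, delta_t_ms) {
  out <- numeric(length(delta_t_ms))
  pos <- delta_t_ms > 0 & delta_t_ms <= kernel$window_ms
  neg <- delta_t_ms < 0 & -delta_t_ms <= kernel$window_ms
  out[pos] <- kernel$a_plus * exp(-delta_t_ms[pos] / kernel$tau_plus_ms)
  out[neg] <- kernel$a_minus * exp(delta_t_ms[neg] / kernel$tau_minus_ms)
  out
}

#' Plastic synapse
#'
#' State of one additive STDP synapse: weight `g` (normalised units, clamped
#' to `[g_min, g_max]`), postsynaptic current `i_post` (weight units; the
#' network layer applies the current gain), exponential decay constants for
#' current (`tau_scd_ms`, default 15 ms) and weight (`tau_swd_ms`, default
#' 35 h), the additive update scale `eta`, and ring buffers of recent pre and
#' post spike times inside the pairing window.
#'
#' @param g Initial weight.
#' @param kernel An [stdp_kernel()].
#' @param g_min,g_max Weight bounds (normalised units).
#' @param eta Additive update scale (weight units per kernel unit).
#' @param tau_scd_ms Synaptic current decay constant (ms).
#' @param tau_swd_ms Synaptic weight decay constant (ms; 35 h by default).
#' @return An object of class `synapse`.
#' @export
synapse <- function(g = 0.5, kernel = stdp_kernel(), g_min = 0, g_max = 1,
                    eta = 1, tau_scd_ms = 15, tau_swd_ms = 35 * 3600 * 1000) {
  stopifnot(g_min <= g, g <= g_max, eta >= 0, tau_scd_ms > 0,
            tau_swd_ms > tau_scd_ms)
  structure(list(g = g, i_post = 0, kernel = kernel, g_min = g_min,
                 g_max = g_max, eta = eta, tau_scd_ms = tau_scd_ms,
                 tau_swd_ms = tau_swd_ms, pre_buffer = numeric(0),
                 post_buffer = numeric(0), last_t = -Inf),
            class = "synapse")
}

evict <- function(buf, t, window) buf[buf >= t - window]

check_time <- function(syn, t) {
  if (t < syn$last_t) {
    stop("out-of-order synaptic event at t = ", t,
         " (last event at ", syn$last_t, "): scheduler bug")
  }
}

#' Presynaptic spike event
#'
#' Delivers current (`i_post` incremented by `g`), applies the LTD side of
#' all-to-all pairing against every buffered postsynaptic spike inside the
#' window, clamps the weight, and records the spike time.
#'
#' @param syn A [synapse()].
#' @param t Spike time in ms; must not precede any earlier event time on
#'   this synapse (same-step pre and post events are allowed and commute,
#'   because zero-lag pairs are excluded).
#' @return The updated synapse.
#' @export
on_pre_spike <- function(syn, t) {
  check_time(syn, t)
  w <- syn$kernel$window_ms
  syn$post_buffer <- evict(syn$post_buffer, t, w)
  dg <- sum(evaluate_kernel(syn$kernel, syn$post_buffer - t))
  syn$g <- min(max(syn$g + syn$eta * dg, syn$g_min), syn$g_max)
  syn$i_post <- syn$i_post + syn$g
  syn$pre_buffer <- c(evict(syn$pre_buffer, t, w), t)
  syn$last_t <- t
  syn
}

#' Postsynaptic spike event
#'
#' Applies the LTP side of all-to-all pairing against every buffered
#' presynaptic spike inside the window, clamps the weight, and records the
#' spike time.
#'
#' @inheritParams on_pre_spike
#' @return The updated synapse.
#' @export
on_post_spike <- function(syn, t) {
  check_time(syn, t)
  w <- syn$kernel$window_ms
  syn$pre_buffer <- evict(syn$pre_buffer, t, w)
  dg <- sum(evaluate_kernel(syn$kernel, t - syn$pre_buffer))
  syn$g <- min(max(syn$g + syn$eta * dg, syn$g_min), syn$g_max)
  syn$post_buffer <- c(evict(syn$post_buffer, t, w), t)
  syn$last_t <- t
  syn
}

#' One 1-ms decay step of a synapse
#'
#' Exact exponential decay of the postsynaptic current and the weight over
#' one step: `i_post <- i_post * exp(-dt / tau_scd)` and
#' `g <- g * exp(-dt / tau_swd)`, the weight then clamped from below at
#' `g_min`.  Using the exact per-step factor (not an Euler approximation)
#' keeps long-horizon decay step-count-exact.
#'
#' @param syn A [synapse()].
#' @param dt Step size in ms (fixed at 1).
#' @return The updated synapse.
#' @export
decay_step <- function(syn, dt = 1) {
  if (!identical(as.numeric(dt), 1)) {
    stop("the model is defined at a fixed 1 ms resolution (dt = 1)")
  }
  syn$i_post <- syn$i_post * exp(-1 / syn$tau_scd_ms)
  syn$g <- max(syn$g * exp(-1 / syn$tau_swd_ms), syn$g_min)
  syn
}
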