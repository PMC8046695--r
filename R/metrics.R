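#' Interspike-interval statistics
#'
#' Consecutive-difference ISI summary of a spike train: mean, sample standard
#' deviation (n - 1 denominator), coefficient of variation `cv = sd / mean`,
#' and the number of intervals.
#'
#' @param spikes_ms Numeric vector of spike times in ms (need not be sorted).
#' @return List with `mean_ms`, `sd_ms`, `cv`, `n_isi`.
#' @export
isi_stats <- function(spikes_ms) {
  if (length(spikes_ms) < 2) {
    stop("at least two spikes are required to form an interspike interval")
  }
  isi <- diff(sort(spikes_ms))
  m <- mean(isi)
  s <- if (length(isi) > 1) stats::sd(isi) else 0
  list(mean_ms = m, sd_ms = s, cv = s / m, n_isi = length(isi))
}

#' Extrapolated long-horizon spike count
#'
#' Projects a steady firing rate over a horizon of days and reports the
#' total spike count in millions (3 significant figures).
#'
#' @param rate_hz Firing rate in Hz; must be non-negative.
#' @param days Horizon in days.
#' @return Spike count in millions.
#' @export
extrapolate_spike_count <- function(rate_hz, days) {
  stopifnot(rate_hz >= 0, days >= 0)
  signif(rate_hz * days * 86400 / 1e6, 3)
}

#' Dominance classification of the 2x2 corticospinal weights
#'
#' Each output neuron receives one contralateral and one ipsilateral synapse;
#' it is labelled `contra` when the contralateral weight exceeds
#' `(1 + margin)` times the ipsilateral one, `ipsi` in the reverse case, and
#' `mixed` otherwise.  In the weight order `w0 = R->OR` (ipsi),
#' `w1 = L->OR` (contra), `w2 = R->OL` (contra), `w3 = L->OL` (ipsi), output
#' OR compares `w1` against `w0` and output OL compares `w2` against `w3`.
#'
#' @param w Numeric vector of the four weights `c(w0, w1, w2, w3)`.
#' @param margin Relative dominance margin (default 0.1 = 10%).
#' @return Named character vector `c(OR = ..., OL = ...)` with values in
#'   `{"contra", "ipsi", "mixed"}`.
#' @export
dominance <- function(w, margin = 0.1) {
  stopifnot(length(w) == 4, all(is.finite(w)), all(w >= 0))
  c(OR = dominance_pair(w[2], w[1], margin),
    OL = dominance_pair(w[3], w[4], margin))
}

#' Dominance label for one contralateral/ipsilateral weight pair
#'
#' @param contra,ipsi Competing weights at one output neuron.
#' @param margin Relative dominance margin.
#' @return `"contra"`, `"ipsi"` or `"mixed"`.
#' @export
dominance_pair <- function(contra, ipsi, margin = 0.1) {
  if (contra > (1 + margin) * ipsi) "contra"
  else if (ipsi > (1 + margin) * contra) "ipsi"
  else "mixed"
}
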