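#' Example synaptic-competition cases
#'
#' Three two-input/one-output competition scenarios distinguished by their
#' initial weights and stage schedules (durations in demo-scale seconds;
#' multiply by the scale factor for paper scale):
#' \describe{
#'   \item{a}{left predominant start (`wL = 0.6`, `wR = 0.3`), both inputs
#'     active throughout; the predominant side wins and takes all.}
#'   \item{b}{as (a), plus a transient blockade of the dominant left input;
#'     the blockade flips the competition to right dominance.}
#'   \item{c}{left considerably stronger (`wL = 0.8`, `wR = 0.2`), both
#'     active; left dominance is established.}
#' }
#'
#' @param case `"a"`, `"b"` or `"c"`.
#' @param config A `run_config`; stage durations scale with its preset.
#' @return List with `topology`, `g0` and `stages`.
#' @export
make_example_case <- function(case = c("a", "b", "c"),
                              config = default_config()) {
  case <- match.arg(case)
  top <- make_topology("two_input_one_output")
  f <- scale_seconds(config)
  both <- c(L = "active", R = "active")
  spec <- switch(case,
    a = list(g0 = c(wL = 0.6, wR = 0.3), stages = list(
      stage_spec("bilateral activation", both, duration_s = 3600 * f))),
    b = list(g0 = c(wL = 0.6, wR = 0.3), stages = list(
      stage_spec("bilateral activation", both, duration_s = 600 * f),
      stage_spec("transient blockade of L", c(L = "blocked", R = "active"),
                 duration_s = 1500 * f),
      stage_spec("bilateral activation resumed", both,
                 duration_s = 2100 * f))),
    c = list(g0 = c(wL = 0.8, wR = 0.2), stages = list(
      stage_spec("bilateral activation", both, duration_s = 3600 * f))))
  c(list(topology = top), spec)
}

scale_seconds <- function(config) {
  if (config$scale$preset == "paper") config$scale$factor else 1
}

#' Run one example competition case
#'
#' @inheritParams make_example_case
#' @param seed Drive-stream seed.
#' @param record_every_ms Weight-logging cadence.
#' @return A `subnetwork_run`; see [simulate_network()].
#' @export
run_example_case <- function(case = c("a", "b", "c"),
                             config = default_config(), seed = 1L,
                             record_every_ms = 1000L) {
  ec <- make_example_case(case, config)
  simulate_network(ec$topology, ec$stages, ec$g0, config, seed = seed,
                   record_every_ms = record_every_ms)
}

#' The five-stage constraint-induced intervention protocol
#'
#' Stage schedule on the 2x2 corticospinal topology, starting from healthy
#' contralateral dominance (`w1, w2 = 0.6` contralateral, `w0, w3 = 0.3`
#' ipsilateral):
#' \enumerate{
#'   \item initial healthy stable state — bilateral activation;
#'   \item unilateral inactivation (R blocked) — the active hemisphere's
#'     ipsilateral projection grows, the blocked hemisphere's contralateral
#'     projection decays: hemiplegic bilateral projection from L;
#'   \item bilateral activation — the deficit is stuck (hysteresis);
#'   \item reverse inactivation (L blocked) — the constraint; terminates
#'     when both contralateral weights exceed their ipsilateral competitors
#'     by the margin;
#'   \item bilateral activation — the restored contralateral dominance
#'     persists.
#' }
#' Durations are demo-scale seconds (multiplied by the scale factor under
#' the paper preset).
#'
#' @param config A `run_config`.
#' @param margin Dominance margin for the reverse-inactivation predicate.
#' @return List of [stage_spec()] objects.
#' @export
cimt_protocol <- function(config = default_config(), margin = 0.1) {
  f <- scale_seconds(config)
  both <- c(R = "active", L = "active")
  list(
    stage_spec("healthy baseline", both, duration_s = 600 * f),
    stage_spec("unilateral inactivation (R blocked)",
               c(R = "blocked", L = "active"), duration_s = 1800 * f),
    stage_spec("bilateral activation (stuck)", both, duration_s = 600 * f),
    stage_spec("reverse inactivation (L blocked)",
               c(R = "active", L = "blocked"),
               terminate_when = "contra_dominant", margin = margin,
               cap_s = 6000 * f),
    stage_spec("bilateral activation (persistence)", both,
               duration_s = 900 * f))
}

#' Healthy initial weights of the corticospinal model
#'
#' Contralateral projections predominant: `w0 = 0.3`, `w1 = 0.6`,
#' `w2 = 0.6`, `w3 = 0.3`.
#'
#' @return Named numeric vector of four weights.
#' @export
healthy_weights <- function() {
  c(w0 = 0.3, w1 = 0.6, w2 = 0.6, w3 = 0.3)
}

#' Run a staged protocol and label each stage's end state
#'
#' @param stages List of [stage_spec()]s (default: the five-stage
#'   constraint-therapy protocol).
#' @param g0 Initial weights (default: healthy contralateral dominance).
#' @param topology Network topology (default: the 2x2 corticospinal model).
#' @param config A `run_config`.
#' @param seed Drive-stream seed.
#' @param margin Dominance margin used for the end-of-stage labels.
#' @param record_every_ms Weight-logging cadence.
#' @return A list of class `protocol_result`: the `run` (see
#'   [simulate_network()]), `stage_dominance` (per-stage-end labels, one row
#'   per stage), and `stage_end_weights`.
#' @export
run_protocol <- function(stages = cimt_protocol(config), g0 = healthy_weights(),
                         topology = make_topology("cst_2x2"),
                         config = default_config(), seed = 1L, margin = 0.1,
                         record_every_ms = 1000L) {
  stopifnot(length(stages) >= 1)
  run <- simulate_network(topology, stages, g0, config, seed = seed,
                          record_every_ms = record_every_ms)
  ends <- stage_end_weights(run)
  dom <- NULL
  if (topology$type == "cst_2x2") {
    dom <- t(apply(ends, 1, function(w) dominance(unname(w), margin)))
    dom <- data.frame(stage = rownames(ends), OR = dom[, "OR"],
                      OL = dom[, "OL"], row.names = NULL)
  }
  structure(list(run = run, stage_dominance = dom,
                 stage_end_weights = ends, margin = margin),
            class = "protocol_result")
}

#' Weights at the end of every stage of a run
#'
#' @param run A `subnetwork_run`.
#' @return Matrix (stages x synapses) of end-of-stage weights.
#' @export
stage_end_weights <- function(run) {
  labs <- run$topology$syn_labels
  tr <- run$trajectory
  out <- t(vapply(seq_len(nrow(run$stage_bounds)), function(k) {
    rows <- which(tr$stage == k)
    unlist(tr[rows[length(rows)], labs])
  }, numeric(length(labs))))
  dimnames(out) <- list(run$stage_bounds$stage, labs)
  out
}

#' @export
print.protocol_result <- function(x, ...) {
  print(x$run)
  if (!is.null(x$stage_dominance)) {
    cat("end-of-stage dominance (margin ", x$margin * 100, "%):\n", sep = "")
    print(x$stage_dominance)
  }
  invisible(x)
}

#' Monosynaptic STDP validation run
#'
#' Drives the one-input/one-output circuit with sustained noise and logs the
#' gradual growth of the single synaptic weight, the direct functional check
#' that causally paired pre/post activity potentiates the connection.
#'
#' @param duration_s Simulated seconds (demo-scale).
#' @param g0 Initial weight.
#' @param config A `run_config`.
#' @param seed Drive-stream seed.
#' @param bin_s Bin width (s) for the binned weight means.
#' @param record_spikes Record spike times as well.
#' @return List with the `run`, `bin_means` (average weight per time bin)
#'   and `bin_s`.
#' @export
validate_stdp <- function(duration_s = 600, g0 = 0.3,
                          config = default_config(), seed = 1L, bin_s = 36,
                          record_spikes = FALSE) {
  top <- make_topology("monosynaptic")
  st <- list(stage_spec("sustained activation", c(n0 = "active"),
                        duration_s = duration_s))
  run <- simulate_network(top, st, c(w = g0), config, seed = seed,
                          record_every_ms = 200L,
                          record_spikes = record_spikes)
  tr <- run$trajectory
  bins <- floor(tr$time_ms / (bin_s * 1000))
  bin_means <- tapply(tr$w, bins, mean)
  list(run = run, bin_means = as.numeric(bin_means), bin_s = bin_s)
}
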