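#' Network topologies
#'
#' Three tiny two-layer wirings are used throughout:
#' \describe{
#'   \item{`monosynaptic`}{one input, one output, one synapse — the STDP
#'     validation circuit.}
#'   \item{`two_input_one_output`}{inputs L and R converging on one output —
#'     the synaptic-competition circuit (also the retina-to-cortex wiring of
#'     the ocular-dominance comparison).}
#'   \item{`cst_2x2`}{the corticospinal model: cortical inputs R and L,
#'     spinal outputs OR and OL, with `w0 = R->OR` (ipsilateral),
#'     `w1 = L->OR` (contralateral), `w2 = R->OL` (contralateral),
#'     `w3 = L->OL` (ipsilateral).  Contralateral weights decay with
#'     `tau_swd` and ipsilateral ones 1.5x faster (`tau_swd / 1.5`),
#'     reflecting the developmental advantage of the crossed projection.}
#' }
#'
#' @param type Topology name.
#' @return List describing inputs, outputs and synapses, of class `topology`.
#' @export
make_topology <- function(type = c("cst_2x2", "two_input_one_output",
                                   "monosynaptic")) {
  type <- match.arg(type)
  top <- switch(type,
    monosynaptic = list(
      inputs = "n0", outputs = "n1",
      syn_pre = 1L, syn_post = 1L,
      syn_labels = "w", syn_side = "contra"),
    two_input_one_output = list(
      inputs = c("L", "R"), outputs = "O",
      syn_pre = c(1L, 2L), syn_post = c(1L, 1L),
      syn_labels = c("wL", "wR"), syn_side = c("contra", "contra")),
    cst_2x2 = list(
      inputs = c("R", "L"), outputs = c("OR", "OL"),
      syn_pre = c(1L, 2L, 1L, 2L), syn_post = c(1L, 1L, 2L, 2L),
      syn_labels = c("w0", "w1", "w2", "w3"),
      syn_side = c("ipsi", "contra", "contra", "ipsi")))
  structure(c(list(type = type), top), class = "topology")
}

#' One protocol stage
#'
#' A stage fixes the drive mode of every input and lasts either a fixed
#' simulated duration or, for the reverse-inactivation stage, until the
#' restored contralateral weights exceed their ipsilateral competitors by a
#' relative margin.
#'
#' @param name Stage label.
#' @param drive Named character vector mapping each input name to `"active"`
#'   or `"blocked"`.
#' @param duration_s Stage duration in simulated seconds (exclusive with
#'   `terminate_when`).
#' @param terminate_when `"contra_dominant"` to end the stage at the first
#'   step where every contralateral weight exceeds `(1 + margin)` times its
#'   ipsilateral competitor.
#' @param margin Relative dominance margin for the predicate.
#' @param cap_s Hard cap (simulated seconds) for a predicate-terminated
#'   stage; exceeding it is an error carrying the partial trajectory.
#' @return An object of class `stage_spec`.
#' @export
stage_spec <- function(name, drive, duration_s = NULL, terminate_when = NULL,
                       margin = 0.1, cap_s = 6000) {
  if (is.null(duration_s) == is.null(terminate_when)) {
    stop("exactly one of `duration_s` and `terminate_when` must be given")
  }
  if (!is.null(duration_s)) stopifnot(duration_s > 0)
  if (!is.null(terminate_when)) {
    terminate_when <- match.arg(terminate_when, "contra_dominant")
  }
  stopifnot(all(drive %in% c("active", "blocked")))
  structure(list(name = name, drive = drive, duration_s = duration_s,
                 terminate_when = terminate_when, margin = margin,
                 cap_s = cap_s),
            class = "stage_spec")
}

stage_matrix <- function(stages, topology) {
  t(vapply(stages, function(st) {
    dr <- st$drive[topology$inputs]
    if (anyNA(dr)) {
      stop("stage '", st$name, "' does not specify a drive mode for every ",
           "input of the '", topology$type, "' topology")
    }
    as.integer(dr == "active")
  }, integer(length(topology$inputs))))
}

#' Simulate a staged run of one subnetwork
#'
#' Wraps the compiled engine.  Per 1-ms step: drives are sampled, input
#' neurons stepped, presynaptic events applied (LTD pairing + current
#' delivery), output neurons stepped on the gained sum of their synaptic
#' currents (outputs receive no direct noise), postsynaptic events applied
#' (LTP pairing), then all currents and weights decay.  Synaptic delivery is
#' within-step, so causal pre-to-post lags are >= 1 ms.
#'
#' @param topology A [make_topology()] object.
#' @param stages List of [stage_spec()] objects.
#' @param g0 Initial synaptic weights (one per synapse).
#' @param config A simulation config, see [default_config()].
#' @param seed Integer seed for this subnetwork's drive streams.
#' @param record_every_ms Weight-logging cadence (ms).
#' @param record_spikes Record per-neuron spike times (memory-heavy on long
#'   runs; spike counts per stage are always recorded).
#' @return A list of class `subnetwork_run`: `trajectory` (data.frame with
#'   `time_ms`, `stage`, one column per weight), `g_final`, `stage_bounds`,
#'   `spike_counts`, `pred_met`, `spikes` (optional), plus the call metadata.
#' @export
simulate_network <- function(topology, stages, g0, config = default_config(),
                             seed = 1L, record_every_ms = 100L,
                             record_spikes = FALSE) {
  stopifnot(inherits(topology, "topology"),
            length(g0) == length(topology$syn_pre))
  syn <- config$synapse
  tau_swd_ms <- ifelse(topology$syn_side == "ipsi",
                       syn$tau_swd_ms / syn$decay_ratio_ipsi, syn$tau_swd_ms)
  durs <- vapply(stages, function(st) {
    if (is.null(st$duration_s)) -1 else st$duration_s * 1000
  }, numeric(1))
  pred_stages <- which(durs < 0)
  margin <- if (length(pred_stages)) stages[[pred_stages[1]]]$margin else 0
  cap_ms <- if (length(pred_stages)) stages[[pred_stages[1]]]$cap_s * 1000 else 0
  contra_idx <- which(topology$syn_side == "contra")
  ipsi_idx <- which(topology$syn_side == "ipsi")
  if (length(pred_stages) && (length(contra_idx) != length(ipsi_idx) ||
                              length(contra_idx) == 0)) {
    stop("a 'contra_dominant' predicate stage needs paired contralateral/",
         "ipsilateral synapses (use the cst_2x2 topology)")
  }
  res <- cpp_simulate_network(
    nrn = unlist(config$neuron, use.names = FALSE),
    ker = unlist(config$kernel, use.names = FALSE),
    tau_scd_ms = syn$tau_scd_ms, eta = syn$eta, g_scale = syn$g_scale,
    g_min = syn$g_min, g_max = syn$g_max,
    syn_pre = topology$syn_pre - 1L, syn_post = topology$syn_post - 1L,
    g0 = g0, tau_swd_ms = tau_swd_ms,
    n_in = length(topology$inputs), n_out = length(topology$outputs),
    stage_active = stage_matrix(stages, topology), stage_dur_ms = durs,
    pred_contra = contra_idx, pred_ipsi = ipsi_idx,
    pred_margin = margin, pred_cap_ms = cap_ms,
    i_lo = config$drive$lo_frac * config$drive$i_th,
    i_hi = config$drive$hi_frac * config$drive$i_th,
    seed = seed, record_every_ms = as.integer(record_every_ms),
    record_spikes = record_spikes)
  traj <- data.frame(time_ms = res$time_ms, stage = res$stage)
  W <- res$W
  colnames(W) <- topology$syn_labels
  traj <- cbind(traj, as.data.frame(W))
  names(res$g_final) <- topology$syn_labels
  cnt <- res$spike_counts
  colnames(cnt) <- c(topology$inputs, topology$outputs)
  rownames(cnt) <- vapply(stages, `[[`, "", "name")
  spikes <- res$spikes
  if (is.null(spikes) || length(spikes) == 0) {
    spikes <- NULL
  } else {
    names(spikes) <- c(topology$inputs, topology$outputs)
  }
  out <- structure(list(
    trajectory = traj, g_final = res$g_final,
    stage_bounds = data.frame(
      stage = vapply(stages, `[[`, "", "name"),
      start_ms = res$stage_start_ms, end_ms = res$stage_end_ms,
      pred_met = res$pred_met),
    spike_counts = cnt, spikes = spikes,
    topology = topology, stages = stages, g0 = g0, seed = seed,
    record_every_ms = record_every_ms, config = config),
    class = "subnetwork_run")
  failed <- vapply(stages, function(st) !is.null(st$terminate_when),
                   logical(1)) & !res$pred_met
  if (any(failed)) {
    cond <- structure(
      class = c("synapcomp_predicate_error", "error", "condition"),
      list(message = paste0(
             "stage '", stages[[which(failed)[1]]]$name, "' did not reach ",
             "contralateral dominance within its cap; constraint duration ",
             "insufficient (partial trajectory attached)"),
           call = NULL, run = out))
    stop(cond)
  }
  out
}

#' @export
print.subnetwork_run <- function(x, ...) {
  cat("<subnetwork_run> topology:", x$topology$type,
      "| seed:", x$seed, "\n")
  cat("stages:\n")
  b <- x$stage_bounds
  for (i in seq_len(nrow(b))) {
    cat(sprintf("  %-24s %8.1f - %8.1f s\n", b$stage[i],
                b$start_ms[i] / 1000, b$end_ms[i] / 1000))
  }
  cat("final weights:\n")
  print(round(x$g_final, 4))
  invisible(x)
}

#' Plot the weight trajectory of a run
#'
#' @param x A `subnetwork_run`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.subnetwork_run <- function(x, ...) {
  labs <- x$topology$syn_labels
  graphics::matplot(x$trajectory$time_ms / 1000,
                    as.matrix(x$trajectory[, labs, drop = FALSE]),
                    type = "l", lty = 1, xlab = "time (s)",
                    ylab = "synaptic weight", ...)
  graphics::abline(v = x$stage_bounds$end_ms / 1000, col = "grey", lty = 3)
  graphics::legend("topright", legend = labs, col = seq_along(labs), lty = 1,
                   bty = "n")
  invisible(x)
}

#' One 1-ms step of a subnetwork (reference implementation)
#'
#' Pure-R single step with the exact event order of the compiled engine,
#' consuming one uniform per active input (inputs in order) from the same
#' seeded streams.  Used as an independent cross-check of the engine and for
#' unit-level inspection; far too slow for production runs.
#'
#' @param state State list from [init_subnetwork_state()].
#' @param currents Numeric vector of input currents for this step (one per
#'   input; blocked inputs must be 0).  For parity with the engine, take
#'   the step-th draw of [unif_stream()] stream `stage * 256 + input`.
#' @return The updated state.
#' @export
step_subnetwork <- function(state, currents) {
  top <- state$topology
  n_in <- length(top$inputs)
  t <- state$t
  in_spiked <- logical(n_in)
  for (i in seq_len(n_in)) {
    r <- step_neuron(state$neurons[[i]], state$params, currents[i])
    state$neurons[[i]] <- r$state
    in_spiked[i] <- r$spiked
    if (r$spiked) state$spike_log[[i]] <- c(state$spike_log[[i]], t)
  }
  for (s in seq_along(top$syn_pre)) {
    if (in_spiked[top$syn_pre[s]]) {
      state$synapses[[s]] <- on_pre_spike(state$synapses[[s]], t)
    }
  }
  out_spiked <- logical(length(top$outputs))
  for (o in seq_along(top$outputs)) {
    inc <- which(top$syn_post == o)
    i_o <- state$g_scale * sum(vapply(state$synapses[inc], `[[`, 0, "i_post"))
    j <- n_in + o
    r <- step_neuron(state$neurons[[j]], state$params, i_o)
    state$neurons[[j]] <- r$state
    out_spiked[o] <- r$spiked
    if (r$spiked) state$spike_log[[j]] <- c(state$spike_log[[j]], t)
  }
  for (s in seq_along(top$syn_pre)) {
    if (out_spiked[top$syn_post[s]]) {
      state$synapses[[s]] <- on_post_spike(state$synapses[[s]], t)
    }
  }
  state$synapses <- lapply(state$synapses, decay_step)
  state$t <- t + 1L
  state
}

#' Initialise a reference subnetwork state
#'
#' @param topology A [make_topology()] object.
#' @param g0 Initial weights.
#' @param config See [default_config()].
#' @return State list consumed by [step_subnetwork()].
#' @export
init_subnetwork_state <- function(topology, g0, config = default_config()) {
  params <- do.call(izhikevich_params, config$neuron)
  kernel <- do.call(stdp_kernel, config$kernel)
  rest <- resting_state(params)
  syn <- config$synapse
  tau_swd_ms <- ifelse(topology$syn_side == "ipsi",
                       syn$tau_swd_ms / syn$decay_ratio_ipsi, syn$tau_swd_ms)
  synapses <- lapply(seq_along(g0), function(s) {
    synapse(g = g0[s], kernel = kernel, g_min = syn$g_min, g_max = syn$g_max,
            eta = syn$eta, tau_scd_ms = syn$tau_scd_ms,
            tau_swd_ms = tau_swd_ms[s])
  })
  n <- length(topology$inputs) + length(topology$outputs)
  list(topology = topology, params = params,
       neurons = replicate(n, rest, simplify = FALSE),
       synapses = synapses, g_scale = syn$g_scale,
       spike_log = replicate(n, numeric(0), simplify = FALSE), t = 0L)
}

#' Run independent replicate subnetworks
#'
#' Runs `n` identically configured subnetworks on disjoint seeded noise
#' streams and aggregates their outcomes.  When every replicate shares the
#' same time grid (no predicate-terminated stage), the mean and sd weight
#' trajectories are also returned.
#'
#' @param n Number of replicates (>= 1; the hardware-style pool is 128).
#' @param topology,stages,g0,config,record_every_ms As [simulate_network()].
#' @param seeds Optional explicit seeds (must be distinct); derived from
#'   `base_seed` via [derive_seeds()] otherwise.
#' @param base_seed Base seed used when `seeds` is NULL.
#' @return List of class `replicate_runs`: `runs`, `g_final` (matrix
#'   n x n_syn), `mean_trajectory` (or NULL), `seeds`.
#' @export
run_replicates <- function(n, topology, stages, g0, config = default_config(),
                           seeds = NULL, base_seed = 1L,
                           record_every_ms = 1000L) {
  stopifnot(n >= 1)
  if (is.null(seeds)) seeds <- derive_seeds(base_seed, n)
  if (anyDuplicated(seeds)) stop("duplicate seeds across replicates")
  stopifnot(length(seeds) == n)
  runs <- lapply(seeds, function(s) {
    simulate_network(topology, stages, g0, config, seed = s,
                     record_every_ms = record_every_ms)
  })
  gf <- do.call(rbind, lapply(runs, `[[`, "g_final"))
  same_grid <- length(unique(vapply(runs, function(r) nrow(r$trajectory),
                                    0L))) == 1L
  mean_traj <- NULL
  if (same_grid) {
    labs <- topology$syn_labels
    arr <- vapply(runs, function(r) as.matrix(r$trajectory[, labs,
                                                           drop = FALSE]),
                  as.matrix(runs[[1]]$trajectory[, labs, drop = FALSE]))
    mean_traj <- data.frame(time_ms = runs[[1]]$trajectory$time_ms,
                            stage = runs[[1]]$trajectory$stage)
    for (j in seq_along(labs)) {
      m <- arr[, j, , drop = FALSE]
      dim(m) <- dim(m)[c(1, 3)]
      mean_traj[[paste0(labs[j], "_mean")]] <- rowMeans(m)
      mean_traj[[paste0(labs[j], "_sd")]] <- apply(m, 1, stats::sd)
    }
  }
  structure(list(runs = runs, g_final = gf, mean_trajectory = mean_traj,
                 seeds = seeds),
            class = "replicate_runs")
}
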