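#' BCM comparator state
#'
#' Rate-based Bienenstock–Cooper–Munro model of two retinal inputs onto one
#' cortical neuron: output `y = w . x`, weight rule
#' `dw_i/dt = x_i * y * (y - theta) / tau_w`, and the sliding modification
#' threshold `dtheta/dt = (y^2 - theta) / tau_theta`.  The equations are the
#' standard quadratic form from the BCM literature; parameters are in
#' arbitrary model time units and were fixed once to place the binocular
#' fixed point in a numerically comfortable range.
#'
#' An open eye sees a shared patterned stimulus (amplitude `amp`, presented
#' with probability `p_stim` per step) plus small independent jitter; a
#' deprived (sutured) eye sees only low-amplitude zero-mean noise of width
#' `noise_dep`.  With stimulus probability below one half, the sliding
#' threshold sits above the drive that uncorrelated noise can produce, so a
#' deprived eye is depressed — the rate-based analogue of uncorrelated-drive
#' LTD.
#'
#' @param w_left,w_right Initial synaptic weights (dimensionless, >= 0).
#' @param theta Initial modification threshold (> 0 after burn-in).
#' @param tau_w,tau_theta Weight and threshold time constants (model steps);
#'   the threshold must slide faster than the weights move.
#' @param amp Stimulus amplitude for an open eye.
#' @param p_stim Per-step stimulus probability (< 0.5).
#' @param noise_open Jitter width on an open eye's input.
#' @param noise_dep Noise width seen by a deprived eye.
#' @return An object of class `bcm_state`.
#' @export
bcm_state <- function(w_left = 0.3, w_right = 0.3, theta = 0.1,
                      tau_w = 400, tau_theta = 40, amp = 1,
                      p_stim = 0.3, noise_open = 0.25, noise_dep = 0.2) {
  stopifnot(w_left >= 0, w_right >= 0, theta > 0, tau_w > 0, tau_theta > 0,
            tau_theta < tau_w, p_stim > 0, p_stim < 0.5)
  structure(list(w = c(left = w_left, right = w_right), theta = theta,
                 tau_w = tau_w, tau_theta = tau_theta, amp = amp,
                 p_stim = p_stim, noise_open = noise_open,
                 noise_dep = noise_dep),
            class = "bcm_state")
}

bcm_conditions <- function() {
  c("normal", "MD", "BD", "reverse_suture", "binocular_recovery")
}

condition_eyes <- function(condition) {
  switch(condition,
         normal = c(left = "open", right = "open"),
         MD = c(left = "open", right = "deprived"),
         BD = c(left = "deprived", right = "deprived"),
         reverse_suture = c(left = "deprived", right = "open"),
         binocular_recovery = c(left = "open", right = "open"),
         stop("unknown condition: ", condition))
}

#' Integrate the BCM model under one rearing condition
#'
#' @param condition One of `"normal"`, `"MD"` (monocular deprivation of the
#'   right eye), `"BD"` (binocular deprivation), `"reverse_suture"`
#'   (right eye opened, left sutured), `"binocular_recovery"` (both open).
#' @param state A [bcm_state()] carrying the starting weights/threshold
#'   (e.g. the end state of a previous condition).
#' @param duration Number of unit time steps.
#' @param seed Seed for the stimulus/noise streams.
#' @param record_every Trajectory logging cadence (steps).
#' @return List with `trajectory` (data.frame: `t`, `w_left`, `w_right`,
#'   `theta`) and `state` (the end [bcm_state()]).
#' @export
run_bcm_condition <- function(condition, state = bcm_state(),
                              duration = 20000, seed = 1L,
                              record_every = 50L) {
  eyes <- condition_eyes(condition)
  u <- matrix(unif_stream(seed, 11L, 3L * duration), ncol = 3)
  w <- state$w
  th <- state$theta
  n_rec <- floor((duration - 1) / record_every) + 2L
  rec <- matrix(NA_real_, n_rec, 4)
  r <- 0L
  for (t in seq_len(duration)) {
    s <- state$amp * (u[t, 1] < state$p_stim)
    x <- numeric(2)
    for (i in 1:2) {
      x[i] <- if (eyes[i] == "open") {
        s + state$noise_open * (2 * u[t, i + 1] - 1)
      } else {
        state$noise_dep * (2 * u[t, i + 1] - 1)
      }
    }
    y <- sum(w * x)
    w <- pmax(w + x * y * (y - th) / state$tau_w, 0)
    th <- th + (y * y - th) / state$tau_theta
    if (!all(is.finite(w)) || !is.finite(th)) {
      stop("BCM integration diverged (non-finite weights)")
    }
    if (t %% record_every == 1L || t == duration) {
      r <- r + 1L
      rec[r, ] <- c(t, w, th)
    }
  }
  rec <- rec[seq_len(r), , drop = FALSE]
  state$w <- w
  state$theta <- th
  list(trajectory = data.frame(t = rec[, 1], w_left = rec[, 2],
                               w_right = rec[, 3], theta = rec[, 4]),
       state = state)
}

#' Run the STDP network under one rearing condition
#'
#' Maps the rearing condition onto the two-input/one-output spiking network:
#' an open eye is an active noise-driven input, a sutured eye is a blocked
#' input.  Initial weights default to the end state of the natural preceding
#' history (binocular for `normal`/`MD`/`BD`, post-deprivation asymmetric
#' for `reverse_suture` and `binocular_recovery`).
#'
#' @inheritParams run_bcm_condition
#' @param g0 Initial weights `c(wL, wR)`; `NULL` picks the condition's
#'   conventional starting point.
#' @param duration_s Simulated seconds (demo scale).
#' @param config A `run_config`.
#' @return A `subnetwork_run` (weights `wL`, `wR`).
#' @export
run_stdp_condition <- function(condition, g0 = NULL,
                               config = default_config(), duration_s = 1500,
                               seed = 1L) {
  eyes <- condition_eyes(condition)
  if (is.null(g0)) {
    g0 <- if (condition %in% c("reverse_suture", "binocular_recovery")) {
      c(wL = 0.9, wR = 0.2)
    } else {
      c(wL = 0.6, wR = 0.6)
    }
  }
  drive <- ifelse(eyes == "open", "active", "blocked")
  names(drive) <- c("L", "R")
  st <- list(stage_spec(condition, drive, duration_s = duration_s))
  simulate_network(make_topology("two_input_one_output"), st, g0, config,
                   seed = seed, record_every_ms = 1000L)
}

#' Side-by-side BCM vs STDP rearing-condition comparison
#'
#' Runs the five classic ocular-dominance conditions through both models.
#' `normal`, `MD` and `BD` start from the binocular state; `reverse_suture`
#' and `binocular_recovery` start from the monocularly deprived end state
#' (for BCM, the actual end state of its own MD run).  The headline contrast
#' is `binocular_recovery`: the BCM deprived-eye weight recovers toward the
#' binocular fixed point, while the STDP deprived-eye weight stays
#' suppressed by the open eye — the hysteresis that distinguishes the two
#' theories.
#'
#' @param config A `run_config` for the STDP side.
#' @param seed Base seed.
#' @param bcm_duration Steps per BCM condition.
#' @param stdp_duration_s Simulated seconds per STDP condition (demo scale).
#' @return List of class `bcm_comparison`: `trajectories` (long data.frame:
#'   `model`, `condition`, `t`, `w_open`, `w_deprived` in MD orientation)
#'   and `summary` (final weights and deprived/open ratio per model and
#'   condition).
#' @export
bcm_compare <- function(config = default_config(), seed = 1L,
                        bcm_duration = 20000, stdp_duration_s = 1500) {
  conditions <- bcm_conditions()
  seeds <- derive_seeds(seed, 2L * length(conditions))
  # BCM: chain MD so that recovery/reverse start from the deprived state
  bin0 <- bcm_state()
  norm <- run_bcm_condition("normal", bin0, bcm_duration, seeds[1])
  md <- run_bcm_condition("MD", norm$state, bcm_duration, seeds[2])
  bcm_runs <- list(
    normal = norm,
    MD = md,
    BD = run_bcm_condition("BD", norm$state, bcm_duration, seeds[3]),
    reverse_suture = run_bcm_condition("reverse_suture", md$state,
                                       bcm_duration, seeds[4]),
    binocular_recovery = run_bcm_condition("binocular_recovery", md$state,
                                           bcm_duration, seeds[5]))
  stdp_runs <- lapply(seq_along(conditions), function(i) {
    run_stdp_condition(conditions[i], config = config,
                       duration_s = stdp_duration_s, seed = seeds[5 + i])
  })
  names(stdp_runs) <- conditions

  rows <- list()
  summ <- list()
  for (cond in conditions) {
    b <- bcm_runs[[cond]]$trajectory
    rows[[paste0("b", cond)]] <- data.frame(
      model = "BCM", condition = cond, t = b$t,
      w_open = b$w_left, w_deprived = b$w_right)
    s <- stdp_runs[[cond]]$trajectory
    rows[[paste0("s", cond)]] <- data.frame(
      model = "STDP", condition = cond, t = s$time_ms / 1000,
      w_open = s$wL, w_deprived = s$wR)
    bw <- bcm_runs[[cond]]$state$w
    sw <- stdp_runs[[cond]]$g_final
    summ[[paste0("b", cond)]] <- data.frame(
      model = "BCM", condition = cond, w_open = bw[["left"]],
      w_deprived = bw[["right"]],
      ratio = bw[["right"]] / max(bw[["left"]], 1e-12))
    summ[[paste0("s", cond)]] <- data.frame(
      model = "STDP", condition = cond, w_open = sw[["wL"]],
      w_deprived = sw[["wR"]],
      ratio = sw[["wR"]] / max(sw[["wL"]], 1e-12))
  }
  structure(list(trajectories = do.call(rbind, c(rows, make.row.names = FALSE)),
                 summary = do.call(rbind, c(summ, make.row.names = FALSE)),
                 bcm_runs = bcm_runs, stdp_runs = stdp_runs),
            class = "bcm_comparison")
}

#' @export
print.bcm_comparison <- function(x, ...) {
  cat("<bcm_comparison> final weights by condition:\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
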