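test_that("compiled engine matches the pure-R reference step-for-step", {
  cfg <- demo_cfg()
  top <- make_topology("two_input_one_output")
  g0 <- c(wL = 0.6, wR = 0.4)
  n_steps <- 3000
  st <- list(stage_spec("s", c(L = "active", R = "active"),
                        duration_s = n_steps / 1000))
  eng <- simulate_network(top, st, g0, cfg, seed = 9, record_every_ms = 1L,
                          record_spikes = TRUE)

  # reference: same seeded streams, same per-step event order, in pure R
  state <- init_subnetwork_state(top, g0, cfg)
  uL <- unif_stream(9, 0, n_steps)
  uR <- unif_stream(9, 1, n_steps)
  lo <- cfg$drive$lo_frac * cfg$drive$i_th
  hi <- cfg$drive$hi_frac * cfg$drive$i_th
  gL <- gR <- numeric(n_steps)
  for (t in seq_len(n_steps)) {
    cur <- c(lo + (hi - lo) * uL[t], lo + (hi - lo) * uR[t])
    state <- step_subnetwork(state, cur)
    gL[t] <- state$synapses[[1]]$g
    gR[t] <- state$synapses[[2]]$g
  }

  expect_equal(state$synapses[[1]]$g, eng$g_final[["wL"]], tolerance = 1e-10)
  expect_equal(state$synapses[[2]]$g, eng$g_final[["wR"]], tolerance = 1e-10)
  expect_identical(state$spike_log[[1]], eng$spikes$L)
  expect_identical(state$spike_log[[2]], eng$spikes$R)
  expect_identical(state$spike_log[[3]], eng$spikes$O)
  # weight paths agree everywhere, not just at the end (engine time t is
  # the state after the (t + 1)-th completed step)
  tr <- eng$trajectory[eng$trajectory$time_ms < n_steps, ]
  expect_equal(gL[tr$time_ms + 1], tr$wL, tolerance = 1e-10)
  expect_equal(gR[tr$time_ms + 1], tr$wR, tolerance = 1e-10)
})

test_that("with all drives blocked the network is silent and weights decay", {
  cfg <- demo_cfg()
  top <- make_topology("cst_2x2")
  g0 <- c(w0 = 0.3, w1 = 0.6, w2 = 0.6, w3 = 0.3)
  T_s <- 200
  st <- list(stage_spec("off", c(R = "blocked", L = "blocked"),
                        duration_s = T_s))
  r <- simulate_network(top, st, g0, cfg, seed = 1, record_spikes = TRUE)
  expect_true(all(r$spike_counts == 0))
  tau_c <- cfg$synapse$tau_swd_ms
  tau_i <- tau_c / cfg$synapse$decay_ratio_ipsi
  expected <- g0 * exp(-T_s * 1000 / c(tau_i, tau_c, tau_c, tau_i))
  expect_equal(unname(r$g_final), unname(expected), tolerance = 1e-9)
})

test_that("a blocked hemisphere's synapses change by decay only", {
  cfg <- demo_cfg()
  top <- make_topology("cst_2x2")
  g0 <- c(w0 = 0.3, w1 = 0.6, w2 = 0.6, w3 = 0.3)
  T_s <- 120
  st <- list(stage_spec("uni", c(R = "blocked", L = "active"),
                        duration_s = T_s))
  r <- simulate_network(top, st, g0, cfg, seed = 4, record_spikes = TRUE)
  # R never fires; its synapses w0 (ipsi) and w2 (contra) follow the pure
  # decay law exactly even though their postsynaptic neurons are active
  tau_c <- cfg$synapse$tau_swd_ms
  tau_i <- tau_c / cfg$synapse$decay_ratio_ipsi
  expect_identical(length(r$spikes$R), 0L)
  expect_equal(r$g_final[["w0"]], 0.3 * exp(-T_s * 1000 / tau_i),
               tolerance = 1e-9)
  expect_equal(r$g_final[["w2"]], 0.6 * exp(-T_s * 1000 / tau_c),
               tolerance = 1e-9)
  # while the active hemisphere keeps its output neurons firing
  expect_gt(length(r$spikes$L), 0)
  expect_gt(length(r$spikes$OR), 0)
})

test_that("output neurons receive no direct noise", {
  cfg <- demo_cfg()
  top <- make_topology("two_input_one_output")
  st <- list(stage_spec("s", c(L = "active", R = "active"), duration_s = 60))
  r <- simulate_network(top, st, c(wL = 0, wR = 0), cfg, seed = 2,
                        record_spikes = TRUE)
  # with zero weights all output activity would have to come from direct
  # drive; there is none
  expect_identical(length(r$spikes$O), 0L)
  expect_gt(length(r$spikes$L), 800)
})

test_that("replicates use disjoint seeds and aggregate order-independently", {
  cfg <- demo_cfg()
  top <- make_topology("two_input_one_output")
  st <- list(stage_spec("s", c(L = "active", R = "active"), duration_s = 30))
  g0 <- c(wL = 0.6, wR = 0.3)
  one <- simulate_network(top, st, g0, cfg, seed = 101L,
                          record_every_ms = 1000L)
  reps <- run_replicates(2, top, st, g0, cfg, seeds = c(101L, 202L))
  expect_equal(reps$runs[[1]]$g_final, one$g_final)
  swapped <- run_replicates(2, top, st, g0, cfg, seeds = c(202L, 101L))
  expect_equal(reps$g_final[order(reps$seeds), ],
               swapped$g_final[order(swapped$seeds), ])
  expect_error(run_replicates(2, top, st, g0, cfg, seeds = c(5L, 5L)),
               "duplicate")
  expect_true(all(!duplicated(derive_seeds(1, 128))))
  # degenerate aggregation: n = 1 equals a plain run
  r1 <- run_replicates(1, top, st, g0, cfg, seeds = 101L)
  expect_equal(r1$g_final[1, ], one$g_final)
})

test_that("replicate consensus matches the single-run competition outcome", {
  # frozen regression: at these seeds, every one of 16 replicates of the
  # left-predominant competition resolves to left dominance, as does the
  # corresponding single run
  cfg <- demo_cfg()
  ec <- make_example_case("a", cfg)
  reps <- run_replicates(16, ec$topology, ec$stages, ec$g0, cfg,
                         base_seed = 42L, record_every_ms = 1e6L)
  left_wins <- reps$g_final[, "wL"] > 1.1 * reps$g_final[, "wR"]
  expect_gte(sum(left_wins), 14)
  single <- run_example_case("a", cfg, seed = 42L, record_every_ms = 1e6L)
  expect_true(single$g_final[["wL"]] > 1.1 * single$g_final[["wR"]])
})

test_that("an unreachable stage predicate fails with the partial trajectory", {
  cfg <- demo_cfg()
  st <- list(stage_spec("hopeless", c(R = "blocked", L = "blocked"),
                        terminate_when = "contra_dominant", margin = 0.1,
                        cap_s = 20))
  err <- tryCatch(
    simulate_network(make_topology("cst_2x2"), st,
                     c(w0 = 0.5, w1 = 0.5, w2 = 0.5, w3 = 0.5), cfg,
                     seed = 1),
    synapcomp_predicate_error = function(e) e)
  expect_s3_class(err, "synapcomp_predicate_error")
  expect_s3_class(err$run$trajectory, "data.frame")
  expect_gt(nrow(err$run$trajectory), 0)
})
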