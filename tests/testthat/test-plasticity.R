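test_that("kernel matches its closed form at reference lags", {
  k <- stdp_kernel()
  # 1.03 * exp(-10/14) and -0.51 * exp(-10/34), frozen from direct evaluation
  expect_equal(evaluate_kernel(k, 10), 0.5042279, tolerance = 1e-6)
  expect_equal(evaluate_kernel(k, -10), -0.3800463, tolerance = 1e-6)
  # zero outside the pairing window and at the excluded zero lag
  expect_identical(evaluate_kernel(k, c(65, -65, 0)), c(0, 0, 0))
  # the boundary lag is included
  expect_gt(evaluate_kernel(k, 64), 0)
  expect_lt(evaluate_kernel(k, -64), 0)
  # sign structure
  expect_true(all(evaluate_kernel(k, 1:64) > 0))
  expect_true(all(evaluate_kernel(k, -(1:64)) < 0))
})

test_that("presynaptic events deliver current and apply buffered LTD", {
  k <- stdp_kernel()
  syn <- synapse(g = 0.5, kernel = k, g_min = -1e9, g_max = 1e9)
  # no buffered post spikes: pure delivery
  s1 <- on_pre_spike(syn, t = 100)
  expect_equal(s1$i_post, 0.5)
  expect_equal(s1$g, 0.5)
  # one post spike 10 ms earlier: single-pair LTD
  syn2 <- on_post_spike(syn, t = 90)
  s2 <- on_pre_spike(syn2, t = 100)
  expect_equal(s2$g, 0.5 - 0.3800463, tolerance = 1e-6)
  # two post spikes, lags 10 and 20 ms: all-to-all sum
  syn3 <- on_post_spike(on_post_spike(syn, t = 80), t = 90)
  s3 <- on_pre_spike(syn3, t = 100)
  expect_equal(s3$g, 0.5 + evaluate_kernel(k, -10) + evaluate_kernel(k, -20),
               tolerance = 1e-12)
})

test_that("postsynaptic events apply buffered LTP including the window edge", {
  k <- stdp_kernel()
  syn <- synapse(g = 0.1, kernel = k, g_min = -1e9, g_max = 1e9)
  expect_equal(on_post_spike(syn, 50)$g, 0.1) # empty pre buffer
  s <- on_pre_spike(syn, t = 100)
  expect_equal(on_post_spike(s, t = 110)$g, 0.1 + 0.5042279,
               tolerance = 1e-6)
  # pre spikes 5 and 64 ms before the post spike both count
  s2 <- on_pre_spike(on_pre_spike(syn, t = 36), t = 95)
  expect_equal(on_post_spike(s2, t = 100)$g,
               0.1 + 1.03 * exp(-5 / 14) + 1.03 * exp(-64 / 14),
               tolerance = 1e-12)
})

test_that("decay operators are exact exponentials, step-count-exact", {
  syn <- synapse(g = 1, g_min = 0, g_max = 1)
  syn$i_post <- 1
  for (i in 1:15) syn <- decay_step(syn)
  expect_equal(syn$i_post, exp(-1), tolerance = 1e-12)
  # weight decay over one full time constant (engine decay operator,
  # repeated single steps) agrees with exp(-t/tau) over 1e6 steps
  tau <- 35 * 3600 * 1000
  expect_equal(cpp_decay_n(1, tau, 1e6), exp(-1e6 / tau), tolerance = 1e-12)
  expect_equal(cpp_decay_n(0, tau, 1000), 0)
  # R-level operator agrees with the engine operator
  syn2 <- synapse(g = 0.8)
  for (i in 1:1000) syn2 <- decay_step(syn2)
  expect_equal(syn2$g, cpp_decay_n(0.8, 35 * 3600 * 1000, 1000),
               tolerance = 1e-12)
})

test_that("event-driven updates equal the brute-force pair sum on random scripts", {
  k <- stdp_kernel()
  set.seed(42)
  for (rep in 1:100) {
    pre <- random_script(rep)
    post <- random_script(rep + 1000)
    ev <- rbind(data.frame(t = pre, type = "pre"),
                data.frame(t = post, type = "post"))
    ev <- ev[order(ev$t), ]
    syn <- synapse(g = 0, kernel = k, g_min = -1e9, g_max = 1e9)
    for (i in seq_len(nrow(ev))) {
      syn <- if (ev$type[i] == "pre") on_pre_spike(syn, ev$t[i])
             else on_post_spike(syn, ev$t[i])
    }
    expect_equal(syn$g, brute_force_pairing(k, pre, post), tolerance = 1e-10)
  }
})

test_that("weights stay inside their bounds under arbitrary spike sequences", {
  k <- stdp_kernel()
  set.seed(7)
  for (rep in 1:20) {
    syn <- synapse(g = runif(1), kernel = k, g_min = 0, g_max = 1)
    times <- sort(sample.int(3000, 200))
    for (t in times) {
      syn <- if (runif(1) < 0.5) on_pre_spike(syn, t) else on_post_spike(syn, t)
      expect_gte(syn$g, 0)
      expect_lte(syn$g, 1)
    }
  }
})

test_that("same-step pre and post events commute (zero-lag pairs excluded)", {
  k <- stdp_kernel()
  base <- synapse(g = 0.5, kernel = k, g_min = -1e9, g_max = 1e9)
  base <- on_pre_spike(base, 10)
  base <- on_post_spike(base, 40)
  a <- on_post_spike(on_pre_spike(base, 100), 100)
  b <- on_pre_spike(on_post_spike(base, 100), 100)
  expect_equal(a$g, b$g, tolerance = 1e-14)
})

test_that("spike buffers never retain spikes older than the window", {
  syn <- synapse(g = 0.5)
  syn <- on_pre_spike(syn, 10)
  expect_identical(syn$pre_buffer, 10)
  syn <- on_pre_spike(syn, 100)
  expect_identical(syn$pre_buffer, 100)  # 10 is outside the 64 ms window
  expect_error(on_pre_spike(syn, 60), "out-of-order")
})

test_that("the expected per-pair update under uniform random lags is depressing", {
  k <- stdp_kernel()
  # closed-form area of the windowed kernel over [-window, window]
  ltp_area <- k$a_plus * k$tau_plus_ms * (1 - exp(-k$window_ms / k$tau_plus_ms))
  ltd_area <- k$a_minus * k$tau_minus_ms *
    (1 - exp(-k$window_ms / k$tau_minus_ms))
  expect_lt(ltp_area + ltd_area, 0)
  # empirical mean over >= 1e4 random pairs against the area oracle
  set.seed(1)
  lags <- runif(2e5, -k$window_ms, k$window_ms)
  vals <- evaluate_kernel(k, lags)
  emp <- mean(vals)
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(emp, 0)
  expect_lt(abs(emp - (ltp_area + ltd_area) / (2 * k$window_ms)), 3 * se)
})
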