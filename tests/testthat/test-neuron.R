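test_that("subthreshold dynamics settle on the analytic resting point", {
  p <- izhikevich_params()
  # stable root of 0.04 v^2 + 4.8 v + 140 = 0 is v = -70, with u = b v = -14
  rest <- resting_state(p)
  expect_equal(rest$v, -70)
  expect_equal(rest$u, -14)

  # the fixed point is invariant under the map
  r <- step_neuron(rest, p, i_in = 0)
  expect_false(r$spiked)
  expect_equal(r$state$v, -70, tolerance = 1e-12)
  expect_equal(r$state$u, -14, tolerance = 1e-12)

  # and attracts a perturbed state to well below 1e-6
  s <- neuron_state(v = -66, u = -13)
  for (i in 1:3000) s <- step_neuron(s, p, 0)$state
  expect_lt(abs(s$v + 70), 1e-6)
  expect_lt(abs(s$u + 14), 1e-6)
})

test_that("spike reset lands on c and adds exactly d to the recovery term", {
  p <- izhikevich_params()
  s <- neuron_state(v = 29, u = -10)
  r <- step_neuron(s, p, i_in = 50)
  expect_true(r$spiked)
  expect_identical(r$state$v, p$c)
  # u after the reset equals the Euler-updated u plus d
  u_euler <- s$u + p$a * (p$b * s$v - s$u)
  expect_equal(r$state$u, u_euler + p$d, tolerance = 1e-12)
})

test_that("constant suprathreshold current produces repetitive spiking", {
  p <- izhikevich_params()
  s <- neuron_state(-70, -14)
  n_spikes <- 0
  for (i in 1:1000) {
    r <- step_neuron(s, p, i_in = 10)
    s <- r$state
    n_spikes <- n_spikes + r$spiked
  }
  expect_gte(n_spikes, 2)
})

test_that("current below rheobase leaves a neuron at equilibrium silent", {
  p <- izhikevich_params()
  s <- resting_state(p, i_in = 3.5)
  fired <- FALSE
  for (i in 1:5000) {
    r <- step_neuron(s, p, i_in = 3.5)
    s <- r$state
    fired <- fired || r$spiked
  }
  expect_false(fired)
})

test_that("rheobase matches the equilibrium-discriminant oracle", {
  # discriminant of 0.04 v^2 + (5 - b) v + 140 + I on the u-nullcline
  # vanishes at I = ((5 - b)^2 - 0.16 * 140) / 0.16 = 4.0 for b = 0.2
  expect_equal(rheobase(), 4.0, tolerance = 1e-6)
  # a and d do not enter the equilibrium equation
  expect_equal(rheobase(izhikevich_params(a = 0.05, d = 2)), 4.0,
               tolerance = 1e-6)
  # and the bisection tracks the analytic value for other b
  b <- 0.25
  expect_equal(rheobase(izhikevich_params(b = b)),
               ((5 - b)^2 - 0.16 * 140) / 0.16, tolerance = 1e-6)
})

test_that("identical state and input sequence give bit-identical paths", {
  p <- izhikevich_params()
  i_seq <- sample_current(drive_config(seed = 7), 1:500)
  run <- function() {
    s <- neuron_state(-70, -14)
    v <- numeric(500)
    for (i in seq_along(i_seq)) {
      s <- step_neuron(s, p, i_seq[i])$state
      v[i] <- s$v
    }
    v
  }
  expect_identical(run(), run())
})

test_that("non-finite state or input is a hard failure", {
  p <- izhikevich_params()
  expect_error(step_neuron(neuron_state(), p, i_in = NaN), "non-finite")
  expect_error(step_neuron(list(v = Inf, u = 0), p, 0), "non-finite")
  expect_error(step_neuron(neuron_state(), p, 0, dt = 0.5), "1 ms")
})
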