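# Shared fixtures: a demo-scale config and a slow-plasticity variant used to
# isolate decay and pairing effects in short deterministic runs.
demo_cfg <- function() default_config()

frozen_cfg <- function() {
  cfg <- default_config()
  cfg$synapse$eta <- 0
  cfg
}

# random Poisson-like spike scripts on a 1 ms grid (distinct sorted times)
random_script <- function(seed, duration_ms = 2000, rate_hz = 20) {
  n <- stats::rpois(1, rate_hz * duration_ms / 1000)
  sort(sample.int(duration_ms, min(n, duration_ms)))
}

# brute-force all-to-all pairing over a finite window: every (pre, post)
# pair with 0 < |lag| <= window contributes kernel(lag)
brute_force_pairing <- function(kernel, pre, post) {
  s <- 0
  for (tp in pre) {
    d <- post - tp
    d <- d[d != 0 & abs(d) <= kernel$window_ms]
    s <- s + sum(evaluate_kernel(kernel, d))
  }
  s
}
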