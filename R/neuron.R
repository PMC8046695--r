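#' Izhikevich neuron parameters
#'
#' Parameter set for the two-variable quadratic integrate-and-fire neuron
#' `v' = 0.04 v^2 + 5 v + 140 - u + I`, `u' = a (b v - u)`, with the reset
#' `v <- c, u <- u + d` applied whenever `v` reaches `v_peak`.  Defaults are
#' the canonical regular-spiking (RS) cortical cell: `a = 0.02`, `b = 0.2`,
#' `c = -65` mV, `d = 8`, `v_peak = 30` mV.
#'
#' @param a Recovery time scale (1/ms in model units); must be positive.
#' @param b Recovery sensitivity to `v`.
#' @param c Post-spike reset potential (mV).
#' @param d Post-spike recovery increment; must be positive.
#' @param v_peak Spike cutoff (mV).
#' @return An object of class `izhikevich_params`.
#' @export
izhikevich_params <- function(a = 0.02, b = 0.2, c = -65, d = 8, v_peak = 30) {
  stopifnot(a > 0, d > 0, is.finite(c), is.finite(b), is.finite(v_peak))
  structure(list(a = a, b = b, c = c, d = d, v_peak = v_peak),
            class = "izhikevich_params")
}

#' Neuron state
#'
#' Membrane potential `v` (mV) and recovery variable `u` (model units).
#' The default is the RS resting point (-70, -14).
#'
#' @param v Membrane potential (mV).
#' @param u Recovery variable.
#' @return An object of class `neuron_state`.
#' @export
neuron_state <- function(v = -70, u = -14) {
  stopifnot(is.finite(v), is.finite(u))
  structure(list(v = v, u = u), class = "neuron_state")
}

#' Resting equilibrium of the subthreshold dynamics
#'
#' Solves `0.04 v^2 + (5 - b) v + 140 + I = 0` on the recovery nullcline
#' `u = b v` and returns the stable root (the more hyperpolarised one).
#'
#' @param params An [izhikevich_params()] object.
#' @param i_in Constant input current (model units).
#' @return A [neuron_state()] at the stable equilibrium, or `NULL` when no
#'   equilibrium exists (the neuron fires indefinitely at this current).
#' @export
resting_state <- function(params = izhikevich_params(), i_in = 0) {
  disc <- (5 - params$b)^2 - 4 * 0.04 * (140 + i_in)
  if (disc < 0) return(NULL)
  v <- (-(5 - params$b) - sqrt(disc)) / (2 * 0.04)
  neuron_state(v = v, u = params$b * v)
}

#' One 1-ms Euler step of an Izhikevich neuron
#'
#' A single forward-Euler update of `(v, u)` with both derivatives evaluated
#' at the pre-step state, followed by the spike test `v >= v_peak` and, when
#' it fires, the reset `v <- c`, `u <- u + d` applied within the same step.
#' The spike timestamp is the index of the step in which the reset occurred.
#'
#' @param state A [neuron_state()].
#' @param params An [izhikevich_params()].
#' @param i_in Input current for this step (model units).
#' @param dt Step size in ms; the model is defined at `dt = 1`.
#' @return List with elements `state` (the updated [neuron_state()]) and
#'   `spiked` (logical).
#' @export
step_neuron <- function(state, params, i_in, dt = 1) {
  if (!identical(as.numeric(dt), 1)) {
    stop("the model is defined at a fixed 1 ms resolution (dt = 1)")
  }
  if (!is.finite(state$v) || !is.finite(state$u) || !is.finite(i_in)) {
    stop("non-finite neuron state or input current (divergent configuration)")
  }
  v <- state$v + (0.04 * state$v^2 + 5 * state$v + 140 - state$u + i_in)
  u <- state$u + params$a * (params$b * state$v - state$u)
  if (!is.finite(v) || !is.finite(u)) {
    stop("neuron state became non-finite (divergent configuration)")
  }
  spiked <- v >= params$v_peak
  if (spiked) {
    v <- params$c
    u <- u + params$d
  }
  list(state = neuron_state(v, u), spiked = spiked)
}

#' Rheobase of the Izhikevich neuron
#'
#' The minimal constant current above which the subthreshold dynamics have no
#' resting equilibrium, so firing is sustained.  Located by bisection on
#' equilibrium existence (the sign of the discriminant of
#' `0.04 v^2 + (5 - b) v + 140 + I = 0`); for the RS defaults this is exactly
#' 4.0 model units.  Note that the 1-ms discrete-time map can escape the
#' shrinking basin of attraction somewhat below this value (see the methods
#' vignette), which is why the noise drive is calibrated against the target
#' firing rate rather than against the rheobase.
#'
#' @param params An [izhikevich_params()].
#' @param upper Upper bracket for the bisection (model units).
#' @param tol Bisection tolerance.
#' @return Rheobase current in model units.
#' @export
rheobase <- function(params = izhikevich_params(), upper = 1000, tol = 1e-10) {
  has_eq <- function(i) (5 - params$b)^2 - 4 * 0.04 * (140 + i) >= 0
  lo <- -140
  hi <- upper
  if (!has_eq(lo) || has_eq(hi)) {
    stop("rheobase bisection could not bracket the equilibrium boundary ",
         "(pathological parameters)")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (has_eq(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
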