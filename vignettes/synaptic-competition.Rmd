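---
title: "Synaptic competition, hysteresis and constraint-induced reversal: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synaptic competition, hysteresis and constraint-induced reversal: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model equations and their assumptions, the parameters that matter and
why their defaults are what they are, the numerical choices, and what the
simulated results do and do not show about real nervous systems.

## The model

### Neurons

All cells are regular-spiking (RS) Izhikevich neurons,

$$v' = 0.04v^2 + 5v + 140 - u + I,\qquad u' = a(bv - u),$$

with the reset $v \leftarrow c$, $u \leftarrow u + d$ whenever $v$ reaches
$30$ mV, and $a = 0.02$, $b = 0.2$, $c = -65$ mV, $d = 8$. The reset
potential is the canonical RS value of $-65$ mV; a configuration field
allows any other value. Integration is a single forward-Euler step at the
model's native 1 ms resolution, with both derivatives evaluated at the
pre-step state and the spike test applied after the update (`step_neuron()`).
No sub-stepping is used: the 1 ms map *is* the model, not an approximation
to be refined, and all calibrations below refer to it.

Two properties of this map matter later and are easy to miss:

* Its **rheobase** — the smallest constant current with no resting
  equilibrium — is exactly 4.0 model units for the RS parameters
  (`rheobase()`, located by bisection on the equilibrium discriminant).
* The discrete map is **more excitable than the flow**: started from the
  zero-current rest point $(-70, -14)$, the 1 ms Euler transient can escape
  the shrinking basin of attraction at currents somewhat below rheobase.
  Subthreshold-silence statements therefore hold for a neuron started *at
  the equilibrium of its own holding current*, which is how the tests state
  them.

### Synapses

Synapses are additive, all-to-all STDP with the asymmetric exponential
kernel

$$f(\Delta t) = \begin{cases} A_+\,e^{-\Delta t/\tau_+} & 0 < \Delta t \le W\\
A_-\,e^{-|\Delta t|/\tau_-} & -W \le \Delta t < 0 \end{cases}$$

with $\Delta t = t_{post}-t_{pre}$, $A_+ = 1.03$, $A_- = -0.51$,
$\tau_+ = 14$ ms, $\tau_- = 34$ ms and pairing window $W = 64$ ms. Every
pre/post pair inside the window contributes; a pair at exactly the window
edge counts, simultaneous spikes ($\Delta t = 0$, where the kernel is
discontinuous) contribute nothing by convention. Updates are purely
additive — $g \mathrel{+}= \eta \sum f$ — and the weight is clamped to
$[g_{min}, g_{max}] = [0, 1]$ after every event. A presynaptic spike also
delivers current: the synapse's postsynaptic current jumps by $g$ and then
decays exponentially with $\tau_{SCD} = 15$ ms; the weight itself decays
with $\tau_{SWD} = 35$ h.

One consequence of the finite window deserves emphasis. Over the *infinite*
lag axis the depression area $|A_-|\tau_- = 17.3$ exceeds the potentiation
area $A_+\tau_+ = 14.4$, so uncorrelated spike pairs are net-depressing.
The 64 ms window, however, truncates 15% of the LTD lobe but only 1% of
the LTP lobe, leaving a windowed area of only $\approx -0.43$ ms — the
expected update per uncorrelated pair is still negative (the tests assert
this against the closed-form area), but it is *weak*. In this
parameterisation, the decisive force pulling an uncorrelated synapse down
is therefore the combination of near-zero pairing drift with the always-on
weight decay, while a causally driving synapse enjoys strong timing-locked
potentiation. Competition survives the truncation; it just flows through
decay rather than through raw LTD mass.

### Drive

Input-layer neurons are driven by i.i.d. uniform current on
$[0.6, 1.7]\times I_{th}$, redrawn every 1 ms from per-neuron seeded
streams; a blocked input receives exactly zero. The two hemispheres' trains
are statistically independent (flat cross-correlogram, asserted in the
tests).

The scale $I_{th}$ ("threshold current") has no printed value in the source
material, which instead pins the *outcome*: a mean input firing rate of
15 Hz. The natural first candidate, the analytic rheobase 4.0, under-drives
the 1 ms map — it yields ≈ 9.8 Hz and 102 ms intervals. The package
therefore treats the 15 Hz operating point as the binding constraint and
calibrates $I_{th}$ against it by bisection (`calibrate_i_th()`), freezing
the default at **5.81 model units**, which reproduces 15.0 Hz and a
66.7 ms mean ISI. The dispersion of the resulting train (ISI sd ≈ 6.5 ms,
CV ≈ 0.097) is an emergent property with no free knob left; across every
integration variant we examined (simultaneous Euler, the two-half-step
update, either recovery-update order, $I_{th}$ from 4 to 8) the CV never
fell below ≈ 0.096. Reference dispersion values quoted for comparable
hardware (sd 4.88 ms, CV 0.0725) evidently depend on noise-generation
details that are not part of the printed model, and the package makes no
attempt to chase them.

### Network and scheduler

The corticospinal circuit is 2×2: cortical inputs R and L, spinal outputs
OR and OL, with `w0 = R→OR` and `w3 = L→OL` ipsilateral and `w1 = L→OR`,
`w2 = R→OL` contralateral. Ipsilateral weights decay 1.5× faster
($\tau_{SWD}/1.5$), encoding the developmental advantage of the crossed
projection. Each 1 ms step proceeds: sample drives → step inputs → apply
presynaptic events (LTD pairing, current delivery) → step outputs on
`g_scale ×` the summed synaptic currents → apply postsynaptic events (LTP
pairing) → decay currents and weights. Delivery is within-step, so causal
pre-to-post lags are ≥ 1 ms and positive, as STDP requires; outputs receive
no direct noise. Spinal transmission delays and gray-matter termination
patterns are not modelled. A pure-R reference (`step_subnetwork()`)
reproduces the compiled engine's trajectories to $10^{-10}$ and is part of
the test suite.

## Time scales and the demo preset

The interesting dynamics span milliseconds (spikes) to days (weight decay).
The `demo` preset divides $\tau_{SWD}$ and all preset stage durations by a
common factor of 100, leaving every millisecond-scale constant untouched,
so that the rate *ratios* governing the competition (causal LTP per second
: pairing drift per second : decay per second) are preserved while the full
five-stage phenomenology plays out in a few thousand simulated seconds.
The `paper` preset keeps the 35 h constant and day-scale stages (the
five-stage schedule then spans roughly 19 simulated days); it is available
behind `default_config("paper")`. All shipped tests run demo scale; the
exact absolute time axis of multi-day hardware runs is not reproducible
anyway because per-stage durations were never printed, so the package
treats stage lengths as design parameters (below) and asserts the
phenomenology, not the axis.

## How the competition actually works here

With near-periodic 15 Hz input trains, a synapse strong enough to fire its
target within a few milliseconds of each presynaptic spike collects
≈ $15 \cdot A_+ e^{-2/\tau_+}\,\eta$ of potentiation per second — far more
than its decay — and saturates at $g_{max}$. A synapse too weak to trigger
the (adaptation-elevated) target collects only the weak uncorrelated
pairing drift and loses to its own decay. The boundary between the two
regimes is set by the spike-triggering threshold of the quadratic neuron,
which is itself raised by the recovery variable $u$ when the target is
already being driven by a competitor ($d = 8$ per spike, decaying with
$1/a = 50$ ms): the busier the output, the stronger a challenger must be.
This threshold nonlinearity, not the kernel's area asymmetry, is what makes
the outcome depend on initial conditions (winner-take-all), makes it stick
(hysteresis: a weakened projection faces a busy target), and makes
constraint work (blocking the winner silences the target, drops its
threshold back to rest, and lets the weak synapse grow on pure causal LTP).

Two coupled gains position the model in that regime and are the only truly
free parameters:

| parameter | default | units | role |
|---|---|---|---|
| `g_scale` | 50 | current units per unit weight | converts a weight into the postsynaptic current jump; sets which weights can fire a quiet (≳ 0.12) vs a busy (≳ 0.45–0.6) target |
| `eta` | 5e-5 | weight units per kernel unit | additive plasticity step; sets growth to ≈ 5–7×10⁻⁴ s⁻¹ for a driving synapse, safely above decay (≤ 7.9×10⁻⁴ s⁻¹ at $g = 1$) for winners and below it for losers |

They were fixed once, by mapping the net drift field of a
winner/challenger pair over `(g_scale, eta)` on demo scale, and all
protocols share them. With these values, a weight at the upper bound is
retained (its causal LTP exceeds its decay), a challenger below ≈ 0.45
cannot break into a busy target, and a weight as low as ≈ 0.12 can still
revive a silent one — the corridor the therapy protocol travels.

Stage durations (demo seconds) are likewise package design choices,
calibrated to the decay clock $\tau_{SWD}^{demo} = 1260$ s: healthy
baseline 600 (long enough for contralateral saturation), unilateral
inactivation 1800 (the blocked side's contralateral weight must fall below
the busy-target threshold ≈ 0.45 for the deficit to stick, yet stay above
the quiet-target threshold ≈ 0.12 so the therapy can still act), stuck
bilateral 600, reverse inactivation predicate-terminated (cap 6000), final
bilateral 900. The reverse-inactivation stage ends at the first step where
*both* contralateral weights exceed $(1 + m)$ times their ipsilateral
competitors, $m = 0.1$ — "slightly stronger" — after which the resumed
competition itself completes the restoration; its persistence is asserted
as a strictly growing dominance margin. The example competition cases use
initial weights 0.6/0.3 (predominant) and 0.8/0.2 (considerably stronger),
with a 1500 s blockade in the switching case — long enough
($> \tau_{SWD}\ln(0.6/0.45)$ plus margin) to pull the formerly dominant
side under the busy-target threshold before bilateral drive resumes.

## The BCM comparator

The source material compares the spiking model against the classic
rate-based sliding-threshold rule but does not print those equations; the
package implements the standard quadratic form from the BCM literature,

$$\dot w_i = x_i\,y\,(y-\theta)/\tau_w,\qquad
  \dot\theta = (y^2-\theta)/\tau_\theta,\qquad y = \mathbf{w}\cdot\mathbf{x},$$

with weights clamped at zero and $\tau_\theta \ll \tau_w$. An open eye sees
a shared binary stimulus (amplitude 1, probability $p = 0.3$ per step) plus
independent jitter; a sutured eye sees only low-amplitude zero-mean noise.
Two structural facts give the five rearing regimes without further tuning:
with $p < 1/2$ the monocular fixed point satisfies
$2\bar y < \theta$, so a noise-only (deprived) input is net-depressed; and
because the stimulus is *shared*, open eyes receive equal additive
increments while noise trials depress each weight in proportion to itself,
so binocular vision is the attractor whenever both eyes are open — which is
exactly why BCM, unlike STDP, spontaneously recovers from deprivation once
both eyes reopen. The jitter amplitude (0.25) sets the speed of that
equalisation; it was raised from a first, slower choice so recovery
completes within the 20 000-step condition runs. Time units are arbitrary
model steps, reported as such. The STDP side of the comparison reuses the
two-input/one-output spiking circuit with open = active drive and
sutured = blocked, 1500 demo-seconds per condition, and deprived/open
weight ratios are compared at the end of the binocular-recovery condition
(BCM ≥ 0.5 recovered, STDP ≤ 0.2 persistent — acceptance bands of this
implementation, not quantities from the source).

## Numerical choices

* **Exact exponential decay.** Current and weight decay use the exact
  per-step factor $e^{-1/\tau}$, not an Euler approximation; the decay
  factor and its repeated application are carried in extended precision so
  that a million accumulated one-step decays match $e^{-t/\tau}$ to
  ~10⁻¹³.
* **Event order within a step** is fixed (inputs before outputs), and
  zero-lag pairs are excluded, which makes same-step pre/post processing
  order-independent (asserted).
* **Spike buffers** are deques evicted lazily at each event; a lag exactly
  equal to the window is included, anything older excluded.
* **Random numbers** come from counter-scattered splitmix64 streams: the
  state for `(seed, stream)` is produced by hashing both through the
  splitmix finalizer, so distinct streams are unrelated sequences (a plain
  additive offset would make them shifted copies of one another — a subtle
  correlation that completely changes plasticity outcomes), draws are
  platform-independent, and any run is reproducible from its config echo
  plus seed. Stream ids are `stage × 256 + input`; replicate subnetworks
  derive disjoint seeds from one base seed.
* **Degenerate inputs.** Non-finite neuron states or inputs, out-of-order
  synaptic events, sub-warm-up spike counts, duplicate replicate seeds and
  unreachable stage predicates all fail loudly; the predicate failure
  carries the partial trajectory for inspection.

## What the generator emulates — and what passing tests do not show

The noise drive *is* the synthetic data: it emulates uncorrelated
background cortical activity at a fixed mean rate, nothing more. Real
corticospinal activity is patterned, task-locked, and correlated across
hemispheres; real injuries silence populations partially rather than
gating a single cell's input to zero; and real synaptic populations are
heterogeneous where this model has four identical synapses with two decay
constants. Passing the phenomenology suite therefore shows that the
competition/hysteresis/reversal logic is *sufficient* in a minimal spiking
circuit — not that these parameters describe any real tract, and not that
the mechanism is *necessary* in vivo. The model also says nothing about
critical periods: nothing in it ages.

## Problem sizes

The shipped tests and the acceptance script use: 600 s single-neuron runs
for firing statistics (~9 000 spikes); 3 000-step engine-vs-reference
parity; 100 random 2 s scripts for the pairing oracle; 3 600–4 600 s
demo-scale runs for each competition case and protocol, at 20 seeded
replicates for the winner-take-all and five-stage sequences; 20 000 steps
per BCM condition. A full five-stage paper-scale run (~1.6×10⁹ steps) takes
a few minutes of compiled time and is left to the `paper` preset rather
than the test suite.

## Known limitations

* The ISI dispersion of the driven neuron (sd ≈ 6.5 ms, CV ≈ 0.097) is
  higher than the values quoted for comparable neuromorphic hardware; no
  printed parameter controls it (see *Drive* above).
* Excitatory synapses only; nearest-neighbour pairing, multiplicative
  updates and kernel-shape variants are out of scope.
* The stuck state is metastable over very long bilateral runs: a loser
  parked just under the busy-target threshold is safe on the tested
  horizons, but extreme-duration runs could in principle let rare
  coincidences re-seed it. The healthy state similarly sheds its
  ipsilateral weights toward zero over long bilateral runs, which is the
  competitive equilibrium of this wiring, not an artefact.
* The BCM comparator is a reconstruction of the standard equations for
  qualitative contrast, not a fit to any published BCM figure.
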