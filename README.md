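# synapcomp

Spiking-network simulator of activity-dependent synaptic competition in the
descending motor system, and of its reversal by constraint-induced
intervention.

Hemiplegic injuries leave a lasting asymmetry: the corticospinal projection
from the injured hemisphere loses its spinal targets to the uninjured side's
ipsilateral projection, and the deficit persists even after normal activity
returns. Constraint-induced movement therapy (CIMT) — restraining the
less-impaired side to force use of the impaired one — can reverse it.
`synapcomp` simulates the minimal spiking circuit in which this whole
phenomenology (competition, hysteresis, reversal, persistence of the
therapeutic effect) emerges from spike-timing-dependent plasticity alone,
and contrasts it with the rate-based BCM rule, which predicts spontaneous
recovery instead. It is aimed at computational neuroscientists studying
synaptic competition and at modellers interested in the mechanistic basis of
constraint therapies (CIMT, amblyopia patching).

## Model

* **Neurons** — regular-spiking Izhikevich units integrated at 1 ms:
  `v' = 0.04 v² + 5 v + 140 − u + I`, `u' = a(bv − u)`, with reset
  `v ← c, u ← u + d` at `v = 30` mV (`a = 0.02, b = 0.2, c = −65, d = 8`).
* **Synapses** — additive, all-to-all STDP with the asymmetric exponential
  kernel `Δg = A± · exp(−|Δt|/τ±)` (`A+ = 1.03`, `A− = −0.51`,
  `τ+ = 14` ms, `τ− = 34` ms) over a 64 ms pairing window, postsynaptic
  current decay `τ_SCD = 15` ms, weight decay `τ_SWD = 35` h, weights
  clamped to `[0, 1]`.
* **Drive** — each cortical input neuron receives an i.i.d. uniform current
  on `[0.6, 1.7] × I_th`, redrawn every millisecond from its own seeded
  stream, producing statistically independent ~15 Hz near-periodic trains.
* **Network** — two cortical inputs (R, L) and two spinal outputs (OR, OL);
  each output receives one contralateral (`w1 = L→OR`, `w2 = R→OL`) and one
  ipsilateral (`w0 = R→OR`, `w3 = L→OL`) synapse; ipsilateral weights decay
  1.5× faster. Outputs receive no direct noise — all their activity is
  synaptically driven.
* **Protocols** — staged drive schedules: the three two-input competition
  example cases, the five-stage constraint-therapy protocol, and the five
  ocular-dominance rearing conditions run through both STDP and a
  reconstructed BCM rule (`dw_i/dt = x_i·y·(y−θ)/τ_w`,
  `dθ/dt = (y²−θ)/τ_θ`).

The heavy per-millisecond loop is compiled (Rcpp); a pure-R reference
implementation of the identical update order is exported and tested against
it, and every plasticity update is validated against a brute-force
all-pairs sum.

## Worked example

Firing statistics of one noise-driven input neuron (600 s):

```r
library(synapcomp)
ds <- drive_statistics(drive_config(seed = 1), duration_s = 600)
str(ds[1:5])
#> List of 5
#>  $ rate_hz    : num 15
#>  $ isi_mean_ms: num 66.7
#>  $ isi_sd_ms  : num 6.47
#>  $ isi_cv     : num 0.097
#>  $ n_spikes   : int 8915
```

The neuron fires at 15 Hz with a mean interspike interval of 66.7 ms — a
nearly periodic train (CV ≈ 0.1), which is the background activity every
competition below runs on.

The five-stage constraint-therapy protocol on the 2×2 corticospinal
circuit, from healthy contralateral dominance (`w1, w2 = 0.6`;
`w0, w3 = 0.3`):

```r
pr <- run_protocol(config = default_config(), seed = 11)
pr
#> <subnetwork_run> topology: cst_2x2 | seed: 11
#> stages:
#>   healthy baseline                       0.0 -    600.0 s
#>   unilateral inactivation (R blocked)  600.0 -   2400.0 s
#>   bilateral activation (stuck)        2400.0 -   3000.0 s
#>   reverse inactivation (L blocked)    3000.0 -   3653.1 s
#>   bilateral activation (persistence)  3653.1 -   4553.1 s
#> final weights:
#>     w0     w1     w2     w3
#> 0.0006 1.0000 0.6885 0.4308
#> end-of-stage dominance (margin 10%):
#>                                 stage     OR     OL
#> 1                    healthy baseline contra contra
#> 2 unilateral inactivation (R blocked) contra   ipsi
#> 3        bilateral activation (stuck) contra   ipsi
#> 4    reverse inactivation (L blocked) contra contra
#> 5  bilateral activation (persistence) contra contra
```

Read the `OL` column: blocking R hands OL to the ipsilateral projection
from L (`ipsi`), restoring bilateral drive does **not** recover it (still
`ipsi` — the deficit is stuck), the reverse inactivation (the constraint)
flips it back (`contra`), and the recovery then persists under normal
bilateral input. `plot(pr$run)` draws the four weight trajectories with the
stage boundaries.

The BCM contrast:

```r
cmp <- bcm_compare(seed = 1)
subset(cmp$summary, condition == "binocular_recovery")
#>   model          condition w_open w_deprived  ratio
#>     BCM binocular_recovery   1.94       1.26  0.65
#>    STDP binocular_recovery   1.00       0.10  0.10
```

After monocular deprivation and re-opening of both eyes, BCM's sliding
threshold pulls the deprived pathway back toward the binocular state
(ratio ≈ 0.65), while under STDP the recovered dominant pathway keeps
suppressing it (ratio ≈ 0.10): only the spike-based rule reproduces a
persistent deficit.

A command-line wrapper (`inst/exec/synapcomp`) exposes the same runs as
subcommands (`validate-stdp`, `example-case {a,b,c}`, `cimt`,
`bcm-compare`, `drive-stats`), each writing a trajectory CSV, summary JSON,
config echo and checksummed manifest into a run directory.

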