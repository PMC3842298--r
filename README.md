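# whiskloop

Rats explore by rhythmically sweeping their facial whiskers (vibrissae)
against the world. The rhythm is made by brainstem central pattern
generators (CPGs), but touch can reshape it within a single whisk: a few
tens of milliseconds after a whisker meets an object, the whiskers briefly
retract and re-protract — a *touch-induced pump* (TIP) — while the touching
whisker stays on the object. `whiskloop` is a discrete-event,
statechart-based simulation of the brainstem loop that can generate this
behaviour, for computational neuroscientists who want to compare candidate
feedback circuits against tracked-whisker kinematics.

The model wires, per side of the snout, 29 rigid whiskers (rows of
4/4/7/7/7), their intrinsic and extrinsic mystacial-pad muscles, and
per-whisker pools of first-order afferents (162 cells split into whisking
W, contact C, pressure P and detach D classes), second-order relay cells
and facial motoneurons. Three CPGs drive the tri-phasic muscle sequence

&nbsp;&nbsp;extrinsic protractors → intrinsics → extrinsic retractors

giving whisk cycles of period `cyclesNum·cycleDuration + silenceDuration`
(150 ms by default: ~80 ms protraction, ~70 ms retraction, peaks at 79–81°
from a 70° rest; the rostral-most whisker of seven-whisker rows, which has
no rostral protractor, only reaches ~74.5°). Each muscle integrates
motoneuron volleys into a calcium-like activation `Ca(t)` and pulls with
the saturating torque `A = A_max·(1 − e^{−(Ca−Ca₀)/Ca_sat})`; each whisker
is a damped torsional spring `I·θ̈ = ΣA − b·θ̇ − k·(θ − θ_rest)`.

Touch feedback can be wired three ways, and they disagree observably:

| mechanism | wiring | pumping whiskers | touching-whisker pump |
|---|---|---|---|
| `E_R` | C/P cells excite retractor motoneurons | all 29 ipsilateral | ~0.6° |
| `DIRECT_I_P` | C/P cells inhibit the touching whisker's intrinsic motoneurons | touching + its in-row neighbours | ~3° |
| `INDIRECT_I_P` | C/P cells inhibit the intrinsic CPG | all 29 ipsilateral | ~5° (others ~10°) |

In all three, the pump is triggered by the pressure volley, whose latency
grows with the radial distance of contact — so pump delay increases with
`r` (≈16 ms at r = 0.4 under `E_R`).

An analysis layer segments whisk cycles at retraction minima, detects and
characterises pumps (delay, amplitude, spatial spread), computes exact
binomial occurrence tests, and generates synthetic tracked-whisker traces
with ground truth for testing.

## Worked example

Free-air whisking with the calibrated defaults, then a pump run against a
pole at 40% of whisker A4's length:

```r
library(whiskloop)

free <- run_simulation(whisk_configuration("CPG_ONLY", "NONE", seed = 1),
                       duration_ms = 1000)
glance(free)
#>   whisking_mechanism tip_mechanism duration_ms n_whiskers n_cycles cycle_ms
#> 1           CPG_ONLY          NONE        1000         29        5      150
#>   protraction_ms retraction_ms amplitude n_spikes n_contacts n_events
#> 1          75.95         74.05     11.86   155553          0    18886
```

Five whisk cycles of exactly 150 ms, ~12° amplitude, and the full spike
log of every afferent and motoneuron pool. Now the retractor-excitation
pump circuit:

```r
sim <- run_simulation(whisk_configuration("CPG_ONLY", "E_R", seed = 1),
                      duration_ms = 650,
                      obstacle = obstacle("A4", theta_obs_deg = 74.7, r = 0.4))
sim
#> <whisk_sim> CPG_ONLY + E_R, 650 ms, seed 1
#>   trajectories: 37729 samples over 29 whiskers; spikes: 101065; contacts: 5

tips <- detect_tips(sim$trajectories, sim$contacts)
subset(tips, first_in_cycle & episode > 1 & whisker == "A4")
#>   episode delay_ms amplitude contact_maintained
#>       2       16      0.58               TRUE
#>       3       16      0.58               TRUE
#>       4       16      0.58               TRUE

tip_spread(subset(tips, episode == 2), touching = "A4")
#>   episode n_pumping        identity
#> 1       2        29 all_ipsilateral
```

The touching whisker pumps 0.58° sixteen milliseconds after each contact
without leaving the pole, and every ipsilateral whisker pumps with it —
the spatial signature that separates retractor excitation from direct
intrinsic inhibition (which moves only the touching whisker and its in-row
neighbours; try `"DIRECT_I_P"`). `autoplot(sim)` draws the row of
trajectories with contact spans shaded; `plot_tips(sim)` marks the
detected pumps.

A command-line interface wraps the same functions:

```sh
./exec/whiskloop run --config cfg.json --seed 1 --out outdir
./exec/whiskloop sweep --axis obstacle.r --values 0.2:0.7:0.1 --out outdir
./exec/whiskloop calibrate --out params.json
```

## Package layout

* `R/scheduler.R`, `R/statechart.R` — deterministic discrete-event core
  and the minimal executable-statechart semantics (FIFO tie-breaking,
  run-to-completion, per-state timeouts, condition connectors).
* `R/neural.R`, `R/network.R` — CPG/neuron dynamics, transduction, and
  construction of the wired pad for every configuration.
* `R/plant.R`, `R/simulate.R` — muscles, whisker dynamics, obstacle
  contact, and the run orchestration (tibble trajectories, spike logs,
  JSONL transition traces, round-trippable on-disk results).
* `R/analysis.R`, `R/fixtures.R` — cycle segmentation, pump detection and
  spread classification, exact binomial tests, synthetic trace generator.
* `R/calibrate.R` — coordinate-search calibration against the kinematic
  benchmarks; the shipped `inst/extdata/default-params.json` is its
  product.
* `vignettes/whisking-model.Rmd` — the model, its assumptions, parameter
  rationale and limitations.
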