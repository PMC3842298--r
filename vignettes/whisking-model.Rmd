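---
title: "An executable statechart model of the whisking brainstem loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An executable statechart model of the whisking brainstem loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`whiskloop` simulates the shortest sensorimotor loop of the rat vibrissal
system — trigeminal afferents, trigeminal nuclei, facial-nucleus
motoneurons, mystacial-pad muscles and the whiskers themselves — as a
collection of communicating statecharts under a deterministic discrete-event
scheduler. The model's purpose is to ask which brainstem feedback circuit
can turn whisker–object touch into the touch-induced pump (TIP): the brief
retraction-and-re-protraction that interrupts protraction a couple of tens
of milliseconds after contact.

This vignette is the package's own account of the model: the moving parts,
the parameters that matter and why they have the values they have, the
numerical choices, and what the synthetic data used by the test-suite does
and does not establish.

## The components and their charts

Every component is a live chart instance with one active state:

* **CPGs.** Three central pattern generators (`Int`, `ExtP`, `ExtR`) — one
  per muscle class — alternate between `Activate` and `Relax`. In
  `Activate` a CPG broadcasts one stimulation event to every motoneuron of
  its type each `cycleDuration` (5 ms), `cyclesNum` times, then relaxes for
  `silenceDuration`. The full period is exactly
  `cyclesNum * cycleDuration + silenceDuration`; the condition-connector
  evaluation that sends the chart to `Relax` is counted against the silent
  period so this closed form holds. Phase offsets between the three CPGs
  (a silent lead-in on the first cycle) stagger them into the tri-phasic
  drive: extrinsic protractors first, intrinsics second, extrinsic
  retractors third. With the shipped defaults the period is 150 ms.
* **Neurons** (`Rest` → `GenerateAP` → absolute → relative refractory →
  `Rest`). Event-driven threshold units, not membrane models: stimuli
  accumulate inside a sliding integration window (4 ms), with per-source
  saturating caps; a firing cell relays its action potential after
  `t_relay` (1 ms), is absolutely refractory for 2 ms and relatively
  refractory (threshold raised by `rrp_factor`) for 20 ms. Pools of
  identical cells (10 motoneurons and 10 second-order cells per type per
  whisker; 162 first-order afferents per whisker, split 73 whisking / 33
  contact / 28 pressure / 28 detach) are updated vectorised, but the
  per-cell semantics are exactly the chart's and are exposed through
  `new_neuron()` / `deliver_stimulus()`.
* **Muscles** (`Rest` / `Contract`). Each motoneuron volley adds to a
  calcium-like activation `Ca` that decays exponentially; the muscle
  contracts while `Ca >= Ca_0` and its force is the saturating
  `A_max * (1 - exp(-(Ca - Ca_0)/Ca_sat))`. Each whisker is slung by two
  intrinsic muscles (the rostral-most keeps only its caudal one; in
  four-whisker rows the missing rostral muscle is replaced by a
  pseudo-intrinsic protractor, in seven-whisker rows it is simply absent),
  one superficial extrinsic protractor group, and superficial plus deep
  extrinsic retractor groups. Group muscles contract as a unit, which is
  how one whisker's feedback can move every whisker.
* **Whiskers** (`Rest` / `Move`). Rigid levers: damped torsional springs
  around a 70° rest angle, integrated with fixed-step semi-implicit Euler
  at 0.5 ms, interleaved with the event queue at step boundaries.
* **Obstacle** (`NoContact` / `Contact`), static and present from t = 0.

## Sensory transduction and the feedback configurations

Whisking (W) cells fire during protraction with per-cell jitter and a small
per-protraction spike budget; contact (C) cells fire once at contact onset;
pressure (P) cells fire repetitive volleys while contact persists, the
first delayed by `pressure_latency(r)` — affine and strictly increasing in
the radial contact fraction `r`; detach (D) cells fire once at contact
offset. Each second-order cell pools a random half of its subtype's
first-order pool (the seeded fan-in draw).

The **whisking axis** selects who drives the motoneurons: the CPG alone
(`CPG_ONLY`, a single burst crosses threshold), second-order whisking cells
alone (`SENSORY_ONLY`), or both (`CPG_PLUS_SENSORY`) — in the joint regime
per-class saturating caps guarantee that neither source alone can ever
reach threshold, so motoneurons fire only on coincidence.

The **TIP axis** wires contact + pressure second-order cells onto one of
three targets: the touching whisker's extrinsic-retractor motoneurons
(excitatory, `E_R`), its intrinsic motoneurons (inhibitory, `DIRECT_I_P`),
or the intrinsic CPG itself (inhibitory, `INDIRECT_I_P`). A slow (30 ms)
touch gate at the target integrates the pooled volleys with
reset-by-subtraction: the contact-onset volley alone is sub-threshold, so
the pump is always triggered by the pressure volley and the pump delay
inherits the radial-distance dependence of the pressure latency. An
inhibitory trigger silences its target for a veto window and shunts further
volleys while the veto lasts; an excitatory trigger fires every eligible
retractor motoneuron as one compound volley.

## Why the plant looks the way it does

The published force/motion routine of the original model is not available,
so the plant is a damped torsional spring with calcium-gated saturating
muscle torque, calibrated against the printed kinematics. Three design
choices deserve explanation:

* **Intrinsic sharing factor 9/11.** A contracting intrinsic muscle drives
  its caudal whisker at weight 1 and its rostral neighbour at weight
  s = 9/11. The three printed peak targets (79–81° for ordinary whiskers,
  ~74.5° for the rostral-most of seven-whisker rows, from a 70° rest) pin
  s exactly: with unit torque D per muscle, (1+s)D = 10° and sD = 4.5°
  have the unique solution D = 5.5°, s = 9/11. A smaller share cannot reach
  74.5° without a persistent protractor bias that would in turn cap the
  CPG-inhibition pump at well under the printed ~10°.
* **Elastic contact, not a positional clamp.** While touching, the pole
  acts as a stiff one-sided spring (`k_contact`, plus extra damping
  `b_contact`) on the base angle above the contact azimuth: the whisker
  "briefly protracts while bending", and during a pump it straightens
  without leaving the pole until it retracts past `eps_contact` (2°).
  Contact stiffening is also what makes the touching whisker's pump
  smaller (~0.6°) than its neighbours' (~1–2°) under retractor excitation:
  the same retractor volley moves a contact-stiffened whisker less. A hard
  clamp was tried first and rejected: it accumulates a protraction surplus
  that the retractor volley must cancel before the touching whisker can
  move at all, which makes the printed touching-whisker amplitude
  incompatible with the printed terminal retraction.
* **Twitch-like vs ramp-like retractors.** Retractor motoneurons fire
  phasically (their relative-refractory threshold is high, so they respond
  to strong synchronous input roughly every 15 ms rather than following
  every CPG burst). The superficial retractor is a fast twitch muscle
  (tau 4 ms) that responds per compound volley — this is the pump effector
  — while the deep retractors are slow (tau 22 ms), pool-normalised
  integrators that carry the sustained phase-3 retraction. One compound
  volley into a rested twitch muscle produces a brisk ~1° pump; the same
  volleys arriving rhythmically in phase 3 average out to the ~2 torque
  units that bring the whiskers back to their ~68° trough.

## Parameters

All defaults live in `inst/extdata/default-params.json` (read by
`whisk_params()`, overridable per run). The ones that matter most:

| parameter | default | meaning |
|---|---|---|
| `cpg.*` | 150 ms period | tri-phasic windows: ExtP bursts 5–35 ms, Int 30–85 ms, ExtR 88–148 ms of each cycle |
| `plant.inertia/damping/stiffness` | 8 / 8 / 1 | overdamped lever, ~7 ms response time |
| `plant.k_contact`, `b_contact` | 4, 5 | pole stiffness/damping felt by the touching whisker |
| `muscle.intrinsic.*` | tau 12 ms, Ca0 1.25 | phase-2 protractor; sets peaks with the 9/11 share |
| `muscle.extR_sup.*` | tau 4 ms, A_max 18 | fast twitch; the pump effector |
| `muscle.extR_deep.*` | tau 22 ms, A_max 1.15 | slow ramp; terminal retraction |
| `afferent.pressure_latency_*` | 15.7 ms at r = 0.4, slope 16 ms | pressure first-spike latency, calibrated with the conduction delays so end-to-end pump delays run ~13–21 ms over r = 0.2–0.7 |
| `neuron.veto_direct_ms` / `veto_indirect_ms` | 18 / 20 | inhibition windows of the two I-P mechanisms |
| `neuron.tip_w`, `tip_threshold` | 0.12, 1.5 | touch-gate weights: one 10-cell volley is 1.2, so contact alone never triggers |

These values were fixed by `calibrate_params()`-style coordinate search
against the free-air benchmarks (cycle 150 ms, protraction ≈ 80 ms,
retraction ≈ 70 ms, peaks 79–81° / 74.5°) and the pump benchmarks at
r = 0.4 (delays ≈ 17/19 ms; amplitudes 0.6° / 3° / 5° / 10° for the
respective mechanisms and whisker groups), and then frozen. They stand in
for the original model's unavailable parameter file; they are a calibrated
operating point, not transcribed measurements.

## Numerical and algorithmic choices

* **Time** is an integer microsecond counter; equal-due-time events
  dispatch strictly FIFO by insertion order, which makes every run
  reproducible event-for-event (the original tool's simultaneous-event
  order is unspecified; FIFO is our choice).
* **Events with no enabled transition are discarded and logged** — the
  "cannot respond to any stimulus" reading of refractoriness.
* **Run-to-completion:** transition actions may post events but nothing
  dispatches until the action returns.
* **Performance:** synaptic traffic is batched into grouped bus events
  (one per compound volley rather than one per synapse), and the queue,
  spike log, transition trace and trajectory recorder are C++-backed
  containers; a 2 s, 29-whisker run dispatches ~30k events.
* **Degenerate inputs:** zero-duration runs return empty trajectories with
  valid metadata; a flat trace segments into zero cycles; non-finite plant
  states abort with a diagnostic.

## The analysis layer

Cycle segmentation low-pass filters at 40 Hz (zero-phase Butterworth, as
tracked-whisker data are filtered) and delimits cycles at retraction
minima, pruning oscillations under 3° so pumps do not split cycles.

The pump detector filters at 80 Hz and scans a 45 ms window after each
contact onset for the pump signature: a drop of at least `delta_tip`
(0.3°, chosen to clear numerical ripple while keeping the ~0.5° touching
whisker pump) from the running maximum, a trough reached within 35 ms at a
peak retraction velocity of at least 0.08°/ms (pumps are brisk; slow
free-air sags are not), and a re-protraction of at least 0.15° within
25 ms of the trough, all before the cycle's terminal retraction. The pump
onset is the last sample within 0.1° of the pre-drop maximum, so the
touching whisker's delay measures the start of its retraction relative to
contact onset. Windows truncated by the end of the record are skipped.
Whiskers that slow by half without retracting are reported separately by
`detect_slowdowns()`.

`binom_test_exact()` is the exact binomial tail sum used for
pump-occurrence comparisons.

## The synthetic trace generator

`generate_whisk_fixture()` emulates tracked-whisker output: smooth
asymmetric whisk cycles (half-cosine protraction and retraction), a
contact plateau for touching whiskers, pumps injected at known delay and
amplitude (a fast drop and slower recovery), and additive white noise. It
provides exact ground truth for the segmentation and detection tests —
durations are recovered exactly, injected pumps to within a sample — and a
Monte-Carlo recovery check (100 seeded fixtures, 1° pumps in 0.1° noise).

What it does *not* emulate: head motion, whisker bending and tracking
dropouts of real video data, amplitude/frequency drift across cycles, or
pump shapes other than the stereotyped drop-recovery. Passing these tests
therefore validates the analysis pipeline's logic, not its performance on
arbitrary real recordings.

## Problem sizes in the test-suite

The packaged tests run the full 29-whisker pad: one 2 s free-air run,
0.5–0.65 s runs per feedback mechanism, a six-point radial-distance sweep
at 0.47 s per point, and 0.8 s runs per whisking configuration — sizes
chosen so the whole suite exercises every configuration in a few minutes
while containing at least three whisk cycles per measurement.

## Known limitations

* Pump probability and across-cycle dynamics are out of scope: the model
  pumps on every contacted cycle, as the open-loop brainstem circuit
  should; the rat's ~25% occurrence is attributed to top-down gating that
  is deliberately not modelled.
* The deep-retractor groups contribute little to the pump volley, so
  non-touching pump amplitudes are nearly equal across rows rather than
  split between the A–B and C–E deep-muscle groups.
* Whisker bending is reduced to the elastic contact spring; torsion, pad
  translation and bilateral coordination are not modelled.
* Neurons are threshold units: no conductances, adaptation beyond the
  whisking-cell spike budget, or synaptic plasticity.
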