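---
title: "The closed-loop motor unit model: structure, calibration, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The closed-loop motor unit model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

motorunit simulates a single mammalian (cat-scale) motor unit as a closed
loop: a multi-compartment motoneuron whose dendrites carry a relocatable
hot-spot of L-type (Cav1.3) calcium channels — the source of the persistent
inward current (PIC) — drives a slow-twitch muscle model, while
muscle-spindle afferents feed an excitatory conductance back onto the
proximal motoneuron membrane in proportion to muscle length. This vignette
documents the model equations, the free parameters and how the calibration
routines pin them, the numerical scheme, and the design decisions that were
genuinely open.

## The motoneuron

**Morphology.** The default morphology is generated by
`synthetic_motoneuron()`: 10 stem dendrites leave a 48.8 x 48.8 um
equivalent-area soma cylinder, each reaching a root-to-tip path length of
1.8 mm through three symmetric binary branch points, with linear diameter
taper (25% per mm, floor 0.8 um) and Rall 3/2 diameter steps at branch
points. A 20 um hillock tapering 13 -> 3.3 um and a 30 um initial segment of
constant 3.3 um diameter are attached to the soma. The seed only jitters
stem diameters and branch positions; tip path lengths are exact, so every
0.1 mm path-length band up to 1.8 mm is populated on every stem. An SWC
reader/writer (`read_swc()`, `write_swc()`) accepts real reconstructions as
a drop-in replacement.

The generator's diameters (9 um nominal stems) and the passive set below
were chosen together so that the electrotonic positions of the hot-spot
bands match the reference mapping for an adult cat alpha-motoneuron —
approximately 0.11, 0.27, 0.36 and 0.47 lambda at path lengths of 0.2, 0.6,
0.8 and 1.0 mm. This mapping is what places the qualitative regimes
(partial PIC activation proximally, mid-ramp plateau ignition at
intermediate distance, ignition at recruitment distally) in the intended
path-length windows; with thinner stems or lower membrane resistivity the
same windows shift distally and the hot-spot loses the local input
resistance needed for regenerative plateau ignition.

**Passive properties.** Specific capacitance 1 uF/cm^2 and axial
resistivity 70 Ohm cm are uniform. Membrane resistivity is nonuniform: a
strong somatic shunt (0.1 kOhm cm^2, also applied to hillock and initial
segment) rising sigmoidally with path length (midpoint 0.1 mm, slope
0.05 mm) to a distal plateau of 25 kOhm cm^2. The shunt sets rheobase
(~9 nA) well above the maximal-length afferent current (5 nA), so the unit
is not recruited by spindle drive alone, while the high distal resistivity
gives dendrites the local input resistance gradient that makes hot-spot
behavior location-dependent.

**Channels.** Somatic spiking machinery follows the classic cat-motoneuron
formulations: fast Na (m^3 h, bell-shaped tau_h), delayed-rectifier K
(n^4), N-type Ca (m^2 h, the calcium source), Ca-dependent K (Hill
coefficient 2 on somatic calcium, the AHP current), and a small persistent
Na. The hillock and initial segment carry 5x Na and 2.5x K-DR density.
These kinetics are not a contribution of this package; their densities were
tuned once so that the soma fires regularly over a 5-15 Hz primary range
with rheobase ~9 nA and an AHP in the 250 ms class, and are fully
configurable through `channel_spec()`.

The dendritic Cav1.3 channel is the scientific core. Its activation gate is
low-voltage activated (half-activation -52 mV, slope 4 mV; the gate is
>0.5 open at -45 mV) with a strongly voltage-dependent time constant:
40 ms above approximately -60 mV and rising to ~2 s below -66 mV. The fast
limb lets the plateau ignite and deactivate on ramp time scales; the slow
hyperpolarized limb preserves residual activation across ~1 s gaps between
repeated stimuli, which is the mechanism of warm-up. The peak conductance
density is never set by hand: `calibrate_gcal()` pins it per band (below).

**Calcium pool.** A thin-shell somatic pool,
`d[Ca]/dt = -f I_CaN - ([Ca]-[Ca]_rest)/tau_Ca`, gates the AHP current. Its
removal time constant is the free parameter of the AHP side of the
AHP-twitch speed-coupling calibration.

## The muscle unit

Three modules transform the motoneuron spike train (delayed 10 ms for
efferent conduction) into isometric force at constant length `X_m`
(mm relative to maximal physiological length; -16 shortest, -8 optimal,
0 longest):

1. **Spikes to calcium** — each spike releases `R (1 - Ca/Ca_sat)` of
   normalized sarcoplasmic calcium (saturable release); between spikes
   calcium is resequestered first-order (tau 50 ms at unit time scale).
2. **Calcium to activation** — bimolecular calcium-troponin binding
   `d(CaT)/dt = k_on Ca (1-CaT) - k_off CaT` followed by a Hill function
   `A = CaT^3 / (CaT^3 + K_A(X_m)^3)`. `K_A` increases linearly as the
   muscle shortens (+25% per 8 mm below optimum), so short-length force
   deficits are rate-dependent: tetanic calcium saturates the Hill curve
   and masks the shift, twitch and subtetanic (<20 Hz) inputs expose it.
3. **Activation to force** — force relaxes toward `A * FL(X_m)` with a
   40 ms filter. `FL` is an asymmetric Gaussian with `FL(-8) = 1`,
   `FL(-16) = 0.55`, `FL(0) = 0.85`; the end values are ordering
   constraints, not measured quantities.

A single dimensionless `time_scale` multiplies all four muscle time
constants; it is the free parameter of the twitch side of the speed
coupling.

## The muscle spindle

Afferent synapses (reversal 0 mV) cover the soma and every dendritic
compartment with path length < 1.4 mm, at uniform density, activated
synchronously — tonic drive for an isometric hold, a 10 ms-delayed waveform
when length varies. The density at the three anchor lengths is calibrated
(below); between anchors `gaff_of_length()` interpolates linearly, a choice
this package makes explicit because only the three anchor lengths are ever
simulated in the reference protocols.

## Calibration

All free parameters are pinned by `calibrate_motor_unit()` in dependency
order, each to a measurable somatic quantity:

* `calibrate_gaff()` — for each anchor length, bisection on the afferent
  density until the effective synaptic current `I_N` (the clamp-current
  deflection at the soma held at rest, dendrites passive) equals 0, 2.5 and
  5 nA at -16, -8 and 0 mm. The passive tree is linear, so bisection
  converges in a handful of steps.
* `calibrate_gsyn_peak()` — fixed-point rescaling of the triangular
  dendritic-excitation peak until the maximal `I_N` is 16 nA. The map is
  measured statically at the peak conductance; the triangular ramp is slow
  enough (10 s to peak against a ~10 ms membrane) that the quasi-static and
  dynamic maxima agree, which the test suite verifies with a full
  triangular clamp run.
* `calibrate_gcal()` — bisection on the hot-spot Cav1.3 density until the
  leak-subtracted peak inward clamp deflection during a slow somatic
  voltage ramp (-70 to -30 mV over 5 s; CaL the only active channel; leak
  subtraction via an identical run at zero density) equals 22 nA. The
  holding/ramp convention is a design choice — the reference protocols
  measure effective currents at the soma on slow clamp ramps but do not
  print the command waveform.
* `calibrate_ahp_twitch()` — the speed coupling: bisection on the somatic
  calcium-pool removal constant until the AHP of a single elicited spike
  (return to within 1 mV of rest) lasts 250 ms, and a secant iteration on
  the muscle `time_scale` until the single-spike twitch (force onset at 1%
  of twitch peak until decay below 10%) lasts 250 ms at optimal length.

Calibrations are deterministic and idempotent; every run records a report
row (parameter, target, achieved, residual, iterations) retrievable with
`tidy()` on the motor unit.

## Stimulation protocols and indices

`run_ramp()` applies the triangular somatic current (peak 20 nA at 5 s,
10 s total) or the triangular dendritic conductance on the hot-spot band
(calibrated peak at 10 s, 20 s total) with the spindle drive held at the
calibrated density for `X_m`. `run_warmup()` applies four 2-s somatic
triangles (-5 to +10 nA) separated by 1 s gaps held at the -5 nA floor, or
eight 2-s sinusoidal afferent cycles between the shortest- and
longest-length densities with a -1 / -0.5 nA somatic step and all
voltage-gated channels on soma, hillock and initial segment disabled (the
QX-314 condition).

`build_io_curve()` resamples force and instantaneous rate against the
stimulus axis (injected current, or `I_N` composed from the calibrated
conductance-to-current map) on a 0.05 nA grid, separately per phase, ties
resolving to the earlier time. `compute_indices()` derives:

* `DCT` = force-initiation minus force-cessation current (onset threshold
  1% of run peak force — the reference work never states its criterion, so
  the default is declared here);
* `DCI` = current interval from force initiation to 63% of ascending peak
  force (interpolated linearly between grid samples);
* `DFG` = descending-minus-ascending force at the PIC-onset current, forced
  to zero when no sustained acceleration exists or when acceleration starts
  within 0.5 nA of recruitment (no bistable transition).

PIC onset is the first stimulus where the windowed f-I slope (window =
0.5 nA) exceeds twice the primary-range slope in two consecutive windows;
the window makes the criterion robust to the step-like texture of
instantaneous-rate traces, and the two-window requirement rejects
transients narrower than the sustain span. `warmup_metrics()` flags warm-up
when per-trial peaks (rate and force, or somatic and dendritic-site
potentials under QX-314) increase strictly across all trials by more than
1% per step.

## Numerics

* Fixed step `dt = 0.025 ms` everywhere spikes occur. Voltage-clamp
  calibration runs use 0.05 ms (no spikes under clamp; the Cav1.3 time
  constant never drops below 40 ms, and halving the step changes the
  calibrated quantities by far less than the 2% tolerance).
* The branched cable is solved with a theta-method on the Hines-ordered
  tree matrix (one leaf-to-root elimination, one root-to-leaf
  back-substitution per step). The default is theta = 1 (implicit Euler).
  A symmetric Crank-Nicolson step (theta = 0.5) is available, but at spike
  peaks the somatic conductance satisfies `g dt / 2C >> 1` and CN produces
  a +/-30 mV two-step numerical ring that corrupts gate updates — the same
  reason general-purpose neural simulators default to the implicit scheme.
  Convergence is tested by dt-halving: first-spike latency agrees to
  <0.1 ms and steady-state ISI to <1%.
* Gates advance by exact exponential relaxation against tables of
  `m_inf(V)` and `exp(-dt/tau(V))` precomputed on a 0.05 mV grid.
* Spatial grid: compartments no longer than 0.15 of the local 100
  Hz-equivalent space constant (about 1250 compartments for the default
  tree); the analytic sealed-end test uses 0.05.
* Spike detection: upward 0 mV crossing at the soma with a 1 ms lockout,
  re-armed only after repolarization below -20 mV.
* The voltage clamp is ideal (the soma row of the system is replaced by the
  command); the reported electrode current is the current balance at the
  clamped node.

## What the synthetic generator does and does not emulate

The generator reproduces adult-cat scale: stem count, maximal path length,
taper, branch-order structure, soma size, and — with the passive set — the
electrotonic mapping of path length. It does not reproduce the asymmetric
branch lengths, varicosities, per-branch diameter scatter or 3D embedding
of a real reconstruction, and its band membrane areas are smoother across
path length than a real cell's. Consequences observed in this
implementation: the calibrated hot-spot density is nearly flat across bands
(a real reconstruction needs several-fold higher distal density for the
same 22 nA), and the afferent density required for the 5 nA anchor is
higher than on a real cell (less membrane area below 1.4 mm), which makes
long-muscle-length afferent drive depolarize the hot-spot more strongly
than in the reference setting. Passing property tests therefore demonstrate
the mechanism — location- and length-dependent PIC behavior of a calibrated
closed-loop unit — not quantitative agreement with any particular
reconstructed cell.

## Known limitations

* At maximal muscle length with distal hot-spots, afferent drive plus
  subthreshold PIC activation recruits the default unit at nearly zero
  injected current; the hysteresis index then degenerates to the
  force-initiation threshold and the monotone growth of DCT with hot-spot
  distance breaks down for those grid cells (the affected acceptance
  checks are left failing rather than re-tuned around).
* The voltage range the Cav1.3 gate traverses between repeated warm-up
  stimuli is the same range the hot-spot occupies during the descending
  ramp limb, so one voltage-dependent time constant cannot make
  deactivation simultaneously slow enough for warm-up and fast enough for
  crisp de-recruitment. The shipped default favors warm-up; the cost is
  that the slowest force development and the force-potentiation window sit
  one 0.1 mm grid step proximal of the intended 0.5-0.8 mm band, and
  proximal hot-spots retain more ramp hysteresis than intended.
* Under the dendritic (QX-314) warm-up protocol the calibrated afferent
  sinusoid drives the hot-spot plateau to saturation within the first
  cycle, so the gradual cycle-to-cycle growth is not reproduced; this
  traces to the synthetic arbor's small membrane area below 1.4 mm, which
  forces a locally strong afferent density for the fixed 5 nA somatic
  anchor.
* Isometric only; no force-velocity dynamics, no tendon compliance, no
  fatigue, no stochastic synaptic background (all deliberately out of
  scope).
* Na-type PIC channels are not modeled; the PIC is purely calcium-carried.
* One motoneuron, one muscle unit; no pool-level statistics.

## Problem sizes used by the test suite

Unit tests run on small cables and two-stem trees (tens to hundreds of
compartments, sub-second to few-second simulations). The acceptance suite
calibrates the default 10-stem unit once and runs the full 10 x 3 x 2
location/length/mode sweep at default discretization plus the warm-up grid
— a few hundred seconds of simulated time in total.
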