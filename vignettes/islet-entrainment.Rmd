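---
title: "Modeling entrainment and synchronization of islet calcium oscillations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling entrainment and synchronization of islet calcium oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletsync)
```

## The scientific problem

Pancreatic islets exhibit slow oscillations of cytosolic Ca^2+^ (and,
downstream, of insulin secretion) with periods of a few minutes.
Individual islets are autonomous oscillators; a population of isolated
islets drifts out of phase unless something synchronizes them.  One
candidate synchronizing signal is pulsatile cholinergic (muscarinic)
input: brief pulses of an agonist such as carbachol raise intracellular
IP~3~, releasing Ca^2+^ from the endoplasmic reticulum and thereby
nudging the phase of each islet's oscillation.  `isletsync` provides the
computational machinery for studying this mechanism end to end: a
biophysical model of the islet oscillator with IP~3~ pulse dynamics,
builders for periodic and randomly spaced pulse protocols, nadir-based
phase response curves (PRCs), and the spectral analysis pipeline used to
read periods, entrainment ratios, and synchrony out of Ca^2+^ traces.

## The model

The core is a dual-oscillator β-cell model: two coupled conditional
oscillators, one glycolytic and one electrical, extended with an IP~3~
balance equation and IP~3~-gated Ca^2+^ release from the ER.

**Electrical/Ca^2+^ subsystem.**  Membrane potential $V$ carries a
voltage-gated Ca^2+^ current, a delayed-rectifier K^+^ current (gating
variable $n$), a Ca^2+^-activated K^+^ current, and an ATP-inhibited
K(ATP) current whose open fraction follows Magnus–Keizer nucleotide
gating with ADP computed from a conserved adenine pool
($ADP = A_\mathrm{tot} - ATP$).  Cytosolic Ca^2+^ ($c$) integrates the
membrane flux (influx through Ca_V channels minus plasma-membrane pump
extrusion) and the ER flux (leak plus IP~3~-receptor release minus
SERCA uptake); ER Ca^2+^ ($c_{er}$) mirrors the ER flux scaled by the
cytosol-to-ER volume ratio.

**Glycolytic subsystem.**  Phosphofructokinase (PFK) is modeled with the
classic 16-state allosteric scheme: AMP and FBP activate, ATP inhibits,
and F6P binds cooperatively.  F6P integrates a constant glucokinase
input $J_{GK}$ (glucose is fixed at the experimental 11 mM) minus the
PFK rate; FBP integrates the PFK rate minus consumption by
Ca^2+^-activated pyruvate dehydrogenase (PDH),
$J_{PDH} = v_{PDH}\, \frac{c}{c + k_{PDH}} \sqrt{FBP}$.

**Coupling.**  Metabolism acts on the membrane through ATP: nucleotide
balance relaxes toward a target set by a saturating function of
$J_{PDH}$, so glycolytic FBP waves become ATP waves that open and close
K(ATP).  The membrane acts back on metabolism through Ca^2+^ activation
of PDH.  These are exactly the two couplings the model structure
requires; a direct Ca^2+^ dependence of net ATP consumption is included
as an optional term (`ca_atp`) but disabled by default — see *Design
choices*.

**IP~3~ dynamics.**  A muscarinic pulse is treated as a pulse of IP~3~
production:
$$\frac{d[IP_3]}{dt} = \frac{A - [IP_3]}{\tau_{IP_3}},$$
with $A = 0.35\ \mu M$ while a pulse is on and $A = 0$ otherwise, and
$\tau_{IP_3} = 10$ s.  This linear equation has a closed-form
exponential solution (`ip3_closed_form()`) used as an oracle in the test
suite.  IP~3~ gates a Hill-type ER release flux, so each pulse dumps a
fraction of the ER store into the cytosol.  Agonist concentration is
not modeled: any pulse maps to the single drive amplitude
$0.35\ \mu M$.

### Provenance and calibration

The model family (dual conditional oscillators, Magnus–Keizer K(ATP)
gating, the 16-state PFK scheme, Ca^2+^-activated PDH) follows the
published β-cell dual-oscillator literature.  The exact kinetic
constants used in the original simulations are not published alongside
the behavioral results this package targets, so the defaults of
`iom_params()` are this package's own calibration, chosen once to
satisfy the stated behaviors:

* sustained bursting of cytosolic Ca^2+^ with a dominant period of
  ~5 min at default parameters, stable over hours;
* FBP oscillating at the same period as Ca^2+^ (the metabolic and
  electrical oscillators are phase-locked);
* a *type 2* PRC for single 10-s IP~3~ pulses: phase advances when the
  pulse lands in the Ca^2+^ plateau ($\phi < 0.5$), essentially no
  shift early in the silent phase ($0.5 < \phi < 0.6$), and delays late
  in the silent phase ($\phi > 0.6$);
* 1:1 entrainment of heterogeneous model islets by 10-s pulses
  delivered every 5 min, and transient synchronization by randomly
  spaced pulses.

Mechanistically, the pulse acts through the PDH feedback: during the
plateau the released Ca^2+^ burns FBP faster and ends the active phase
early (advance); at the FBP trough just after the plateau the burn has
nothing to consume (the quiet band); during the silent-phase FBP
recovery the burn pushes glycolytic re-ignition back (delay).  The
positions of the quiet band and the sign change therefore track the
phase of the FBP trough, which is what the calibration pins down.

### Design choices

* **The `ca_atp` term defaults to zero.**  With a strong direct
  Ca^2+^→ATP-consumption term, a silent-phase Ca^2+^ transient dips ATP,
  disinhibits PFK (ATP is a PFK inhibitor), and *advances* glycolytic
  re-ignition — producing advances at all phases and no delay region.
  The model structure statement lists only the ATP→K(ATP) and
  Ca^2+^→PDH couplings, and the type-2 PRC requires the PDH route to
  dominate, so the direct consumption pathway ships disabled (it can be
  re-enabled for exploration).

* **Phase anchors.**  Phase 0 is the beginning of a burst active phase,
  detected as the upward crossing of the midpoint between cycle
  extremes; phase 1 is the Ca^2+^ nadir ending the following silent
  phase.  In this calibration the nadir precedes the next burst onset
  by roughly a tenth of a cycle, so `compute_prc()` lays its pulse grid
  over the onset-to-nadir span, matching the anchor definition rather
  than assuming the two coincide.

* **Nadir matching in `phase_shift()`.**  The first perturbed nadir
  after the pulse (excluding a short settling window of the pulse
  transient itself) is paired with the nearest unperturbed nadir, ties
  toward the earlier one, and the shift is wrapped into $(-0.5, 0.5]$.

* **Event-exact pulses.**  The integration (stiff-capable `lsoda` on a
  compiled right-hand side, relative tolerance $10^{-8}$) is split at
  every pulse onset and offset, so the square-wave drive switches
  exactly at pulse boundaries.  Nadir times are refined by parabolic
  interpolation, giving the ~1-s timing precision the PRC needs.

* **Population heterogeneity.**  `make_heterogeneous_population()`
  samples Ca_V and K(ATP) conductances by stratification: islet $i$
  draws from the $i$-th sub-interval of the Ca_V range and the opposite
  stratum of the K(ATP) range, like constructing model islets with
  deliberately different conductance pairs.  The default ranges give
  natural periods of roughly 4.7–5.5 min.  The K(ATP) ceiling keeps
  every draw clear of a regime boundary: beyond it the model is
  bistable with a silent steady state (low Ca^2+^ → PDH off →
  glycolysis steady → ATP high → K(ATP) silence) into which a heavy
  pulse train can push an islet.

* **Unsynchronized initial conditions.**  `phase_spread_states()`
  places each islet on its own limit cycle at evenly spread phases
  (thirds for three islets), emulating the arbitrary phases of
  independently oscillating islets at the start of an experiment.

## The analysis pipeline

The trace pipeline mirrors standard islet fluorescence analysis:

1. **`background_subtract()`** removes the least-squares line.
2. **`interpolate_upsample()`** inserts two points per sample gap by
   linear interpolation (configurable; one published description
   mentions a single inserted point, the methods text two — two is the
   default).
3. **`stft_spectrogram()`** slides a 256-point Hanning window in hops of
   5 samples; each tapered window is zero-padded to 2000 samples so the
   magnitude spectrum has 1000 positive-frequency bins (zero-padding is
   the only reading that reconciles a 256-point window with 1000 bins).
   The frequency axis is converted to period in minutes.
4. **`major_period()`** reports the FFT-peak period of a detrended,
   Hann-tapered segment, zero-padded until the period resolution is
   0.1 min or better across the reportable 2–15 min range, rounded to
   0.1 min (the conventional reporting precision).  Periods above
   10 min are masked from spectrogram band reporting by default because
   such bands are artifacts of the windowed transform on slow records.
5. **`classify_entrainment()`** finds the smallest coprime $p\!:\!q$
   (both $\le 3$) with $p \cdot T_{stim} \approx q \cdot T_{resp}$
   within a 15% tolerance.
6. **`synchronization_index()`** is a Kuramoto order parameter: each
   trace gets an instantaneous phase advancing linearly between
   successive nadirs, and the index is the time-average of the modulus
   of the population's mean unit phase vector.  The definition is this
   package's choice; the original analysis assessed synchrony visually
   from mean traces and spectrograms.

`analyze_group()` chains all stages and reports per-islet periods
before/during pulsing, entrainment modes, and the synchronization index
before/during/after the train, with the windows delimited by the first
and last pulse onsets.

When a ~28-min STFT window is centred near a boundary between regimes it
mixes the two; segment-resolved band readings are therefore taken from
windows centred well inside a segment.

## Synthetic data

`synth_group()` generates groups of surrogate islet recordings with the
statistical structure the pipeline assumes: per-islet sine or
relaxation (plateau/trough, duty cycle 0.5) waveforms with
heterogeneous periods, amplitudes and phases, a linear baseline drift,
additive Gaussian noise, and 20-s sampling — the acquisition interval of
the fluorescence recordings being emulated.  `s2_fixture()` builds the
piecewise variable-frequency validation sinusoid (30-min segments of
period 5, 3, 4 min at amplitudes 30, 50, 20 on a constant background).
`resettable_oscillator_group()` provides cheap phase oscillators whose
phases jump toward a common target at each pulse, for exercising the
synchronization metrics without ODE runs.

What the synthetic data do *not* emulate: photobleaching, motion
artifacts, instrument delivery lag, amplitude rundown, or any coupling
between islets.  Tests passing on synthetic groups demonstrate that the
pipeline recovers known structure; they do not validate the biological
model against real recordings.

## Problem sizes and runtime

The shipped experiments use sizes that keep full runs fast while
preserving the studied behavior: 120 min of model time for the free
period; 50 pulse phases for the PRC (each a ~45-min simulation); three
model islets, 12 pulses over 55 min for periodic entrainment; eight
random pulses with integer gaps of 2–18 min for the non-periodic
protocol, with an hour of post-train simulation so that the decay of
synchrony is visible.  The entire test suite runs in about a minute on
one core.

## Known limitations

* The calibration matches published *behavior*, not published
  *constants*; quantitative details away from the calibrated behaviors
  (absolute concentrations, current magnitudes) should not be
  over-interpreted.
* Pulse resetting in this calibration is moderate (single-pulse phase
  shifts up to ~0.2 of a cycle over most phases).  Randomly spaced
  trains synchronize the population transiently, but with three islets
  the Kuramoto index typically rises by ~0.2–0.3 over its pre-pulse
  value rather than saturating near 1; long (15–18 min) gaps allow
  partial dispersal between pulses.  Stronger resetting calibrations
  proved incompatible with the PRC's delay structure (delays beyond
  half a period wrap) and with monostability (silent-state capture
  after heavy pulsing).
* A single model cell stands in for a whole islet (gap-junction
  coupling within an islet is not modeled), receptor/G-protein/PLC
  kinetics upstream of IP~3~ are collapsed into the square drive, and
  insulin secretion is not modeled.

## A worked example

```{r example, eval = FALSE}
library(isletsync)

# three heterogeneous model islets, unsynchronized, pulsed every 5 min
pops <- make_heterogeneous_population(3, seed = 1)
states <- phase_spread_states(pops)
train <- periodic_train(pulse_profile(rest_time_r = 5), n_pulses = 12,
                        t_start = 1200)
traces <- lapply(seq_along(pops), function(i)
  ca_trace_of(simulate_iom(pops[[i]], train,
                           t_end = max(train$onsets) + 600, dt_out = 1,
                           initial = states[[i]]), every = 20))
g <- trace_group(traces[[1]]$times, lapply(traces, `[[`, "values"))
report <- analyze_group(g, pulse_train = train)
report
```
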