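---
title: "Detecting, classifying and localizing epileptiform discharges on a slice MEA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting, classifying and localizing epileptiform discharges on a slice MEA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ictomap analyzes multi-electrode-array (MEA) recordings of epileptiform
activity in neonatal hippocampal slices: recurrent trains of interictal-like
discharges (IIDs) punctuated by ictal-like discharges (IDs), induced in
vitro by low-Mg^2+^ or high-K^+^ bathing solution. The pipeline answers
three questions about such recordings: *where* does each network discharge
start (CA3a/b or the subiculum), *what* is it (IID or ID), and *how* is the
recurring cycle structure (IID train + one ID + resting period) organized,
overall and across drug epochs. Because public raw recordings of this kind
are scarce, the package ships a synthetic slice-recording generator with
ground truth, and every analytical claim made by the package is exercised
against that generator in the test suite.

## The recording model

The array is an 8x8 grid with the four corners void: 60 electrodes, 30 um
diameter, 200 um pitch. Electrode ids are two-digit column-row codes ("27" =
column 2, row 7), and coordinates place electrode "11" (void) at the origin
with x increasing along columns. A *region map* assigns each electrode to
DG, CA3a/b/c, CA1, Sub, or "none"; it is recording-specific (regions are
identified from the slice photograph), so the package treats it as an input
and ships one canonical fixture map used by the simulator and tests.

Raw data are wide-band voltages (acquisition at 20 kHz). Analysis operates
on the field potential (FP): a 1-100 Hz band-pass followed by decimation to
1 kHz.

## Preprocessing: why second-order sections and why zero phase

The filter is a 4th-order Butterworth band-pass applied forward and
backward. The paper-style analysis chain defines only the band and the
rates; the filter family and the zero-phase requirement are design choices,
made because every downstream quantity is an *onset time* — a causal filter
would delay onsets by a frequency-dependent amount and distort delay maps.
Forward-backward application cancels the phase exactly (the bundled tests
verify that a band-limited pulse peak moves by less than one output sample).

Numerically, the filter is applied as cascaded biquads (second-order
sections) rather than as an expanded 8th-order polynomial. This is not a
stylistic choice: at 20 kHz the normalized band edges are 1e-4 and 1e-2, the
poles cluster against the unit circle, and *any* direct-form implementation
of the expanded polynomial — ours, and reference implementations in other
ecosystems — overflows catastrophically. The zero-pole-gain design (analog
prototype, band transform, bilinear map) comes from the `signal` package;
the pairing of conjugate pole pairs with the band-pass zeros follows the
standard rule of assigning the double zero at z = +1 to the pole pairs
nearest the lower band edge, which keeps every section's intermediate gain
bounded. Edges are handled with odd-reflection padding of several time
constants of the 1 Hz corner plus steady-state initial conditions. The
remaining edge imperfection (reflection inflates local variance in the
first/last fraction of a second) is handled downstream: events whose onset
falls within `edge_guard_s` (0.5 s) of the recording boundary are dropped.

## Event detection

Detection follows the baseline-referenced threshold rule: a channel event is
confirmed when the FP deviates from the baseline mean by more than 4 baseline
SDs of either polarity, and its onset is the first supra-threshold sample.

Two parts of this rule require care that the one-line description hides:

**Baseline selection.** The baseline is a 500 ms stretch free of
discharges. We automate the choice by sliding a 500 ms window in 100 ms
steps and ranking windows by SD. Taking the strict *minimum* SD window is an
extreme-value estimator: the minimum over thousands of overlapping windows
sits ~25% below the true noise SD, which silently lowers the threshold to
~3 sigma and floods the detector with noise events. `estimate_baseline()`
therefore selects the window at the lower *quartile* of the window-SD
distribution (`baseline_quantile = 0.25`): still guaranteed to avoid
discharge-containing windows whenever at least a quarter of the trace is
quiescent (resting periods dominate these recordings), but nearly unbiased
for the noise floor.

**Offsets and merging.** Only the onset is classically defined; durations
(needed for the 5 s IID/ID cutoff) require an explicit offset rule. The rule
is hysteresis plus a quiet gap: an event ends at the last sample at or above
`offset_hysteresis * threshold` (default 0.5) before the signal stays below
that level for at least `merge_gap_s` (default 0.3 s — long enough to unify
multi-component IIDs, short enough to keep successive IIDs seconds apart
distinct). Applied to raw samples this rule never terminates: band-limited
noise crosses a 2 sigma level ~8 times per second (Rice's formula), so a
0.3 s fully-quiet run essentially never occurs. Quietness is therefore
judged on a 50 ms moving-RMS *envelope* of the deviation, which is smooth at
the noise floor and high throughout oscillatory ictal activity. Onset
candidates must also carry envelope support (envelope at or above the
hysteresis level), so isolated single-sample noise crossings can neither
found an event nor — via the merge rule — pre-date a genuine one. Events
shorter than `min_event_s` (20 ms) are discarded.

With the default simulator noise (10 uV raw, ~6 uV in band), this detector
produces no false events on hours of pure noise, recovers isolated event
onsets within 2 samples at 500 Hz, and recovers durations to ~0.1 s.

## Grouping, initiation and origin

Per-electrode events become network discharges by single-linkage chaining on
onset times with a 0.3 s window — the same time scale the field uses to
declare two events independent (see below). On the time line this equals
cutting sorted onsets at gaps larger than the window, and the test suite
checks it against a brute-force transitive-closure oracle. Each discharge
keeps at most one event per electrode (earliest wins) and must span at least
`min_electrodes = 3` electrodes.

One guard augments the chaining: a leading group of fewer than
`min_electrodes` members separated from the rest of the front by more than
`stray_lead_s = 0.1` s is detached. Propagation across the slice takes tens
of milliseconds, so one or two electrodes "leading" the network by hundreds
of milliseconds cannot belong to the same front; without the guard, a rare
noise event landing shortly before a discharge steals its initiation site.

The initiation site is the region of the earliest member electrode (ties:
smallest mean onset delay to the other members, then lexicographic id).
Initiation in CA3a/b defines a CA3-origin discharge; initiation in the
subiculum a Sub-origin discharge; anything else is labelled "other" and
excluded from cycle statistics. For Sub-origin discharges, a CA1 member
onset within `backward_delay_limit_s = 0.3` s contradicts the
no-backward-propagation criterion: the discharge is *flagged* as a
conflicting grouping, never silently relabelled. In practice these flags
mark subicular events fused by the grouping window with a CA3-origin
discharge arriving moments later; since such fusions inherit the other
origin's duration, cycle segmentation excludes flagged discharges by
default.

Classification is by duration at the initiation electrode: events lasting
more than `id_cutoff_s = 5` s are IDs, all others IIDs.

Delay maps report each member electrode's onset relative to a reference
electrode in ms; averaged maps are element-wise means over the discharges in
which an electrode participated, anchored on a common reference (by default
the modal initiation electrode of the origin/class being averaged — which of
the two conventions the original contour plots used is not stated, so the
reference is a per-slice choice and is recorded in the output).

## Cycles and latencies

Per origin, an ID closes the current cycle; IIDs after an ID open the next;
trailing IIDs without a closing ID form an incomplete cycle (reported,
excluded from summaries to avoid censoring bias). Whether IIDs between an ID
and the resting period belong to the closing or the opening cycle is
unspecified in the source analyses; the adopted rule (post-ID IIDs open the
next cycle) is one consistent choice. The resting period of a cycle is the
gap from its ID offset to the next cycle's first onset. Latencies to the
first event of each origin x class are measured from the annotated
solution-application time (an input, not inferred).

## Region parameters and statistics

Per-region event amplitude and duration average the two designated adjacent
electrodes along the pyramidal (CA3, CA1, Sub) or granule (DG) cell layer;
which two electrodes a given study averaged per slice is not recorded, so
the pair is part of the region map and the fixture map fixes one choice.
Frequencies are discharges per minute of epoch duration (the natural unit
when epochs differ in length). Epoch comparisons use a two-sided paired
t-test (two matched epochs) or fixed-effects one-way ANOVA
(control/drug/washout), at alpha = 0.05 with raw p-values (no
multiple-testing correction, matching the source analyses; reports flag
this). Identical matched samples are reported as t = 0, p = 1, and a
constant non-zero paired difference as |t| = Inf, p = 0, since the standard
test is undefined at zero variance.

Western-blot densitometry is processed at the table level: relative level =
target band / beta-actin band of the same sample; each subicular level is
then normalized to the hippocampus-proper (HP) level (HP = 1.0), and HP vs
Sub are compared per protein with a paired t-test across animals.
`simulate_densitometry()` builds a synthetic intensity table (log-normal
intensities, specified true Sub/HP ratios) for testing this workflow.

## The synthetic slice generator

The generator emulates exactly the features the pipeline contracts on, and
nothing more:

* **Two independent origins as renewal processes.** CA3 origin: pacemaker
  electrode "27" (CA3b), propagating anterogradely CA3a/b -> CA1 -> Sub and
  retrogradely CA3a/b -> CA3c -> DG with per-edge delays of 10-15 ms
  (per-edge numbers are not published; tens of ms matches the delay-map
  scale), plus an intra-region conduction delay of 4 ms per 200 um pitch
  (0.05 m/s). Sub origin: pacemaker "83", expressed on subicular electrodes
  only — no backward propagation to CA1 by construction. Overlap between
  the two processes is allowed and left to the grouping stage.
* **Cycle structure.** Per-cycle IID counts are `2 + Binomial(18, 0.344)`:
  support exactly 2-20 and mean exactly 8.19. Resting periods are
  `113 + 391 * Beta(2, 4.098)` s: support exactly 113-504 s and mean exactly
  241.23 s. First-event latencies are uniform over the reported ranges
  (180-290 s CA3-IID, 230-1840 s CA3-ID, 190-250 s Sub-IID, 280-1540 s
  Sub-ID). Within a cycle, IID onsets are 5-10 s apart; the first cycle
  stretches its gaps so the drawn first-ID latency is honoured. Only
  summary moments and ranges of these quantities are published; the
  distribution families are modeling choices, moment-matched once.
* **Waveforms.** IIDs are an area-balanced spike-wave (40 ms negative lobe,
  60 ms positive rebound of equal area) plus a tapered 7 Hz afterburst
  filling the drawn duration; IDs add a sustained 8 Hz tonic-clonic-like
  burst under an attack/release envelope. Area balance and in-band lobes
  matter: an unbalanced or too-slow template acquires large symmetric
  compensation shoulders under the zero-phase 1 Hz high-pass, which would
  smear detected onsets backwards by hundreds of ms. Amplitudes are
  region-specific (CA3-origin: 300 uV in CA3b down to 150 uV in Sub;
  Sub-origin: 180 uV), preserving the reported ordering (CA3-origin
  amplitude in CA3 above Sub-origin amplitude in Sub); CA3-origin IDs are
  longer (10-25 s) than Sub-origin IDs (5.5-10 s) and CA3-origin IIDs
  shorter (0.3-1 s) than Sub-origin IIDs (0.8-2 s), also preserving the
  reported orderings.
* **Drug epochs.** Epoch annotations carry origin x class rate multipliers
  in [0, 1], applied by thinning (0 = abolished). The bumetanide scenario
  zeroes CA3-origin IDs and halves CA3-origin IIDs and Sub-origin IDs; the
  d-AP5 scenario zeroes Sub-origin IDs only.
* **Noise.** i.i.d. Gaussian per sample and channel (default 10 uV), the
  simplest model the SD-based threshold contract needs.

What the generator does *not* emulate — electrode drift, line noise,
non-stationary noise floors, waveform variability within a class, partial
propagation failures, GDP-like developmental events — bounds what passing
tests show: they validate the analysis rules and their interaction, not
robustness to every artifact of real recordings.

## Problem sizes and numerical choices

The recovery experiments simulate 21 slices (matching the reported n) of
2500 s each, generated directly at a 500 Hz field-potential rate with the
1-100 Hz band (the acquisition-rate path, 20 kHz -> 1 kHz, is exercised by
dedicated unit tests on short snippets). These sizes give every slice
several complete cycles per origin while keeping a full cohort tractable on
a single CPU; they are stated here as the package's reference experiment
definition. The drug-epoch experiment uses 2000 s control and drug epochs
and a 1200 s washout (the control epoch still exceeds the longest
first-ID latency, so every epoch contains ictal activity to compare).

Two known small biases of the plain estimators are documented rather than
corrected, because the estimator definitions are part of the contract:
the mean observable resting period in a finite recording is length-biased
low by ~1-3% (the recording end falls preferentially inside long resting
periods, and slices with short resting periods contribute more cycles), and
rare cross-origin superpositions make a few percent of subicular events
undetectable (they are buried inside a CA3-origin ID on the same
electrodes), and a subicular IID starting shortly before a CA3-origin ID
reaches the subiculum can fuse with it into one long subiculum-only event
that classifies as a spurious Sub-origin ID — the conflict flag catches the
within-window case but not this channel-level fusion. Both effects are
visible when comparing recovered values with the generator's configured
means and stay well inside the acceptance bands.

## Determinism

Every stochastic step is seeded: a simulation is bit-identical for an
identical config (including seed), the pipeline is deterministic given a
recording and a config, and cohort experiments derive per-slice seeds from
one master seed. Reports rerun on the same input are byte-identical.
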