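---
title: "Methods: freeze-index, APA and reactive-posture analysis in pfk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: freeze-index, APA and reactive-posture analysis in pfk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfk)
```

pfk implements the biomechanical analysis chain used to assess postural
control in movement-disorder patients under different neurostimulation
conditions: spectral quantification of freezing of gait (FoG) from a lumbar
accelerometer, anticipatory postural adjustment (APA) extraction from
step-initiation force-plate trials, center-of-pressure / center-of-mass
(COP/COM) metrics for support-surface perturbation trials, and
percent-change outcome statistics across stimulation conditions. This
vignette is the package's account of the underlying models, the tunable
parameters, the numerical choices, and what the synthetic-data closed loop
does and does not demonstrate.

## Signal model and shared primitives

Every channel is a `uniform_ts`: one signal sampled at a fixed rate
(200 Hz throughout the protocol defaults), sample *i* at `t0 + (i-1)/fs`.
All intervals (baselines, RMS windows) are half-open `[start, end)` in
seconds, which avoids double-counting boundary samples when windows abut.

**Zero-phase filtering.** Kinematic and kinetic channels are conditioned
with a dual-pass Butterworth low-pass filter: the filter is applied
forward and then backward, cancelling its phase response. The package
reads "dual-pass fourth-order" as a second-order filter per pass
(effective fourth order after both passes), the common biomechanics
convention; `filter_spec(order_per_pass = 4)` selects the alternative
reading. Two numerical choices make the output reproducible bit for bit:

* odd-reflection padding of `3(2n+1)` samples at each end, stripped after
  filtering, and
* steady-state initialization of the filter state for the first padded
  sample (the pre-history of input and output is taken at the DC fixed
  point of the first sample).

Together these give DC gain 1 to machine precision and suppress edge
transients. No cutoff correction is applied by default — the combined
two-pass magnitude is −3 dB slightly *below* the nominal 10 Hz cutoff,
gain exactly 1/2 *at* it — because the protocol states the nominal cutoff
only; `filter_spec(correct_cutoff = TRUE)` pre-warps the design if the
−3 dB convention is wanted.

**Onset detection.** Onsets use the classic baseline-threshold rule: the
first sample at/after the search start whose deviation from the baseline
mean exceeds `k = 2` baseline standard deviations and *stays* beyond the
threshold for `min_hold = 0.05` s (10 samples at 200 Hz). The hold
rejects single-sample noise spikes; the protocol is silent on it, and
0.05 s is short against every physiological latency involved. A
configurable `sd_floor` (default 1e-9 signal units) keeps the threshold
finite on noise-free signals whose baseline SD is exactly zero. Polarity
defaults to the absolute deviation, since force-plate axis signs are
hardware conventions; a signed mode is available.

## Freeze-of-gait index

Within a sliding window (span 7.5 s, the protocol value) of the
vertical lumbar acceleration, the freeze index is the peak spectral power
in the freeze band (3–8 Hz trembling) divided by the peak power in the
locomotor band, with windows whose index exceeds 2 classified as
freezing. The analysis text states both 0–3 Hz and 0.5–3 Hz for the
locomotor band; the package defaults to **0.5–3 Hz** (the band used in
the operative formula sentence, and the one that excludes DC) and leaves
both edges configurable in `band_spec()`.

Windows are demeaned and Hann-tapered before the periodogram. The taper
is a package choice (the protocol is silent): peak-power *ratios* are
meaningful only if spectral leakage from the locomotor tone into the
freeze band is controlled, and the Hann mainlobe/sidelobe trade-off is
the standard one. Frequency resolution is `1/span` ≈ 0.133 Hz. Windows
whose locomotor peak falls below `power_floor` (default `1e-12 ×`
series variance) are flagged invalid rather than producing an unbounded
index — the index is defined *during walking*.

**Event calling and edge refinement.** The window stride (`hop`) is
0.25 s; maximal runs of above-threshold windows become events, each
window accounting for its center ± hop/2, and runs separated by less
than `merge_gap = 0.5` s merge. A 7.5 s window, however, smears episode
edges: the index crosses the threshold when the taper-weighted episode
overlap reaches a level that depends on the trembling/locomotor
amplitude ratio, so pure window-run accounting misstates episode
duration by up to ±2 s depending on episode intensity. `detect_fog`
therefore refines each coarse event against the freeze-band amplitude
envelope: the 3–8 Hz band-passed signal's 0.5 s moving RMS crosses the
half-power level between its quiet and plateau values at the true edge
with no amplitude-dependent bias (squared RMS grows linearly with
episode overlap of the RMS window). On the synthetic generator this
brings the mean absolute duration error of an 8 s episode from ≈1.6 s
(coarse) to ≈0.03 s. `refine_edges = FALSE` restores the coarse
convention.

Gait time comes from trial start/stop marks when the metadata provides
them, else from first/last crossing of a 0.5 s moving-RMS envelope above
the quiet-baseline envelope mean + 2 SD.

## APA metrics

In a step-initiation trial the APA is the mediolateral ground-reaction
force shift toward the supporting leg preceding the step. The trial
starts in quiet stance; the default baseline is the trial's first 1 s
(configurable per trial). APA onset is the 2-SD crossing of the
mediolateral force; step onset is the 2-SD crossing of the
anteroposterior displacement of the stepping-foot malleolus marker,
searched from the APA onset (the step follows the APA, and this stops
baseline jitter from triggering early). Then:

* `apa_duration = step_onset − apa_onset` (s), zero allowed (simultaneous
  crossings), negative flagged invalid rather than clamped;
* `apa_peak_amplitude` = max |ML force − baseline mean| between the two
  onsets, divided by foot length (N/cm). Amplitude is measured as the
  *deviation from baseline* — "amplitude (peak)" is ambiguous between
  absolute force and deviation, and deviation is the quantity the 2-SD
  rule is about.

Trials where either onset is undetectable are flagged invalid and
excluded from subject averages (and logged by the pipeline), never
silently filled.

## Reactive-posture metrics

**COP.** From the six force-plate channels, plate statics give the AP
coordinate of the point of force application:
`COP_ap = −(My + Fx·dz)/Fz + d_ap` (output in cm), with `(d_ap, ·, dz)`
the plate-origin offset. Statics are ill-conditioned at low vertical
load; any analyzed sample with `|Fz| ≤ 50 N` is an error naming the
first offending timestamp rather than a silently wild COP.

**COM.** The sagittal segmental model uses five AP marker coordinates
(fifth metatarsophalangeal, lateral malleolus, knee, greater trochanter,
shoulder axis) and a segment table of mass fractions and COM fractions:
foot 0.0145/0.50, shank 0.0465/0.433, thigh 0.100/0.433 (each counted
twice — one hemibody's markers represent both sides under the symmetric
displacement assumption) and a single head–arms–trunk segment
0.678/0.626 from trochanter toward shoulder. The weighted fractions sum
to 1, which the constructor enforces; the table is explicit, versioned
in code, and overridable (`anthro_model()`), since segment-parameter
editions differ in their third decimal.

**Metrics.** Both series are low-pass filtered (10 Hz dual-pass),
referenced to their own mean over the 1 s of quiet stance immediately
preceding the perturbation onset, and summarized as RMS displacement
over the post-onset window. The analysis window defaults to **2.5 s**:
the platform movement itself lasts 0.95 s under the protocol parameters
and recovery completes within 2–3 s. Neither the window length nor the
RMS reference is stated by the protocol; the pre-perturbation mean is
the natural zero for a "displacement" amplitude, and both are
configurable.

## Outcome statistics

Analysis operates on trial averages per subject and condition (OFF,
60 Hz, 300 Hz). For each ON condition, `%change = (ON − OFF)/OFF` per
subject and variable; the improvement score flips the sign for
variables where a decrease is an improvement (gait time, FoG time, APA
duration, COP/COM RMS) so that improvement is always positive, and
keeps it for APA amplitude. A subject whose OFF value is 0 has an
undefined percent change and is excluded for that variable — this is
exactly the non-freezing-subject case (OFF FoG time 0), which is why
FoG statistics can rest on fewer subjects than the others. Group percent
changes are tested against zero with a one-sample Student's t test
(`t = mean/(sd/√n)`, df = n−1), two-sided by default (sidedness is
unstated; two-sided is conservative), significance at p ≤ 0.05, no
multiple-testing correction by default (an option exists). Degenerate
cells (n < 2 or zero spread) carry an explanatory note instead of a
fabricated statistic.

## Synthetic data: what it emulates, and what it does not

The generators exist so that every stage has inputs with known ground
truth:

* **Walks** — a 2 Hz locomotor sinusoid with freezing episodes that
  *replace* locomotion by a 3–8 Hz tone (default amplitude 3× the
  locomotor amplitude) plus white noise (sd 0.1 m/s²). Replacement
  mirrors halted progression; an additive mode exists for robustness
  testing.
* **Step trials** — a flat noisy force baseline, a half-cosine force
  rise (0.05 s — the APA force onset is abrupt) to the APA peak at the
  APA onset, and a half-cosine foot-displacement rise (0.3 s) at the
  step onset; force noise defaults to 5% of the APA peak and marker
  noise to 0.1 cm.
* **Perturbation trials** — the protocol's trapezoidal-velocity platform
  profile (12 cm, 15 cm/s, 100 cm/s², movement time 0.95 s; onset drawn
  from the 1–3 s preparatory interval), a second-order damped-oscillator
  sway response (1 Hz, ζ = 0.3, shoulder gain 0.25) distributed over
  markers by height, and plate channels constructed by *inverse statics*
  from a target COP (inverted-pendulum lead over the COM), so the
  analyzed COP has an exact known target.

Every generator is a pure function of its arguments and seed.
`simulate_study()` writes a full subject × condition × paradigm tree
whose condition effects mirror the qualitative study pattern
(high-frequency stimulation shortens FoG, gait time and APA duration and
raises APA amplitude; low-frequency and reactive metrics unchanged; two
of four subjects never freeze).

What passing the closed loop shows: the analysis chain recovers known
onsets, episode durations, spectral ratios, COM/COP trajectories and
percent-change tables from signals with the protocol's structure, at
realistic noise levels, without bias beyond the documented tolerances.
What it does not show: validity on real patient data — real FoG
trembling is broadband and non-stationary, real APAs can abort and
re-trigger ("knee trembling"), markers drop out, and plates drift; none
of that is modelled, deliberately (artifact rejection beyond `min_hold`
and multi-APA segmentation are out of scope).

## Problem sizes and runtime choices

Test-suite sweeps use 12–50 seeded replicates per recovery property and
20–60 s trials; the packaged end-to-end study uses 4 subjects × 3
conditions × (3 walks + 10 steps + 3 perturbations), which completes in
a few seconds and is checked byte-for-byte for determinism. These sizes
are chosen to estimate mean recovery errors stably (Monte-Carlo error
well under the tolerances being asserted) while keeping the default
suite fast.

## Known limitations

* The freeze index is a single-axis, stationarity-assuming measure; very
  short (< window) episodes are detected but their duration estimate
  leans entirely on the envelope refinement.
* The COM model is sagittal-only by design; mediolateral metrics and 3-D
  COM are out of scope.
* `one_sample_t` at n = 2 is formally defined but nearly powerless; the
  pipeline reports it (as the study design does for the two freezing
  subjects) rather than suppressing it.
* Percent change is undefined at OFF = 0 and unstable for OFF near 0;
  affected subject × variable cells are excluded and logged, which the
  analyst should read in the manifest.
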