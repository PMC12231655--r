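---
title: "Models and methods behind setms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind setms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind the
package: what each stage computes, the tunable parameters and their
defaults, what the synthetic-data generator does and — just as importantly —
what it cannot demonstrate about real data.

## The experimental logic being modeled

Sensorimotor mu (an alpha-band rhythm over motor cortex) indexes motor
cortical inhibition: when mu is desynchronized, excitability is high.
Predictable auditory beats phase-align cortical rhythms, and beat-locked
intertrial coherence (ITC) of the mu rhythm dips roughly 150–200 ms before
each strong beat and rebounds shortly after it. Sensory entrained TMS
exploits this by firing single pulses at −200 ms relative to strong beats,
inside the low-coherence (high-excitability) window, and quantifies the
effect through peak-to-peak MEP amplitudes against a standard-timing and an
on-beat auditory control condition.

## Stimulus scheduling

* Beats at `60/tempo` s; in duple meter strong beats occupy even indices,
  giving a ~1 s strong-beat period at 120 BPM.
* Metronome tones: 262 Hz, 60 ms long, linear 10 ms rise/fall, weak beats
  at 1/10 amplitude. Ramps are linear because only "rise and fall" is
  specified physiologically; the shape is inaudible at 10 ms.
* Pulse placement steps every k-th strong beat with k drawn per gap from
  {3, 4, 5} (seeded). This satisfies the ≥ 3 s inter-stimulus floor while
  avoiding strict periodicity. The `standard` condition copies the seTMS
  plan's ISI sequence verbatim — the strongest reading of "matched ISIs".
* Musical excerpts are represented only by their beat grids (tempo and
  meter); the analysis consumes beat times, never audio.

## EEG preprocessing

Zero-phase 4th-order Butterworth high-pass (1 Hz) and low-pass (49 Hz),
applied as the squared Butterworth magnitude in the frequency domain over
odd-reflection padding of three high-pass time constants; this is
numerically equivalent to forward–backward time-domain filtering away from
the edges (the time-domain path, `zero_phase_filter()`, is kept as the
reference and the two are compared in the tests). Resampling uses a
zero-phase anti-alias low-pass at 80% of the target Nyquist followed by
linear interpolation. Average re-referencing and beat-locked epoching with
a [−800, +800] ms window — wider than any analysis window so that wavelet
edge effects can be cropped — complete the chain. Artifact-subspace and
ICA-based cleaning are deliberately out of scope: synthetic inputs are
artifact-free by construction, and those steps belong to existing published
pipelines rather than to this package's computation. Continuous data are
filtered before epoching when a continuous recording is supplied; the
epoch-then-filter order used for the synthetic epochs is equivalent here
because the generator's epochs are stationary and reflect-padded.

## Time–frequency decomposition

Morlet wavelets on a linear 6–48 Hz grid (1 Hz spacing) with a **fixed
500 ms window**: a complex exponential under a Gaussian whose ±3 SD support
equals the window, so the cycle count scales linearly from 3 cycles at 6 Hz
to 24 at 48 Hz. The fixed window keeps each beat's representation free of
its ~1 s-distant neighbors. Wavelets are unit-energy normalized; ITC is
invariant to this choice and ERSP is baseline-relative, so the
normalization only sets the absolute power scale. Output coefficients are
decimated to a 10 ms grid (finer than every analysis window) and restricted
to times where the full window fits in the epoch. The FFT implementation is
checked against a direct time-domain convolution to 1e−8.

ERSP uses the "log mean" convention — trial-mean power, then log, then
subtraction of the log mean baseline power over −500…−200 ms per frequency —
with a 1e−20 µV² floor before the log so degenerate zero-power inputs stay
finite. ITC is the plain resultant length of unit phasors across trials;
trials with an exactly zero coefficient at a point are excluded from the
mean at that point.

## Feature extraction and group statistics

The alpha (8–14 Hz, seven bins on this grid) ITC series, averaged over
C5/C3/C1 after per-channel decomposition (maps are computed per channel
first, averaged second), is searched for its lowest local minimum in the
closed window [−222, −99] ms and highest local maximum in [0, 101] ms.
Window-boundary samples count when they dip below their single in-window
neighbor, so the detected value always equals the in-window extremum;
plateaus count once at their center sample; ties break toward earlier
times; a constant series falls back to the earliest sample. The slope is
reported per second (rise over run), with the bare rise as a secondary
column, because "the rise from trough to peak" admits both readings.

Paired and independent t statistics and simple linear regression are
implemented from their closed forms (the package treats them as part of its
contract) and are verified against `stats::t.test()` / `stats::lm()` to
1e−10 in the tests. No multiple-comparison correction is applied, matching
the analysis being emulated.

## MEP quantification

Fixed chain order: baseline correction (−20…−5 ms mean per trial) → RMS
pre-activation rejection (−200…+13 ms omitting the open interval (−5, 5);
one-sided, > block mean + 2.5 block SD, block statistics over *all* trials)
→ biphasic check (both a positive and a negative excursion beyond
k·σ_noise within 15–40 ms, σ_noise from −200…−20 ms; k defaults to 3 and
is exposed because the criterion is qualitative in origin) → single-pass
5 SD amplitude outlier removal over surviving trials → peak-to-peak over
the closed 18–50 ms window. Each trial carries exactly one rejection
reason. Low-RMS trials are never rejected (quiescence is unremarkable),
and outlier statistics are computed after the RMS/biphasic stages, in
narrative order. The absolute pre-pulse EMG mean over −20…−5 ms is emitted
per condition as a parity check but never gated on.

## The synthetic-data generator

### EEG

Each trial's alpha component on the motor channels is the mixture

    s_k(t) = w(t)·sin(2π f_α t) + (1 − w(t))·sin(2π f_α t + θ_k + B_k(t)),

with θ_k uniform per trial and B_k a Brownian phase walk
(`phase_diffusion` = 5 rad²/s, a ~0.4 s phase coherence time typical of
spontaneous mu bursts; the locked part is beat-reset and does not drift).
The mixing profile `w(t)` is periodic at the strong-beat period: each cycle
has a symmetric raised-cosine dip to `w_trough` at the trough time and bump
to `w_peak` at the peak time (half-width = half the trough-to-peak gap) on
a flat mid-level baseline. Periodicity reflects steady-state entrainment —
the epoch edges carry the neighboring beats' cycles, not an arbitrary
plateau — and symmetry keeps the extremum times unbiased under detection.
A beta component with constant mixing and the same walk, plus white
Gaussian noise (optionally 1/f-shaped) with identical statistics on all 16
montage channels, completes a trial. The mu/beta source is shared by
C5/C3/C1 and absent elsewhere, so the average reference attenuates it by
1 − 3/16 instead of cancelling it.

Defaults were chosen once, on realism grounds: alpha amplitude 10 µV, beta
5 µV, broadband noise SD 30 µV, individual alpha frequency 10.5 ± 0.8 Hz,
100 trials per participant.

### The ITC calibration oracle

The generator's contract is that the *measured* trough/peak alpha ITC
match the requested targets. There is no convenient closed form for the
resultant length of the mixture at a finite trial count, so the mapping
from target ITC to mixing level is Monte-Carlo tabulated at the phasor
level (`itc_response()`, fixed internal seed): per alpha bin, the locked
and nonlocked components and the noise are projected through the package's
own wavelets (numerically computed gains, average-reference scale factors
folded in), unit phasors are averaged over the actual trial count, and ITC
is band- and channel-averaged exactly as the pipeline does. Two further
corrections are solved by fixed-point iteration: (a) the wavelet envelope
smooths the mixing profile, so the two knot *levels* are obtained from a
clamp-aware 2×2 linear solve of the smoothed profile at the extremum
times; (b) the extremum search min/max-selects over its window, so a
curve-level Monte-Carlo (`itc_detect_response`, with envelope-autocorrelated
noise, wavelet-overlap cross-bin noise correlation, and the same phase
walk) estimates the *detected* trough/peak values and times, and the knot
levels and positions are adjusted until the detected quantities match the
targets in expectation. All of this is deterministic given the parameters.

### What the finite-trial ITC floor does and does not allow

The resultant length of n independent uniform phasors has expectation
0.886/√n — about 0.089 at the 100 trials used per participant. A
pointwise ITC estimate therefore *cannot* have expectation below ~0.089,
whatever the generator does; detected troughs dip below that only through
min-selection over the search window, which buys roughly another −0.01 on
this pipeline's smooth curves. Three consequences for the default cohort,
all visible in the acceptance suite and deliberate subjects of this
section rather than hidden tuning targets:

* the cohort-mean detected trough ITC lands near 0.075–0.085 rather than
  the 0.06 target — the target sits below the estimator's floor;
* trough *times* are weakly localized (the dip contrast that survives the
  floor is shallow relative to curve noise), so detected times scatter
  across the window with an SD close to the cohort's designed 40 ms spread
  and a few-millisecond edge-attraction bias;
* per-participant trough-to-peak rises are compressed from the designed
  0.05 to roughly 0.025, capping the reliability of the slope *sign* at
  about 75–85% per participant under these conditions; a 26/27 positive
  fraction is therefore reproduced only in expectation, not deterministically.

Raising the trial count (e.g. 500 trials lowers the floor to 0.040, and
the calibration round-trip test runs there) removes all three effects; the
default keeps the emulated study's own 100-trial regime. The same floor
argument applies to the original measurements, which is worth bearing in
mind when comparing small ITC values across studies.

### EMG

Clean trials are a biphasic difference-of-Gaussians template (5 ms lobes
10 ms apart, first lobe centered 5 ms after the 23 ± 2 ms onset latency)
scaled so the template's true peak-to-peak equals a lognormal draw
(CV 0.5 — MEP amplitudes are right-skewed; at 100 trials this gives a
~0.15 mV standard error at the 3 mV scale) on 0.006 mV background noise
(matching reported pre-pulse EMG levels). Artifact trials add tonic
activity at 10× the background RMS up to +13 ms; outlier trials are set to
6× the participant's clean mean (beyond the 5 SD rule even after the
outlier inflates the estimated SD); absent-response trials carry noise
only. Every trial records its true class and amplitude; the analysis chain
never reads them.

### Cohorts

Participant parameters sit at deterministic stratified normal quantiles
((i − 0.5)/N), so the realized cohort mean equals the group mean exactly;
each field gets its own seeded rank permutation, so no participant is
extreme in everything at once. Strictly positive parameters (the MEP
condition means) are stratified on the log scale and rescaled
multiplicatively — normal stratification at the configured SDs would place
participants at negative amplitudes — preserving both positivity and the
exact arithmetic mean. The two ITC levels share one rank permutation so
`trough ≤ peak` holds participant-wise. The `n_inverted_slope` participants
(default 1) have their trough/peak ITC values swapped; the largest-gap
participants are chosen so the inversion stays detectable above the
estimation noise floor. Datasets are materialized participant-at-a-time
(27 EEG datasets at once would occupy ~0.5 GB); the ground-truth tables are
eager and exact.

## Problem sizes and determinism

The replication driver runs 27 EEG participants (100 epochs × 16 channels
× 1.6 s at 1000 Hz each, full 43-frequency decomposition of the three
motor channels) and 19 MEP participants (3 × 125 trials at 5000 Hz) in a
few minutes on one core. Every random draw — cohort layout, per-participant
data, pulse-plan steps — derives from the master seed through fixed integer
arithmetic, and the calibration oracles use their own fixed internal seed,
so identical inputs give bit-identical outputs; the RNG state of the
calling session is always preserved and restored.

## Known limitations

* No volume conduction, scalp topography, auditory-evoked potentials, TMS
  artifacts, or non-stationary amplitude dynamics: passing tests show the
  *analysis chain* is correct and well-calibrated, not that it is robust to
  real-world artifacts (the artifact-handling stages it would rely on are
  out of scope by design).
* The ITC floor analysis above means small-ITC group targets are matched
  only as closely as the estimator's bias allows at 100 trials.
* The biphasic criterion's k·σ operationalization and the lognormal
  amplitude CV are documented choices where the emulated procedures are
  qualitative or unreported; both are exposed as parameters.
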