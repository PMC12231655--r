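# setms

Tools for **sensory entrained TMS (seTMS)** experiments: pairing predictable
auditory rhythms with single-pulse transcranial magnetic stimulation so that
pulses land in the pre-beat window where the sensorimotor mu rhythm is
phase-desynchronized and motor cortex excitability is high.

The package is written for neurophysiologists who want to schedule
beat-locked stimulation, quantify beat-locked oscillatory phase alignment in
EEG, and quantify motor evoked potentials (MEPs) in EMG — and to validate
that whole chain end to end on synthetic data with known ground truth.

## What it computes

**Stimulus side.** Metronome beat grids (strong beats at ~1 Hz for duple
meter at 120 BPM), 262 Hz tone audio with 10 ms ramps and 1/10-amplitude
weak beats, and TMS pulse plans: `setms` pulses at −200 ms relative to
strong beats, `auditory_control` pulses at 0 ms, and `standard` plans that
copy the seTMS inter-stimulus-interval sequence verbatim (all ISIs ≥ 3 s).

**EEG side.** Zero-phase 4th-order Butterworth band-pass (1–49 Hz),
resampling to 1000 Hz, average re-reference, beat-locked epoching; Morlet
time–frequency decomposition on a linear 6–48 Hz grid with a *fixed 500 ms
wavelet window* (3 cycles at 6 Hz, 24 at 48 Hz); event-related spectral
perturbation (dB, log mean baseline at −500…−200 ms) and intertrial
coherence

    ITC(f, t) = | n⁻¹ Σₖ cₖ(f, t) / |cₖ(f, t)| |  ∈ [0, 1],

averaged over the alpha band (8–14 Hz) and the left-motor channels C5, C3,
C1. Per participant the pre-beat ITC **trough** (local minimum in
[−222, −99] ms), post-beat **peak** (local maximum in [0, 101] ms), and
**slope** (rise from trough to peak, per second) are extracted; trough vs
peak ITC is compared with a paired t test.

**EMG side.** The MEP chain: baseline correction (−20…−5 ms), RMS
pre-activation rejection (−200…+13 ms omitting ±5 ms; > mean + 2.5 SD of
the block), a biphasic-signal check in 15–40 ms, single-pass 5 SD amplitude
outlier removal, and peak-to-peak quantification over 18–50 ms; then
per-condition summaries, paired t tests, and percent-change
(`(seTMS − standard)/standard × 100`) statistics.

**Synthetic data.** `gen_eeg_epochs()` emulates beat-locked mu dynamics as a
mixture of a beat-locked and a slowly decohering random-phase alpha
component whose mixing profile dips before each beat and peaks after it;
the mixing levels are calibrated by a finite-trial-count Monte-Carlo oracle
so the *measured* ITC matches the requested targets. `gen_emg_trials()`
builds biphasic MEP templates with lognormal amplitudes plus seeded
artifact/outlier/absent trials, all with ground-truth labels.
`gen_cohort()` places participants at stratified quantiles so cohort means
of the true parameters are exact.

## Worked example

```r
library(setms)

# a 30 s, 120 BPM block with seTMS pulses
sched <- make_beat_schedule(120, 30)
plan  <- schedule_pulses(sched, "setms", n_pulses = 7, seed = 1)
range(plan$isi_s)
#> [1] 3 5

# one synthetic participant's EEG, analyzed end to end
p  <- eeg_params(seed = 1)           # trough ITC 0.06 @ -156 ms, peak 0.11 @ +46 ms
ep <- gen_eeg_epochs(p)
tf <- morlet_transform(rereference_average(ep), channels = c("C5", "C3", "C1"))
alpha <- channel_average(band_average(itc(tf), c(8, 14)))
itc_features(alpha)
#>   trough_time_ms trough_itc peak_time_ms   peak_itc     slope       rise slope_positive
#> 1           -100 0.05304342           70 0.09377341 0.2395882 0.04072999           TRUE

# the MEP arm on a 19-participant synthetic cohort
mep <- run_mep_study(gen_cohort(cohort_spec(n_eeg = 0, n_mep = 19, master_seed = 0)))
mep$condition_summary$mean_p2p
#> [1] 3.076397 2.478611 2.400605    # seTMS, standard, auditory control (mV)
round(mep$setms_vs_standard$t$t_stat, 2)
#> [1] 19.11
```

The trough/peak features above are one participant's noisy estimates — at
100 trials the intertrial-coherence estimator has a resultant floor of
0.886/√100 ≈ 0.089 that compresses values near the bottom of the scale; the
methods vignette (`vignettes/setms-methods.Rmd`) discusses what this does
and does not allow the synthetic cohorts to demonstrate.

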