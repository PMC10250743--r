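---
title: "Methods: benchmarking a textile EEG sensor layer against a dry-electrode baseline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking a textile EEG sensor layer against a dry-electrode baseline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(texeeg)
```

## The problem

Textile ("garment") EEG sensor layers promise wearable brain monitoring,
but their contact impedances are one to two orders of magnitude above the
wet-electrode standard, which raises two empirical questions: do they
record the same spontaneous and movement-related EEG as an established
metal dry-electrode system, and how much more vulnerable are they to mains
pickup and motion artifacts? `texeeg` implements the complete analysis
used to answer those questions on a four-channel forehead montage (F7,
Fp1, Fp2, F8 at 256 Hz, microvolts), plus a seeded synthetic-session
generator so that every stage of the pipeline is testable without any
recordings on disk.

The package follows the two-study design it analyzes:

* an **impedance study** (6 subjects x 4 electrodes x 3 repetitions per
  technology, |Z| at 10 log-spaced frequencies from 0.1 to 30 Hz) for the
  garment, dry and gel ("wet") configurations, and
* an **EEG study** (10 subjects, both headbands in a cross-over order)
  with four tasks: 3 min eyes-closed rest, 3 min eyes-open rest, 80
  cue-guided reaching movements in 4 blocks of 20, and a scripted
  artifact-induction sequence of 9 actions x 10 s.

## Frequency analysis

Resting-state and artifact-induction recordings pass through:

1. **Amplitude-outlier removal** (resting tasks only — during artifact
   induction the artifacts are the measurand): each channel is high-pass
   filtered at 60 Hz (4th-order zero-phase Butterworth), the magnitude of
   the analytic signal (Hilbert envelope) is z-scored per channel, and
   samples more than 5 SD above the mean are replaced in the *original*
   signal by linear interpolation between the nearest clean neighbours
   (nearest-value extension at the edges). Two numerical guards make this
   well-defined on degenerate inputs: z-scoring is per channel (channel
   noise differs by site), and a sample is only flagged when its envelope
   also exceeds `max(0.01 uV, 1% of the channel RMS)` — the z-score is
   scale-free, so a channel with no high-frequency content at all would
   otherwise flag its own filtering residue. Single flagged samples are
   not dilated into windows.
2. **Broadband filtering** 0.1–100 Hz, 4th-order zero-phase Butterworth.
3. **Welch PSD**: 1 s Hamming windows zero-padded to 1024 points
   (0.25 Hz grid at 256 Hz) with 30 ms overlap. The 30 ms figure is
   honored literally — an 8-sample hop overlap, i.e. near-disjoint
   windows; it is configurable (`analysis_config(psd_overlap_s = )`) for
   anyone who prefers a conventional 30 % overlap. Segment periodograms
   are averaged in linear power; `log10` is applied last; power is floored
   at 1e-20 uV^2/Hz so silent channels stay finite; the grid is truncated
   to 0–60 Hz.
4. **Band power**: log power is first averaged over the four electrodes
   per bin (the "average electrode"), then over the bins whose centers
   fall inside delta 0–3, theta 4–7, alpha 8–12, beta 13–30 or the mains
   band 45–55 Hz (inclusive edges; at 0.25 Hz spacing adjacent bands share
   no bins). The mains band acts as an impedance surrogate.
5. **Statistics**: a two-sided paired Wilcoxon signed-rank test per band
   and task, garment vs dry, with direction reported as the sign of the
   median paired difference. The same comparison runs per 10 s artifact
   action (`segment_by_action`).

### Filter realization

"4th-order non-causal Butterworth" is realized as a high-pass/low-pass
cascade of 4th-order single-sided designs, each applied
forward–backward (so the effective magnitude response is the squared
design response and the phase is zero). A single 8th-order band-pass
polynomial with a 0.1 Hz edge at 256 Hz is numerically ill-conditioned in
transfer-function form; the cascade keeps every polynomial at order 4 and
is stable on 3-minute records. Before filtering, the signal is extended
by odd reflection over `3 * fs / f_edge` samples (three time constants of
the slowest edge, capped at the record length), which suppresses
end-of-record transients.

## Time-frequency analysis

Movement recordings are filtered to 0.3–30 Hz, cut into `[-7, 5]` s
epochs around each movement cue (the window is chosen so that the
`[-5, -2]` s baseline always lies inside the preceding rest period, whose
scripted duration is 7 ± 1 s), and trials whose absolute amplitude
exceeds 250 uV on any channel are discarded (strict inequality: a trial
reaching exactly 250 uV is kept). Each surviving trial is convolved with
complex Morlet wavelets on a 5–30 Hz grid at 0.25 Hz. The wavelet cycle
count is fixed at 7 for all frequencies — the analysis source does not
state one, and a constant-Q, 7-cycle kernel is the common choice for
ERD/ERS work; it is exposed as `n_cycles`. Wavelets are L2-normalized;
the absolute power scale cancels in every downstream quantity.

ERD/ERS maps average power over trials *first*, then express each
frequency row as percent change against the mean baseline power
(`100 * (P - P_ref) / P_ref`); per-trial normalization would give
different maps and is not what the averaging order implies. Per-subject
maps are the mean over the four electrodes, and group maps the mean over
subjects, in that order. Samples within one wavelet half-length (5
Gaussian SDs) of an epoch edge are flagged in the result but not
excluded from any statistic — no edge policy is prescribed by the method
being replicated, so the package keeps everything and reports the flags.

The device comparison applies a two-sided paired Wilcoxon signed-rank
test to every time-frequency bin across subjects, with no
multiple-comparison correction, and zeroes the non-significant bins of
the dry-minus-garment difference map. With n = 10 subjects the smallest
attainable two-sided exact p is 2/1024, and the per-bin false-positive
rate at alpha = 0.05 is 50/1024 ≈ 0.049, which the acceptance checks
verify by simulation.

## The Wilcoxon signed-rank implementation

Every comparison in the pipeline funnels through one implementation.
Zero differences are discarded (the classic convention; the alternative
of keeping them, as in Pratt's variant, is not used), ties receive
midranks, and for up to 25 effective pairs the p-value is exact: the
distribution of the statistic over all `2^m` sign assignments is built by
convolution over the doubled ranks, which is arithmetically identical to
full enumeration but costs `O(m^2 (m+1))` instead of `O(2^m)`. Beyond 25
pairs a normal approximation with tie-corrected variance and continuity
correction takes over. The exact cutoff comfortably covers both study
sizes (n = 10 and n = 6). If *all* differences are zero the test is
degenerate and reported as `W = 0, p = 1`. Two-sided p-values double the
smaller tail and cap at 1.

## Impedance model

The measured quantity is |Z| only, so the data model is magnitude curves
on the 10-point log grid. The generator behind the synthetic impedance
study is a single-dispersion Cole interface,

    Z(f) = R_s + R_p / (1 + (i 2 pi f tau)^alpha),

with alpha = 0.8 and tau = 0.16 s by default, which places the dispersion
inside the measured decade. `calibrate_profile()` solves for `(R_s, R_p)`
so that the curve reproduces a pair of measured anchors at 1 and 10 Hz
(garment 368/171 kOhm, dry 110/78 kOhm, wet 3.2/3.05 kOhm) to within
0.5 %: `R_s` follows from the 10 Hz anchor in closed form given `R_p`, and
the remaining scalar equation is solved by bounded root finding. The
printed anchor impedances serve as *calibration inputs* here — the
underlying raw impedance measurements are not available, so they are not
recomputable results, and the simulated study is labelled synthetic
throughout. Measurement spread is a mean-one log-normal factor per
measurement (`sigma_log = 0.2`, a realistic repeatability figure chosen
once) plus a 3 % per-frequency jitter, so the across-measurement average
converges to the anchors. Curve queries between grid points use log-log
linear interpolation (exact for power laws); the 5 kOhm wet-EEG quality
threshold is checked with strict inequality.

## What the synthetic generator emulates — and what it does not

Each synthetic subject is a `subject_profile`: a 1/f background with
one-sided PSD `pink_scale^2 / f^slope` (slope ~1, inter-channel
correlation 0.7 to mimic shared frontal sources), an amplitude-modulated
alpha rhythm (10 ± 0.5 Hz) whose amplitude drops from ~8 uV (eyes closed)
to ~3 uV (eyes open), blink transients during eyes-open (300 ms
raised-cosine pulses, Fp:F amplitude ratio 3:1), and a movement
desynchronization depth `d`. The amplitude modulation has a ~2 Hz
bandwidth, matching the ~1 s waxing-and-waning of real alpha spindles;
this also keeps the injected ERD identifiable at the study's trial
counts (slower modulation makes per-window band power too noisy for the
effect to be recovered from 50–80 trials).

Device profiles differ only where the study found device differences:
the garment profile doubles the 50 Hz mains amplitude (4 vs 2 uV, with
30 % amplitude modulation so the line occupies a few bins of the 45–55 Hz
band, as real mains pickup does) and multiplies scripted artifact
waveforms by 2.5 (vs 1.0). The instrumental white-noise floor (1 uV) is
deliberately identical, so resting band power below 30 Hz differs between
devices only by sampling variability — the calibration target is the
study's significance pattern at n = 10: comparable resting spectra below
30 Hz, garment significantly higher at 45–55 Hz always and across all
bands during artifact induction.

During movement trials the generator scales the *entire* 8–30 Hz content
— the mu/beta rhythms and the matching slice of the 1/f background — by
`sqrt(1 - d)`, so that 8–30 Hz band power drops by exactly the fraction
`d`. Recovery is not perfectly -100*d %: the wavelet and filter skirts
admit a little unmodulated sub-8 Hz background, biasing the recovered
depth ~1–2 points toward zero, and the amplitude modulation leaves a
±2–3 point sampling spread at 50 trials. Both effects are shared by the
real analysis method and are part of what the acceptance checks measure.

Per-action artifact waveforms (slow sways for gross motion, square-ish
ocular deflections, EMG-like 20–90 Hz noise for jaw/tongue, blink trains)
are free parameters chosen for plausibility; they are *not* estimates of
the real per-action amplitudes, and per-action significance patterns from
the generator should not be read as predictions for real data. More
generally, passing tests on synthetic cohorts demonstrates that the
*pipeline* is correct and that the statistics behave as designed — it
does not validate the physiological realism of the generator: no head
geometry, electrode-contact mechanics, non-stationary impedance drift, or
transmission dropouts are modeled.

## Numerical and design choices

* Sample indexing is 0-based in event files (`onset_sample`), exact at
  256 Hz; epoch time axes always contain t = 0.
* Log base 10 throughout; a constant offset cancels in paired
  differences.
* `log10` power floor 1e-20; ERD/ERS maps are bounded below by -100 % by
  construction and the baseline rows average to 0 exactly.
* Butterworth band-passes are high-pass/low-pass cascades (see above);
  `lo_hz = 0` degenerates to a pure low-pass and `hi_hz = Inf` to a pure
  high-pass.
* The 250 uV trial rule uses absolute amplitude ("higher than 250 uV" is
  read as |x| > 250), strict at the boundary.
* Session seeds inside `run_study()` are drawn uniformly under the master
  seed rather than derived arithmetically: Mersenne-Twister streams from
  related seeds stay correlated at matching draw positions, which would
  bias paired device comparisons.
* EDF support is a minimal, self-contained reader/writer (16-bit, one
  common rate, uV/mV/V units, 1 s records) sufficient for interchange
  with standard tools; channel labels are alias-tolerant ("FP1" = "Fp1").
* The end-to-end replica sizes used by the test-suite and the acceptance
  script (e.g. 10 subjects x 3 tasks for the frequency stage, 50 trials
  for ERD recovery, 500 replicates on a reduced 10 x 20 grid for the
  bin-wise null) were chosen as the smallest designs at which each check
  is statistically meaningful.

## Known limitations

* The crossover order (half the cohort starts with the garment headband)
  is recorded as metadata only; synthetic sessions have no order effects.
* No ICA or regression-based ocular correction — outlier interpolation
  and trial rejection are the only cleaning steps, by design.
* The bin-wise map comparison is uncorrected for multiple comparisons
  (again by design, matching the analysis being replicated); its mask is
  exploratory, not confirmatory.
* Exact Wilcoxon p-values above 25 effective pairs switch to a normal
  approximation; at the study's n this path is never taken.
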