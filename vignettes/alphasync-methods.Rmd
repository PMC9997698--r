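---
title: "Long-range alpha synchronization in covert attention: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Long-range alpha synchronization in covert attention: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphasync)
```

## The scientific problem

During covert visuospatial attention (CVSA) — attending to a location
without moving the eyes — parieto-occipital alpha power becomes
lateralized, and frontoparietal alpha-band *phase synchronization* is
thought to carry the top-down signal that installs that lateralization.
`alphasync` implements the full analysis chain needed to study this:
phase-locking value (PLV) connectivity between a fronto-medial electrode
cluster and two lateral parietal clusters, contralateral/ipsilateral
collapsing, alpha-power lateralization indices, Monte-Carlo and
cluster-based permutation inference, and single-trial decoding of the
attended side — together with a synthetic EEG generator so that every
claim-bearing computation can be exercised and validated without any
recorded dataset.

## The synthetic-data generator

`sim_config()` / `simulate_epochs()` emulate a Posner-cueing EEG session:

* **Trial design.** Attended sides balanced to within one trial; the
  target appears at the cued side with probability 0.75 (cue validity);
  the cue-to-target interval is uniform on 2000 ± 500 ms. The uniform
  jitter law is our choice — only the "± 500 ms" envelope is specified by
  the task design. Default 290 trials per simulated participant.
* **Behavior.** Detection and discrimination are conditionally
  independent given attention, each with probability `sqrt(rate)`, so
  that their conjunction — a correct trial — occurs at the configured
  rate (0.68 valid / 0.46 invalid by default). A uniform-random responder
  is correct on 25% of trials, the chance level all performance tests
  refer to.
* **EEG.** Every channel carries 1/f background noise (spectral
  synthesis, default exponent 1, RMS 5 µV). Parieto-occipital channels
  add a 10 Hz (configurable IAF) oscillation whose amplitude is
  7 µV on the hemisphere contralateral to attention and 10 µV
  ipsilateral — the classic contralateral suppression, ratio 0.7. The
  fronto-medial cluster carries an alpha component that acts as the phase
  reference: each parietal cluster's phase lag to it is drawn per trial
  from a von Mises distribution with concentration `kappa_contra`
  (contralateral network, default 2) or `kappa_ipsi` (ipsilateral,
  default 0.5).

The von Mises lag model was chosen because its mean resultant length has
the closed form \(I_1(\kappa)/I_0(\kappa)\), which is exactly the
large-\(n\) expectation of cross-trial PLV — an analytic oracle the test
suite checks the whole generator → wavelet → PLV path against (observed
agreement at \(\kappa = 2\): better than 0.01 at 300 trials).

Optional per-sample phase jitter (`sample_jitter_kappa`) extends the
model to cross-time coupling; it is off by default because the wavelet's
temporal smoothing attenuates i.i.d. per-sample jitter and would bias
the cross-trial oracle. A `coupling_window` confines the coupling to a
time window (with 100 ms cosine ramps), which is how time-limited
post-target effects are planted; because the 5-cycle wavelet at 10 Hz
has \(\sigma_t \approx 80\) ms, planted windows are kept at least
\(\sim\)250 ms away from windows that must stay null.

What the generator does **not** emulate: volume conduction (no head
model), ocular or muscle artifacts (beyond optional amplitude spikes for
testing the rejector), non-stationary alpha bursts, or heterogeneous
channel noise. Passing tests therefore demonstrate the *correctness of
the computations* under the stated statistical structure, not that real
EEG satisfies that structure.

## Preprocessing

`condition_signal()` demeans, notches 50 Hz (biquad, Q = 35) and
band-limits 0.16–45 Hz with 5th-order high-pass and 16th-order low-pass
Butterworth filters, each applied forward and backward for zero phase
lag. The filters are realized as cascaded second-order sections: a flat
16th-order transfer function with a 45 Hz cutoff at 500 Hz sampling is
numerically unusable, while the SOS cascade is exact and stable (the
low-order case is cross-checked against `signal::butter` in the tests).
The quoted orders are interpreted as one-pass design orders; two-pass
application doubles the effective attenuation.

EOG-based trial rejection uses the peak absolute demeaned amplitude
within the epoch and a *strict* 50 µV rule (a deflection of exactly
50 µV is kept) — the amplitude measure is our choice, the strict
inequality follows the rejection rule's wording. Bad channels are
repaired by inverse-distance-weighted neighbor averaging on the montage
graph rather than spherical splines: simpler, dependency-free, and
sufficient for synthetic fixtures. `hjorth_laplacian()` provides the
local surface-Laplacian control re-reference. Analysis windows are
half-open `[start, end)` in ms throughout.

`epoch_mirror()` prepends and appends a full time-reversed copy of each
epoch before the wavelet transform and `epoch_trim()` restores the
original axis exactly; with mirroring, edge power for a pure tone stays
within 10% of center power versus a >50% droop without it.

## Time-frequency decomposition

`morlet_transform()` convolves with complex 5-cycle Morlet wavelets
(\(\sigma_t = n_c / 2\pi f\)) on the canonical 16-point log-spaced grid
from 2.6 to 42 Hz. The kernel is peak-normalized in the frequency
domain, so a unit tone at center frequency yields an envelope of 0.5 —
the analysis-gain constant; only ratios and phases are claim-bearing.
The upper-alpha analysis band is taken as printed (9.54–14.31 Hz, grid
members ≈ 9.52, 11.47, 13.80 Hz) rather than re-derived, since the
printed edges do not coincide with the stated grid formula.

IAF estimation follows the Welch route: 1000 ms Hann segments, overlap
equal to 10% of the segment, zero-padded to 0.25 Hz resolution,
channel-averaged over the parieto-occipital set, normalized by mean
1–40 Hz power, and searched for the largest local maximum in 5–15 Hz. A
spectrum without an interior peak raises an explicit no-peak error so
the participant can be flagged instead of silently defaulted. The
task-period alpha band around the IAF is `{IAF−1, IAF, IAF+1}` Hz.

## Connectivity

Cross-trial PLV is the modulus of the mean unit phase difference across
trials. Network PLV averages the *moduli* of the nine FM–parietal pair
PLVs — modulus first, then pair mean; the alternative order (complex
mean first) is constructed and rejected in a test. Collapsing:
contralateral = mean of FM-PR|attend-left and FM-PL|attend-right;
ipsilateral the mirror image. Window values average samples within the
half-open window and then the band frequencies (the two rectangular
means commute; covered by a test). ISPC (`plv_cross_time()`) runs the
same statistic across time samples within a trial, giving the
single-trial features; PLM reports the fraction of the interferometric
signal's spectral power within ±1 Hz of DC.

## Inference

The PLV permutation test reassigns attended-side labels (preserving
condition counts, which keeps the PLV small-sample bias identical under
the null), recomputes the full pair → network → collapse → window
pipeline per iteration, and reports the one-tailed
`p = #{surrogate > observed}/n_iter` with the strict inequality; the
minimum reportable p (`1/n_iter`) is attached, and an add-one smoothed
estimator is available behind `smooth = TRUE`. The group test averages
surrogate distributions across participants iteration by iteration.
Type-I error, measured over 300–500 null datasets in the tests and
acceptance script, sits inside [0.03, 0.07] at nominal 0.05.

The cluster-based test thresholds samplewise one-tailed t statistics at
the critical value at α = 0.05 (independent-samples t at the individual
level, sign-flip one-sample t on paired differences at the group level),
forms temporally contiguous clusters, and compares observed cluster
masses against the permutation null of the maximum mass. Family-wise
error measured on nulls is ≈ 0.046; a planted 160 ms effect at d = 1
with 290 trials is recovered essentially always at 2000 randomizations.

## Lateralization index

\(LI = (\alpha_{PR} - \alpha_{PL}) / \tfrac{1}{2}(\alpha_{PL} +
\alpha_{PR})\), negative when left-hemisphere alpha dominates, bounded
in [−2, 2]. The denominator is read as the mean of the two side-averaged
powers (the standard LI form consistent with the sign convention).
Trial-level LI is computed from trial-level power and then averaged; the
alternative order is available through the per-condition summaries.

## Decoding

Ten features per trial: ISPC of each frontoparietal network in each of
the five 200-ms cue-to-target bins (500–1500 ms), upper-alpha averaged.
The RBF-SVM cost and gamma are explored on a log grid from 10⁻⁶ to 10³
(one point per decade by default) on a nested 80/20 sub-train/validation
split inside each of 10 stratified cross-validation folds; the smallest
(cost, gamma) attaining the maximal validation accuracy is selected.
Splits are stratified (the analysis trial selection otherwise skews
folds) and keyed to trial ids, so row order is irrelevant. Baselines:
shrinkage LDA on the same features (analytic shrinkage toward the
scaled identity) and Riemannian minimum-distance-to-mean on per-trial
band-limited channel covariances (regularized by `1e-10·trace·I`),
with the affine-invariant metric and Karcher means.

A genuinely null decoding cohort must plant *neither* coupling nor
amplitude asymmetries: an amplitude imbalance alone is decodable
through its effect on single-trial phase SNR (we measured ≈ 0.81
accuracy from the default 0.7 suppression ratio with equal coupling).

## Problem sizes and numerical choices

The test suite and the acceptance script run the study conditions at
reduced but statistically adequate sizes chosen by us: 300 trials for
Bessel-ratio recovery (tolerance \(3/\sqrt{n}\)), 300–1500 null
datasets for calibration rates, 100 seeds for sign-recovery properties,
120 trials for decoding (95% binomial band ±0.09), five simulated
participants for the end-to-end pipeline. Degenerate inputs error
explicitly (fewer than two trials per condition, empty trial selection,
zero variance, zero total power, no spectral peak, unrepairable
channels). All stochastic stages take explicit seeds and are
bit-reproducible; permutation draws are chunked so memory stays flat at
the full 10⁵-randomization setting.

## Known limitations

Phase estimates near epoch edges rely on mirror padding, which assumes
locally stationary oscillations; the surrogate-averaging group test
assumes a shared iteration count across participants; the Hjorth
re-reference is montage-graph based, not a spherical-spline Laplacian;
and, as stressed above, conclusions about real EEG transfer only to the
extent that the generator's statistical assumptions hold.
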