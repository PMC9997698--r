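# alphasync

Analysis tools for **long-range alpha-band phase synchronization in
covert visuospatial attention (CVSA) EEG**, aimed at researchers asking
whether frontoparietal phase coupling carries a direction-specific
attention signal — and whether that signal survives at the single-trial
level needed for a brain-computer interface.

During covert attention shifts, parieto-occipital alpha power becomes
lateralized and frontal–parietal alpha phase coupling is hypothesized to
increase contralaterally to the attended hemifield. The package
implements the complete chain used to test this:

* **Phase-locking value (PLV)** between a fronto-medial electrode
  cluster (Fz, FC1, FC2) and left/right parietal clusters:

  PLV(x, y) = | (1/n) Σₖ exp(i(φₓ(k) − φᵧ(k))) |

  computed across trials per frequency and time sample, averaged over
  the 9 electrode pairs of each network, and collapsed into
  contralateral/ipsilateral time courses. Cross-time variants — ISPC
  (the same statistic across time within a trial) and PLM (phase
  linearity measurement) — support single-trial analyses.
* **Interhemispheric alpha-power lateralization**:
  LI = (α_PR − α_PL) / mean(α_PL, α_PR), with the analysis band centered
  on the individual alpha frequency (IAF) estimated from a resting Welch
  PSD.
* **Inference**: one-tailed Monte-Carlo permutation tests of the
  contra−ipsi PLV difference (label shuffles preserving condition
  counts; group level by surrogate-distribution averaging) and
  cluster-based permutation tests over the LI time course.
* **Decoding**: RBF-SVM classification of the attended side from ten
  ISPC features (two networks × five 200-ms cue-to-target windows), with
  nested 80/20 hyperparameter optimization over a 10⁻⁶…10³ log grid,
  stratified 10-fold cross-validation, and shrinkage-LDA / Riemannian
  minimum-distance-to-mean baselines.
* **A synthetic EEG generator** (`sim_config()`, `simulate_epochs()`)
  with von Mises frontoparietal phase coupling — whose cross-trial PLV
  has the analytic expectation I₁(κ)/I₀(κ) — plus 1/f background and
  contralateral alpha suppression, so every stage is testable without
  recorded data.

Standard preprocessing is included: zero-phase Butterworth band-limiting
(SOS cascades), 50 Hz notch, strict 50 µV EOG trial rejection,
inverse-distance channel repair, mirror padding for edge-free wavelet
transforms, and a Hjorth-Laplacian control reference.

## Worked example

Simulate one participant with planted contralateral coupling
(κ_contra = 2, κ_ipsi = 0.5), keep validly cued correct trials, and test
the contra−ipsi difference:

```r
library(alphasync)

cfg <- sim_config(n_trials = 80, kappa_contra = 2, kappa_ipsi = 0.5,
                  epoch_start = -0.5, epoch_end = 1.5, seed = 42)
trials <- simulate_behavior(design_trials(cfg), cfg)
keep   <- select_trials(trials)              # valid AND correct: 39 of 80
epochs <- subset_epochs(simulate_epochs(trials, cfg), trials = keep,
                        channels = c("Fz","FC1","FC2","P3","PO3","PO1",
                                     "P4","PO4","PO2"))
bank <- morlet_bank(upper_alpha_subset(make_frequency_grid()), 5, 500)
tens <- morlet_transform(epochs, bank)       # mirror-padded Morlet
coll <- collapse_contra_ipsi(network_plv(tens, trials[keep, ]))
window_average(coll, list(early = c(0, 500), late = c(500, 1000)))
#>   window laterality   plv
#> 1 early  contra     0.622
#> 2 early  ipsi       0.384
#> 3 late   contra     0.613
#> 4 late   ipsi       0.421

perm <- plv_permutation_test(tens, trials[keep, ],
                             windows = list(win = c(0, 1000)),
                             n_iter = 1000, seed = 1)
tidy(perm)
#>   window observed     p p_min
#> 1 win       0.215 0.039 0.001
```

The contralateral network is more phase-locked than the ipsilateral one
(0.62 vs 0.38–0.42), as planted; the permutation test puts the observed
contra−ipsi window difference of 0.215 above the 96th percentile of the
label-shuffled null (p = 0.039, minimum reportable p = 1/1000). With
κ = 2 the generator's analytic cross-trial PLV is
I₁(2)/I₀(2) ≈ 0.698; the measured 0.62 reflects the 39-trial sample and
background noise.

Higher-level drivers `run_target_locked()` / `run_cue_locked()`
orchestrate whole simulated cohorts (preprocessing → selection →
transform → PLV → permutation tests → group inference, plus exploratory
frequency maps, the LI reality check and the decoding branch) from one
`analysis_config()`, and `make_report()` serializes results to JSON.
Fitted-result classes have `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` figures.

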