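---
title: "Resting-state EEG microstate analysis with msdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state EEG microstate analysis with msdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msdyn)
```

## The model

Eyes-closed resting EEG spends most of its time in one of a handful of
quasi-stable scalp potential topographies — *microstates* — each lasting a
few tens of milliseconds before switching abruptly to another. The analysis
implemented here decomposes a multichannel recording into a small set of
template maps and a label sequence, then summarises each class by

* **occurrence** — segments per second (1/s),
* **coverage** — percent of the analysed period spent in the class,
* **duration** — mean dwell time per segment (ms),
* **GEV** — the GFP²-weighted fraction of topographic variance the template
  explains.

Three modelling conventions run through everything:

1. **Polarity is ignored.** A topography and its sign-flipped twin arise
   from the same source configuration under an oscillating generator, so
   every comparison uses the absolute spatial (Pearson) correlation across
   channels, and template estimation uses the dominant eigenvector of the
   assigned maps' cross-product matrix rather than an average, which would
   depend on an arbitrary sign alignment.
2. **Clustering sees only GFP peaks.** The global field power — the spatial
   standard deviation across channels (population form) — peaks at the
   moments of highest topographic signal-to-noise; only those maps enter the
   clustering. Back-fitting then labels *every* sample.
3. **Average reference.** Topographies are compared in the space where the
   instantaneous channel mean is zero; `average_reference()` is idempotent
   and applied before any map comparison.

## The pipeline

`run_full_study()` chains the stages exactly as a two-group clinical study
would run them:

1. *Preprocess*: optional montage reduction, zero-phase Butterworth
   band-pass (order 4; 1–40 Hz by default), anti-aliased downsampling
   (zero-phase Chebyshev-I anti-alias filter at 0.8 of the new Nyquist, then
   spline evaluation on the new grid; 125 Hz by default), average reference.
   Bad channels can be rebuilt by spherical-spline interpolation (order
   m = 4, Legendre expansion truncated at degree 7, ridge 1e-5) when
   electrode positions are available. There is no automatic artifact
   rejection: the analysis window is a per-subject configuration choice,
   as visual artifact screening is not an algorithmic step.
2. *Subject-level clustering*: polarity-invariant modified k-means
   (`modified_kmeans()`) on each subject's GFP-peak maps. Assignment
   maximises squared spatial correlation; templates are re-estimated as
   dominant eigenvectors; convergence is an assignment fixed point or a GEV
   change below 1e-8; the best of `n_restarts` seeded random initialisations
   by GEV wins. Empty clusters are re-seeded from the worst-fitted map.
3. *Group and global clustering*: subject template maps are pooled and
   re-clustered (`multilevel_clustering()`), once per group and once across
   all participants; the global set is what gets back-fitted to everyone.
4. *Back-fitting and smoothing*: winner-takes-all labelling of every sample
   (`backfit_labels()`; ties go to the lower class index; zero-variance
   samples inherit the previous label), then Besag-factor temporal smoothing
   (`smooth_labels()`, window half-size b = 3 samples, strength λ = 10).
5. *Statistics*: per-class Mann–Whitney tests with BH-FDR per parameter
   family, Levene variance checks, Spearman correlations of significant
   parameters with clinical scores, and Hanning-windowed alpha-band power.

## Choosing the number of maps

No single cluster-validity index is reliable for topographic data, so
`choose_k_meta_criterion()` lets a bank of criteria vote and takes the
median vote (ties toward the smaller K). The default bank contains seven
criteria adapted to the polarity-invariant geometry (dissimilarity
`sqrt(1 - r²)`): the GEV elbow, the cross-validation criterion (residual
variance inflated by `((C-1)/(C-1-K))²`), Krzanowski–Lai, Calinski–Harabasz,
Davies–Bouldin, mean silhouette, and the within-dispersion elbow. The bank
is a design choice validated by planted-K recovery on synthetic cohorts
(the suite plants 4 and 5 maps and requires the vote to find them); the
median-vote combination makes the selection robust to any single criterion
misfiring. On clean synthetic data at SNR 10 the vote is typically
unanimous.

## The smoothing objective

`smooth_labels()` iteratively minimises, per sample,

```
cost(k, t) = d²(k, t) / (2 e (C − 1)) − λ · N(b, k, t)
```

where `d²(k, t)` is the squared residual of the (centred) sample under
template k, `e` the residual noise variance of the current labelling
(recomputed each sweep), `C` the channel count, and `N(b, k, t)` the number
of samples within `t ± b` (excluding t itself) currently labelled k. The
misfit term scales with the sample's energy, so low-GFP samples — where the
topography is mostly noise — are exactly the ones the neighbourhood bonus
can recruit into the surrounding segment. `λ = 0` reproduces the plain
winner-takes-all labelling; sweeps are synchronous and stop at a fixed point
or after `max_iterations`. The function takes the recording and model (not
just the label sequence) because the objective needs the full per-class
misfit, not only the winning correlation.

## Temporal parameters and boundary runs

The first and last segments of a window are truncated, which biases dwell
estimates. `temporal_parameters()` therefore defaults to `"mixed"` counting:
edge runs count toward occurrence and coverage but not toward the duration
average. `"inclusive"` counts them everywhere, in which case the exact
conservation identity

```
occurrence_k × duration_k / 1000 = coverage_k / 100
```

holds per class, and coverages always sum to 100%. Duration is summarised by
the **mean** run length (the field convention, and the only choice under
which the identity above is exact); median and mode are available via
`duration_stat`. GEV per class is `Σ GFP²·r² / Σ GFP²` over the samples the
class owns, so the class values add up to the total by construction.

## The statistics layer

Group comparisons use the Mann–Whitney U (midrank ties, tie-corrected
normal approximation with continuity correction — the form that yields the
U/Z/p triples clinical tables report) rather than t-tests, since variance
homogeneity across groups often fails for microstate parameters (the
package includes `levene_test()`, an ANOVA on absolute deviations from the
group mean, to check). FDR correction is Benjamini–Hochberg step-up applied
**within one parameter's family of K class-wise tests** (m = K), not across
all parameters at once: applied to published uncorrected rows this family
definition reproduces the published corrected rows to their printed
precision, which is how the convention was fixed. Spearman correlations use
Pearson on midranks with the t approximation. Alpha power is a Welch-style
average of Hanning-windowed periodograms (2 s windows, 50% overlap,
configurable), normalised so the spectrum sums to the mean square amplitude.

## What the synthetic generator does and does not emulate

`simulate_cohort()` builds two groups of subjects from `k_true` planted
template maps (random orthonormal, zero-mean channel vectors), a first-order
Markov label chain with geometric dwells matching `mean_dwell`, and a
carrier `x_t = map · a_t + noise`, where `a_t` is an alpha-frequency
sinusoid with per-segment random phase and polarity and the noise is
spatially white Gaussian at the requested RMS signal-to-noise ratio. The
patient group multiplies the class-1 entry probability by
`1 + group_effect` (the remaining mass is redistributed over the other
classes), which at the default +35% raises class-1 occurrence by roughly
25–30% once the stationary distribution settles.

Defaults are the study conditions the pipeline is meant to detect: 17
subjects per group, 125 Hz, 120 s per subject, five maps, 80 ms mean dwell
(realistic for resting microstates), alpha carrier at 10 Hz, SNR 5. Tests
use 32 channels — the clustering mathematics is channel-count-agnostic — and
a 204-channel montage is one argument away.

What it deliberately does **not** emulate: correlated template maps (real
microstate topographies correlate at |r| up to ~0.5–0.7; orthogonal maps
make identifiability clean, so recovery tests are upper bounds on real-data
performance), biophysical forward models, 1/f background spectra, artifacts
(blinks, ECG, muscle), and non-stationarity of dwell statistics. Passing the
planted-recovery suite therefore shows the algorithms are correct, not that
every real recording will yield a five-map solution.

## Numerical choices and degenerate inputs

* Correlation of a zero-variance map is an error everywhere except in
  back-fitting, where a flat sample inherits the previous label (class 1 if
  first) with correlation 0.
* Plateau GFP peaks take their first sample; peak detection excludes
  endpoints.
* Winner-takes-all ties resolve to the lowest class index — deterministic
  and seed-independent.
* All randomness (initialisations, generator draws) flows through explicit
  seeds; `run_full_study()` expands one master seed into per-stage child
  seeds and records them in the provenance block, so re-runs are
  byte-identical.
* k-means restarts default to 100 for standalone use; the pipeline defaults
  to 20 (subject) / 50 (global), a speed–quality trade-off that planted-map
  recovery shows to be ample for this problem size.
* The replicate-cohort power and null simulations in the test-suite and
  acceptance script run on the generator's true-label temporal parameters
  (`simulate_cohort(recordings = FALSE)`): they measure the statistics
  layer's operating characteristics at the planted effect size; the full
  EEG path (synthesis → clustering → back-fit → stats) is exercised
  end-to-end on one cohort of 34 subjects.

## A worked example

```{r example, eval = FALSE}
spec <- synthetic_spec(n_channels = 32, duration = 120, snr = 10, seed = 11)
cohort <- simulate_cohort(spec)
res <- run_full_study(cohort, study_config(band = NULL, target_fs = NULL,
                                           subject_k = 5, global_k = "auto",
                                           seed = 3))
res$chosen_k          # number of maps selected by the criterion vote
res$table2            # parameter-by-class group comparison with FDR
res$correlations      # Spearman follow-up on the significant parameters
```

## Known limitations

* Class letters attached by `canonical_templates()` are procedural
  idealisations of the classical topographies (gradients and focal maxima
  over the montage); they order and name maps for reporting but carry no
  anatomical claim, and never influence the fit.
* EDF support covers the standard 16-bit variant with a shared sampling
  rate; EDF+ annotations are ignored.
* No artifact rejection: recordings are assumed cleaned, with the analysis
  window supplied per subject.
* The smoothing objective assumes the template set already explains the
  data well; with grossly misspecified K the noise-variance estimate `e`
  inflates and smoothing becomes conservative.
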