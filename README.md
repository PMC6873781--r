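# msdyn — resting-state EEG microstate dynamics

`msdyn` segments multichannel resting-state EEG into **microstates** — the
few quasi-stable scalp potential topographies that eyes-closed EEG cycles
through on a sub-100 ms time scale — and compares their temporal dynamics
between two clinical groups. It is aimed at EEG researchers who want the
complete, reproducible chain from raw recordings to the group-statistics
tables of a patients-versus-controls microstate study.

## What it computes

For a recording `X` (channels × samples, average-referenced), the global
field power `GFP(t)` is the spatial standard deviation across channels. The
scalp maps at GFP peaks are clustered by a **polarity-invariant modified
k-means**: maps are assigned to the template `a_k` maximising the squared
spatial correlation `r²(x_t, a_k)`, and each template is re-estimated as the
dominant eigenvector of its assigned maps' cross-product matrix, so that
`x` and `−x` are equivalent throughout. The number of maps K is chosen by a
seven-criterion vote (GEV elbow, cross-validation criterion, Krzanowski–Lai,
Calinski–Harabasz, Davies–Bouldin, silhouette, dispersion elbow). Subject
maps are pooled and re-clustered per group and globally; the global maps are
back-fitted to every sample (winner-takes-all on `|r|`) and smoothed with
the Besag-factor scheme (window half-size b = 3, strength λ = 10). Each
class k is then summarised by

- occurrence (segments/s), coverage (%), mean duration (ms),
- `GEV_k = Σ_{t: L_t=k} GFP_t² r_t² / Σ_t GFP_t²`,

and the groups are compared per parameter and class with Mann–Whitney U
(tie-corrected normal approximation, Z and two-sided p), Benjamini–Hochberg
FDR within each parameter's family of K tests, Levene variance checks,
Spearman correlations with clinical scores, and Hanning-windowed alpha-band
(8–14 Hz) power.

A synthetic cohort generator (`simulate_cohort()`) plants known template
maps, Markov-chain label sequences and a group effect, so the whole pipeline
is testable end to end without any data download.

## A worked example

```r
library(msdyn)

spec   <- synthetic_spec(n_channels = 32, duration = 120, snr = 10, seed = 11)
cohort <- simulate_cohort(spec)           # 17 patients + 17 controls
res <- run_full_study(cohort, study_config(band = NULL, target_fs = NULL,
                                           subject_k = 5, global_k = "auto",
                                           seed = 3))
res
#> <study_result> 34 subjects, global K = 5, mean GEV = 0.953
#>   group comparison (p_fdr < 0.05):
#>   parameter class         Z        p_fdr
#>  occurrence     A -2.102502 3.550937e-02
#>  occurrence     B  4.962903 3.472370e-06
#>  occurrence     C -2.225010 3.260071e-02
#>  occurrence     D -2.534506 1.876769e-02
#>  occurrence     E -2.895027 9.478162e-03
#>    coverage     A -2.549016 1.490533e-02
#>    coverage     B  4.959869 3.527044e-06
#>    coverage     C -2.135499 3.272027e-02
#>    coverage     D -2.514378 1.490533e-02
#>    coverage     E -3.203493 3.394281e-03
```

The generator planted a +35% entry-rate increase for one class in the
patient group; the run above selects K = 5 by the criterion vote, recovers
all five planted maps (absolute spatial correlation > 0.999 against the
ground truth in `cohort$templates`), and flags that class — tagged B in this
run; which letter the random planted map lands on depends on its match to
the canonical labelling templates — as strongly increased in patients
(positive Z), with the mirror-image decreases in the remaining classes that
a boosted entry rate forces on a sequence whose total switching rate is
fixed. `res$table2` holds the full
parameter-by-class table (group means ± sd, U, Z, p, FDR-corrected p),
`res$stats_table` the per-subject parameters it was computed from, and
`res$provenance` the seeds and configuration needed to reproduce every
number.

Single steps are available as plain functions: `read_recording()`,
`bandpass_filter()`, `resample_recording()`, `interpolate_channels()`,
`compute_gfp()`, `detect_gfp_peaks()`, `modified_kmeans()`,
`choose_k_meta_criterion()`, `multilevel_clustering()`, `backfit_labels()`,
`smooth_labels()`, `temporal_parameters()`, `global_explained_variance()`,
`compare_groups()`, `correlate_clinical()`, `alpha_band_power()`.

## Documentation

The methods vignette (`vignettes/microstate-analysis.Rmd`) describes the
model, the smoothing objective, the K-selection vote, boundary-run handling,
what the synthetic generator does and does not emulate, and the package's
numerical conventions.
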