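Package: msdyn
Title: Resting-State EEG Microstate Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segmentation of multichannel resting-state EEG into microstates:
    global field power (GFP) peak extraction, polarity-invariant modified
    k-means clustering of scalp topographies, data-driven selection of the
    number of maps by a multi-criterion vote, multilevel (subject, group,
    global) map derivation, winner-takes-all back-fitting with Besag-factor
    temporal smoothing, and extraction of per-class occurrence, coverage,
    mean duration and global explained variance. Includes the nonparametric
    group-statistics layer used in clinical microstate studies (Mann-Whitney
    U with tie-corrected normal approximation, Benjamini-Hochberg false
    discovery rate control per parameter family, Spearman clinical
    correlations, Levene variance checks, Hanning-windowed alpha-band power)
    and a synthetic two-group cohort generator with planted template maps and
    Markov-chain microstate sequences for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
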