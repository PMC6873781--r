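#' Configuration for a full study replica
#'
#' Collects every tunable of the pipeline in one place so a study run is a
#' single reproducible call. Values mirror the conventional resting-state
#' protocol: 1-40 Hz band-pass, 125 Hz analysis rate, average reference,
#' smoothing window half-size 3 samples with Besag factor 10.
#'
#' @param band band-pass edges in Hz, or `NULL` to skip filtering
#' @param target_fs resampling target in Hz, or `NULL` to keep the input rate
#' @param reref re-reference to the common average before analysis
#' @param exclude_channels channel names dropped before analysis (montage
#'   reduction)
#' @param analysis_window optional `c(start, stop)` in seconds
#' @param subject_k number of maps per subject, or `"auto"` for the
#'   multi-criterion vote per subject
#' @param global_k number of maps at group/global level, or `"auto"`
#' @param candidate_ks K range searched when a level is `"auto"`
#' @param n_restarts_subject,n_restarts_global k-means restarts per level
#' @param smooth_b,smooth_lambda temporal smoothing parameters
#' @param boundary_mode run-counting mode for [temporal_parameters()]
#' @param seed master seed; every stochastic stage draws its own child seed
#'   from it
#' @param out_dir if non-`NULL`, tables and provenance are written there
#' @return a `study_config` list
#' @export
study_config <- function(band = c(1, 40), target_fs = 125, reref = TRUE,
                         exclude_channels = character(),
                         analysis_window = NULL,
                         subject_k = 5, global_k = "auto",
                         candidate_ks = 2:8,
                         n_restarts_subject = 20, n_restarts_global = 50,
                         smooth_b = 3, smooth_lambda = 10,
                         boundary_mode = "mixed",
                         seed = 17, out_dir = NULL) {
  structure(as.list(environment()), class = "study_config")
}

#' Run the full microstate study pipeline
#'
#' Preprocess every subject, derive subject-level maps, cluster them per
#' group and globally, back-fit the global maps with temporal smoothing,
#' extract temporal parameters and GEV, and produce the group-statistics
#' tables (subject descriptives, parameter-by-class Mann-Whitney/FDR
#' comparison, clinical correlations for the significant parameters, and the
#' alpha-power comparison).
#'
#' @param subjects either a `synthetic_cohort` (from [simulate_cohort()]) or
#'   a data.frame manifest with columns `subject`, `group`, `path` of
#'   recordings readable by [read_recording()]
#' @param config a [study_config()]
#' @param scores clinical score table; taken from the cohort if omitted
#' @return a `study_result` list: `subject_models`, `group_models`,
#'   `global_model`, `chosen_k`, `segmentations`, `stats_table` (long
#'   per-subject parameters + per-class GEV), `table1`, `table2`,
#'   `correlations`, `alpha_power`, `levene`, `provenance`
#' @export
run_full_study <- function(subjects, config = study_config(),
                           scores = NULL) {
  if (inherits(subjects, "synthetic_cohort")) {
    if (is.null(subjects$recordings))
      stop_msdyn("cohort was simulated without recordings",
                 class = "msdyn_stage_error")
    manifest <- subjects$subjects
    recs <- subjects$recordings
    if (is.null(scores)) scores <- subjects$scores
  } else {
    manifest <- subjects
    recs <- lapply(manifest$path, read_recording)
    names(recs) <- manifest$subject
  }
  if (length(unique(manifest$group)) < 2 || any(table(manifest$group) < 2))
    stop_msdyn("stats stage requires >= 2 subjects in each of two groups",
               class = "msdyn_stage_error")
  n_sub <- nrow(manifest)
  seeds <- child_seeds(config$seed, n_sub + 4)

  # ---- preprocessing ----
  recs <- lapply(recs, function(rec) {
    if (length(config$exclude_channels)) {
      keep <- !(rec$channel_names %in% config$exclude_channels)
      rec <- eeg_recording(rec$data[keep, , drop = FALSE], rec$fs,
                           rec$channel_names[keep],
                           positions = rec$positions[keep, , drop = FALSE],
                           reference = rec$reference)
    }
    if (!is.null(config$band))
      rec <- bandpass_filter(rec, config$band[1], config$band[2])
    if (!is.null(config$target_fs) && config$target_fs < rec$fs)
      rec <- resample_recording(rec, config$target_fs)
    if (!is.null(config$analysis_window)) {
      idx <- seq(max(1, round(config$analysis_window[1] * rec$fs) + 1),
                 min(n_samples(rec),
                     round(config$analysis_window[2] * rec$fs)))
      rec$data <- rec$data[, idx, drop = FALSE]
    }
    if (config$reref) rec <- average_reference(rec)
    rec
  })

  # ---- subject-level clustering at GFP peaks ----
  subject_models <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    pk <- gfp_peak_maps(recs[[i]])
    sk <- config$subject_k
    if (identical(sk, "auto"))
      sk <- choose_k_meta_criterion(pk, config$candidate_ks,
                                    seed = seeds[i],
                                    n_restarts = config$n_restarts_subject
                                    )$chosen_k
    subject_models[[i]] <- modified_kmeans(
      pk, sk, n_restarts = config$n_restarts_subject, seed = seeds[i])
  }
  names(subject_models) <- manifest$subject

  # ---- group- and global-level clustering ----
  pooled <- do.call(rbind, lapply(subject_models, `[[`, "maps"))
  gk <- config$global_k
  if (identical(gk, "auto"))
    gk <- choose_k_meta_criterion(pooled, config$candidate_ks,
                                  seed = seeds[n_sub + 1],
                                  n_restarts = config$n_restarts_global
                                  )$chosen_k
  canon <- if (!is.null(recs[[1]]$positions))
    canonical_templates(recs[[1]]$positions) else NULL
  group_models <- lapply(unique(manifest$group), function(g) {
    multilevel_clustering(subject_models[manifest$group == g], gk,
                          seed = seeds[n_sub + 2], level = "group",
                          n_restarts = config$n_restarts_global,
                          canonical = canon)
  })
  names(group_models) <- unique(manifest$group)
  global_model <- multilevel_clustering(subject_models, gk,
                                        seed = seeds[n_sub + 3],
                                        level = "global",
                                        n_restarts = config$n_restarts_global,
                                        canonical = canon)

  # ---- back-fitting, smoothing, temporal parameters ----
  sp <- smoothing_params(config$smooth_b, config$smooth_lambda)
  segmentations <- vector("list", n_sub)
  stats_rows <- vector("list", n_sub)
  alpha <- numeric(n_sub)
  for (i in seq_len(n_sub)) {
    seg <- backfit_labels(recs[[i]], global_model)
    seg <- smooth_labels(seg, recs[[i]], global_model, sp)
    segmentations[[i]] <- seg
    st <- temporal_parameters(seg, boundary_mode = config$boundary_mode)
    gev <- global_explained_variance(recs[[i]], seg, global_model)
    st$gev_class <- gev$gev_class
    st$gev_total <- gev$gev_total
    st$subject <- manifest$subject[i]
    st$group <- manifest$group[i]
    stats_rows[[i]] <- st
    alpha[i] <- alpha_band_power(recs[[i]])
  }
  names(segmentations) <- manifest$subject
  stats_table <- do.call(rbind, stats_rows)

  # ---- statistics layer ----
  table1 <- if (!is.null(scores)) describe_groups(scores) else NULL
  table2 <- compare_groups(stats_table,
                           class_tags = global_model$labels_meta)
  lev <- do.call(rbind, lapply(c("occurrence", "coverage", "duration"),
    function(par) do.call(rbind, lapply(seq_len(global_model$k),
      function(cl) {
        sub <- stats_table[stats_table$class == cl, ]
        lt <- levene_test(sub[[par]], sub$group)
        data.frame(parameter = par, class = global_model$labels_meta[cl],
                   W = lt$W, p = lt$p)
      }))))
  sig <- table2[table2$p_fdr < 0.05, c("parameter", "class")]
  correlations <- if (!is.null(scores) && nrow(sig))
    correlate_clinical(stats_table, scores, sig,
                       class_tags = global_model$labels_meta) else NULL
  alpha_tab <- data.frame(subject = manifest$subject,
                          group = manifest$group, alpha_power = alpha)
  amw <- mann_whitney_z(alpha[manifest$group == "patient"],
                        alpha[manifest$group == "control"])

  result <- list(
    subject_models = subject_models, group_models = group_models,
    global_model = global_model, chosen_k = gk,
    segmentations = segmentations, stats_table = stats_table,
    table1 = table1, table2 = table2, levene = lev,
    correlations = correlations,
    alpha_power = list(table = alpha_tab, U = amw$U, Z = amw$Z, p = amw$p),
    provenance = list(package_version = as.character(
      utils::packageVersion("msdyn")),
      config = unclass(config), timestamp = format(Sys.time()),
      seeds = seeds))
  class(result) <- "study_result"
  if (!is.null(config$out_dir)) write_study_result(result, config$out_dir)
  result
}

#' Persist a study result as delimited tables and provenance JSON
#'
#' @param result a `study_result`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_study_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  wt(result$stats_table, "stats_table.tsv")
  wt(result$table2, "group_comparison.tsv")
  if (!is.null(result$table1)) wt(result$table1, "subject_characteristics.tsv")
  if (!is.null(result$correlations)) wt(result$correlations,
                                        "clinical_correlations.tsv")
  wt(result$alpha_power$table, "alpha_power.tsv")
  wt(result$levene, "levene.tsv")
  utils::write.table(result$global_model$maps,
                     file.path(dir, "global_maps.tsv"), sep = "\t",
                     row.names = result$global_model$labels_meta,
                     col.names = FALSE, quote = FALSE)
  jsonlite::write_json(result$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d subjects, global K = %d, mean GEV = %.3f\n",
              length(x$segmentations), x$chosen_k,
              mean(x$stats_table$gev_total[!duplicated(x$stats_table$subject)])))
  cat("  group comparison (p_fdr < 0.05):\n")
  sig <- x$table2[x$table2$p_fdr < 0.05, c("parameter", "class", "Z", "p_fdr")]
  if (nrow(sig)) print(sig, row.names = FALSE) else cat("   none\n")
  invisible(x)
}
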