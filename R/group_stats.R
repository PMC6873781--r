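#' Mean alpha-band power across channels
#'
#' Convenience wrapper around [band_power()] for the 8-14 Hz alpha band.
#'
#' @inheritParams band_power
#' @return scalar mean alpha-band power across channels
#' @export
alpha_band_power <- function(rec, band = c(8, 14), window_sec = 2,
                             overlap = 0.5) {
  band_power(rec, band = band, window_sec = window_sec,
             overlap = overlap)$band_power
}

#' Group comparison of microstate temporal parameters
#'
#' For each parameter (occurrence, coverage, duration), runs one
#' Mann-Whitney test per microstate class (patients vs controls) and applies
#' Benjamini-Hochberg FDR correction within that parameter's family of K
#' class-wise tests. This per-parameter family definition is the one that
#' reproduces published corrected rows from their uncorrected counterparts.
#'
#' @param stats_table long data.frame with columns `subject`, `class`, and
#'   the parameters `occurrence`, `coverage`, `duration` (one row per
#'   subject x class), plus optionally `group`
#' @param scores data.frame with columns `subject` and `group`
#'   (`"patient"`/`"control"`); ignored if `stats_table` carries `group`
#' @param parameters which parameter families to test
#' @param class_tags optional class letters for reporting
#' @return data.frame of class `ms_group_comparison`: one row per
#'   parameter x class with group means/sds, `U`, `Z`, `p`, `p_fdr`
#' @export
compare_groups <- function(stats_table, scores = NULL,
                           parameters = c("occurrence", "coverage",
                                          "duration"),
                           class_tags = NULL) {
  if (!("group" %in% names(stats_table))) {
    if (is.null(scores))
      stop_msdyn("no group information supplied",
                 class = "msdyn_parameter_error")
    stats_table$group <- scores$group[match(stats_table$subject,
                                            scores$subject)]
  }
  stats_table$group <- as.character(stats_table$group)
  if (!all(stats_table$group %in% c("patient", "control")))
    stop_msdyn("group must be 'patient' or 'control'",
               class = "msdyn_parameter_error")
  classes <- sort(unique(stats_table$class))
  if (is.null(class_tags)) class_tags <- LETTERS[seq_along(classes)]
  for (g in c("patient", "control"))
    if (length(unique(stats_table$subject[stats_table$group == g])) < 2)
      stop_msdyn("need >= 2 subjects per group",
                 class = "msdyn_parameter_error")
  rows <- list()
  for (par in parameters) {
    fam <- lapply(classes, function(cl) {
      sub <- stats_table[stats_table$class == cl, ]
      xp <- sub[[par]][sub$group == "patient"]
      xc <- sub[[par]][sub$group == "control"]
      xp[is.na(xp)] <- 0; xc[is.na(xc)] <- 0   # absent class counts as zero
      mw <- mann_whitney_z(xp, xc)
      data.frame(parameter = par, class = class_tags[match(cl, classes)],
                 mean_patient = mean(xp), sd_patient = stats::sd(xp),
                 mean_control = mean(xc), sd_control = stats::sd(xc),
                 U = mw$U, Z = mw$Z, p = mw$p)
    })
    fam <- do.call(rbind, fam)
    fam$p_fdr <- bh_fdr(fam$p)
    rows[[par]] <- fam
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ms_group_comparison", "data.frame")
  attr(out, "fdr_family") <- "per-parameter"
  out
}

#' Spearman correlations between clinical scores and microstate parameters
#'
#' Computes the rank correlation of each requested (score, parameter, class)
#' triple across subjects, the follow-up customarily restricted to the
#' parameters that showed significant group differences.
#'
#' @param stats_table long per-subject table as in [compare_groups()]
#' @param scores data.frame with `subject` plus the score columns
#' @param which data.frame with columns `parameter` and `class` selecting the
#'   microstate parameters to correlate
#' @param score_vars names of the clinical score columns to use
#' @param class_tags class letters corresponding to numeric class indices
#' @return data.frame with `score`, `parameter`, `class`, `rho`, `p`, `n`;
#'   undefined correlations (constant columns) are reported as `NA`
#' @export
correlate_clinical <- function(stats_table, scores, which,
                               score_vars = c("MADRS", "YMRS", "STAI_state",
                                              "STAI_trait"),
                               class_tags = NULL) {
  classes <- sort(unique(stats_table$class))
  if (is.null(class_tags)) class_tags <- LETTERS[seq_along(classes)]
  out <- list()
  for (i in seq_len(nrow(which))) {
    par <- which$parameter[i]
    cl <- which$class[i]
    cl_num <- if (is.numeric(cl)) cl else classes[match(cl, class_tags)]
    sub <- stats_table[stats_table$class == cl_num, ]
    v <- sub[[par]][match(scores$subject, sub$subject)]
    for (sv in intersect(score_vars, names(scores))) {
      res <- tryCatch(spearman_rho(as.numeric(scores[[sv]]), v),
                      msdyn_undefined_correlation_error = function(e)
                        list(rho = NA_real_, p = NA_real_,
                             n = length(v)))
      out[[length(out) + 1]] <- data.frame(
        score = sv, parameter = par,
        class = if (is.numeric(cl)) class_tags[match(cl, classes)] else cl,
        rho = res$rho, p = res$p, n = res$n)
    }
  }
  do.call(rbind, out)
}

#' Descriptive group comparison of subject characteristics
#'
#' Per-variable group means, standard deviations and pooled-variance t-tests
#' — the customary subjects table of a two-group clinical study.
#'
#' @param scores data.frame with `subject`, `group` and numeric score
#'   columns
#' @param vars score columns to summarise; defaults to every numeric column
#'   except `subject`
#' @return data.frame with one row per variable: group means +/- sd, `t`,
#'   `p`
#' @export
describe_groups <- function(scores, vars = NULL) {
  if (is.null(vars))
    vars <- setdiff(names(scores)[vapply(scores, is.numeric, TRUE)],
                    "subject")
  rows <- lapply(vars, function(v) {
    xp <- scores[[v]][scores$group == "patient"]
    xc <- scores[[v]][scores$group == "control"]
    tt <- tryCatch(students_t(xc, xp),
                   msdyn_undefined_error = function(e)
                     list(t = NA_real_, p = NA_real_))
    data.frame(variable = v,
               mean_control = mean(xc), sd_control = stats::sd(xc),
               mean_patient = mean(xp), sd_patient = stats::sd(xp),
               t = tt$t, p = tt$p)
  })
  do.call(rbind, rows)
}
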