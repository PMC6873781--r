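#' Smoothing parameters for the label sequence
#'
#' @param window_half_size half-width `b` of the temporal neighbourhood, in
#'   samples (the study value is 3)
#' @param besag_factor nonnegative strength `lambda` of the neighbourhood
#'   bonus (the study value is 10); 0 disables smoothing
#' @param max_iterations cap on relabelling sweeps
#' @return a `smoothing_params` list
#' @export
smoothing_params <- function(window_half_size = 3, besag_factor = 10,
                             max_iterations = 1000) {
  if (window_half_size < 0 || besag_factor < 0)
    stop_msdyn("window_half_size and besag_factor must be >= 0",
               class = "msdyn_parameter_error")
  structure(list(window_half_size = as.integer(window_half_size),
                 besag_factor = besag_factor,
                 max_iterations = as.integer(max_iterations)),
            class = "smoothing_params")
}

#' Winner-takes-all back-fitting of template maps
#'
#' Assigns every sample of the continuous recording (not only GFP peaks) to
#' the template with the highest absolute spatial correlation. Polarity is
#' ignored; ties go to the lower class index. Samples with zero spatial
#' variance inherit the previous sample's label (class 1 if first).
#'
#' @param rec an average-referenced [eeg_recording()]
#' @param model a `microstate_model` with matching channel count
#' @return an `ms_segmentation`: list with `labels` (1..K per sample),
#'   `corr` (winning |correlation| per sample), `fs`, `k`, `smoothing`
#' @export
backfit_labels <- function(rec, model) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(model, "microstate_model"))
  if (ncol(model$maps) != n_channels(rec))
    stop_msdyn("model and recording channel counts differ",
               class = "msdyn_dimension_error")
  cr <- .center_rows(t(rec$data))
  S <- .abs_corr(cr$X, cr$norm, model$maps)
  labels <- max.col(S, ties.method = "first")
  corr <- S[cbind(seq_along(labels), labels)]
  flat <- which(cr$norm == 0)
  for (t in flat) {
    labels[t] <- if (t == 1) 1L else labels[t - 1]
    corr[t] <- 0
  }
  structure(list(labels = as.integer(labels), corr = as.numeric(corr),
                 fs = rec$fs, k = model$k, smoothing = NULL),
            class = "ms_segmentation")
}

#' Besag-factor temporal smoothing of microstate labels
#'
#' Iteratively relabels samples by minimising a per-sample cost that trades
#' the topographic misfit against agreement with the temporal neighbourhood:
#' `cost(k, t) = d2(k, t) / (2 e (C - 1)) - lambda * N(b, k, t)`, where
#' `d2(k, t)` is the squared residual of sample t under template k, `e` the
#' residual noise variance of the current labelling, `C` the channel count,
#' and `N(b, k, t)` the number of samples within `t +/- b` (t excluded)
#' currently labelled k. Because the misfit is scaled by the sample's energy,
#' low-GFP samples are the ones the neighbourhood term can flip — brief
#' interruptions during GFP troughs are absorbed into the surrounding
#' segment. With `lambda = 0` the labelling is returned unchanged.
#'
#' @param seg an `ms_segmentation` from [backfit_labels()]
#' @param rec the recording the segmentation came from
#' @param model the fitted `microstate_model`
#' @param params a [smoothing_params()]
#' @return the segmentation with smoothed labels, updated `corr`, and
#'   `smoothing` recorded
#' @export
smooth_labels <- function(seg, rec, model, params = smoothing_params()) {
  stopifnot(inherits(seg, "ms_segmentation"),
            inherits(params, "smoothing_params"))
  n <- length(seg$labels)
  b <- params$window_half_size
  lam <- params$besag_factor
  if (b >= n)
    stop_msdyn("window half size must be smaller than the series",
               class = "msdyn_parameter_error")
  seg$smoothing <- params
  if (lam == 0 || b == 0) return(seg)
  C <- n_channels(rec)
  K <- model$k
  Xc <- .center_rows(t(rec$data))$X
  energy <- rowSums(Xc^2)
  proj <- (Xc %*% t(model$maps))^2          # (a_k . x_t)^2, n x K
  D2 <- pmax(energy - proj, 0)              # squared residual per class
  labels <- seg$labels
  e <- sum(D2[cbind(seq_len(n), labels)]) / (n * (C - 1))
  if (e <= 0) e <- .Machine$double.eps
  for (it in seq_len(params$max_iterations)) {
    Nb <- .window_counts(labels, K, b)
    cost <- D2 / (2 * e * (C - 1)) - lam * Nb
    new_labels <- max.col(-cost, ties.method = "first")
    if (identical(new_labels, labels)) break
    labels <- new_labels
    e <- sum(D2[cbind(seq_len(n), labels)]) / (n * (C - 1))
    if (e <= 0) e <- .Machine$double.eps
  }
  seg$labels <- as.integer(labels)
  corr <- sqrt(proj[cbind(seq_len(n), labels)] / pmax(energy, 1e-300))
  corr[energy == 0] <- 0
  seg$corr <- pmin(1, as.numeric(corr))
  seg
}

# count, for each sample and class, labels within +/- b excluding self
.window_counts <- function(labels, K, b) {
  n <- length(labels)
  out <- matrix(0L, n, K)
  onehot <- matrix(0L, n, K)
  onehot[cbind(seq_len(n), labels)] <- 1L
  cs <- rbind(0L, apply(onehot, 2, cumsum))
  lo <- pmax(seq_len(n) - b, 1L)
  hi <- pmin(seq_len(n) + b, n)
  for (k in seq_len(K))
    out[, k] <- cs[hi + 1L, k] - cs[lo, k]
  out - onehot
}

#' Maximal runs of constant label
#'
#' @param seg an `ms_segmentation`
#' @return data.frame with columns `class`, `start` (1-based sample index),
#'   `length` (samples), `boundary` (`TRUE` for the first and last run, which
#'   are truncated by the analysis window)
#' @export
extract_segments <- function(seg) {
  r <- rle(seg$labels)
  n <- length(r$lengths)
  data.frame(class = r$values,
             start = cumsum(c(1L, r$lengths[-n])),
             length = r$lengths,
             boundary = seq_len(n) %in% c(1L, n))
}

#' Per-class temporal parameters of a segmentation
#'
#' Occurrence (segments per second), coverage (percent of analysed time) and
#' mean segment duration (ms) for each microstate class. Edge runs are
#' truncated by the analysis window; `boundary_mode` controls whether they
#' count. The default `"mixed"` keeps them for occurrence and coverage but
#' drops them from the duration average (truncated runs bias dwell
#' estimates); `"inclusive"` counts them everywhere, which makes the exact
#' identity `occurrence * duration/1000 = coverage/100` hold per class.
#'
#' @param seg an `ms_segmentation`
#' @param boundary_mode `"mixed"`, `"inclusive"` or `"exclusive"`
#' @param duration_stat `"mean"` (default, the field convention), `"median"`
#'   or `"mode"` summary of run durations
#' @return data.frame of class `ms_temporal_stats` with one row per class:
#'   `class`, `occurrence` (1/s), `coverage` (%), `duration` (ms)
#' @export
temporal_parameters <- function(seg,
                                boundary_mode = c("mixed", "inclusive",
                                                  "exclusive"),
                                duration_stat = c("mean", "median", "mode")) {
  boundary_mode <- match.arg(boundary_mode)
  duration_stat <- match.arg(duration_stat)
  if (!length(seg$labels))
    stop_msdyn("empty segmentation", class = "msdyn_parameter_error")
  if (seg$fs <= 0)
    stop_msdyn("fs must be positive", class = "msdyn_parameter_error")
  runs <- extract_segments(seg)
  K <- seg$k
  total_s <- length(seg$labels) / seg$fs
  occ_runs <- if (boundary_mode == "exclusive")
    runs[!runs$boundary, , drop = FALSE] else runs
  dur_runs <- if (boundary_mode == "inclusive")
    runs else runs[!runs$boundary, , drop = FALSE]
  summarise <- switch(duration_stat,
    mean = mean,
    median = stats::median,
    mode = function(x) as.numeric(names(sort(table(x),
                                             decreasing = TRUE))[1]))
  out <- data.frame(class = seq_len(K))
  out$occurrence <- vapply(seq_len(K), function(k)
    sum(occ_runs$class == k) / total_s, 0)
  out$coverage <- vapply(seq_len(K), function(k)
    100 * sum(seg$labels == k) / length(seg$labels), 0)
  out$duration <- vapply(seq_len(K), function(k) {
    len <- dur_runs$length[dur_runs$class == k]
    if (!length(len)) {
      # class absent (or only boundary runs): fall back to available runs,
      # else 0
      len <- occ_runs$length[occ_runs$class == k]
      if (!length(len)) return(0)
    }
    summarise(len) * 1000 / seg$fs
  }, 0)
  class(out) <- c("ms_temporal_stats", "data.frame")
  attr(out, "boundary_mode") <- boundary_mode
  attr(out, "total_seconds") <- total_s
  out
}

#' Global explained variance of a fitted segmentation
#'
#' GEV is the GFP^2-weighted sum of the squared spatial correlations between
#' each sample and its assigned template, as a fraction of the total GFP^2:
#' the portion of topographic variance the template set accounts for. The
#' per-class values sum to the total.
#'
#' @param rec the recording
#' @param seg its `ms_segmentation`
#' @param model the `microstate_model` used for fitting
#' @return list with `gev_class` (length-K vector) and `gev_total`
#' @export
global_explained_variance <- function(rec, seg, model) {
  gfp <- compute_gfp(rec)$values
  if (length(gfp) != length(seg$labels))
    stop_msdyn("recording and segmentation lengths differ",
               class = "msdyn_dimension_error")
  w <- gfp^2
  if (sum(w) == 0)
    stop_msdyn("all-zero GFP: GEV undefined",
               class = "msdyn_undefined_gev_error")
  contrib <- w * seg$corr^2 / sum(w)
  gev_class <- vapply(seq_len(model$k), function(k)
    sum(contrib[seg$labels == k]), 0)
  list(gev_class = gev_class, gev_total = sum(gev_class))
}

#' Wrap a bare label sequence as a segmentation
#'
#' Used for ground-truth label sequences from the synthetic generator, where
#' no fitted correlation trace exists (`corr` is set to 1).
#'
#' @param labels integer class labels, 1..k
#' @param fs sampling rate in Hz
#' @param k number of classes
#' @return an `ms_segmentation`
#' @export
segmentation_from_labels <- function(labels, fs, k) {
  structure(list(labels = as.integer(labels),
                 corr = rep(1, length(labels)),
                 fs = fs, k = as.integer(k), smoothing = NULL),
            class = "ms_segmentation")
}
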