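#' Construct an EEG recording object
#'
#' The basic container of the package: a channels x samples matrix of scalp
#' potentials (microvolts) with its sampling rate, channel labels, optional
#' unit-sphere electrode positions and reference state.
#'
#' @param data numeric matrix, channels in rows, samples in columns
#' @param fs sampling rate in Hz (> 0)
#' @param channel_names character vector, one label per channel; defaults to
#'   `Ch1..Chn`
#' @param positions optional channels x 3 matrix of unit-sphere electrode
#'   coordinates
#' @param reference `"original"` or `"average"`
#' @param bad_channels subset of `channel_names` flagged as bad
#' @return an object of class `eeg_recording`
#' @export
eeg_recording <- function(data, fs, channel_names = NULL, positions = NULL,
                          reference = c("original", "average"),
                          bad_channels = character()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  reference <- match.arg(reference)
  if (nrow(data) < 2 || ncol(data) < 2)
    stop_msdyn("recording needs >= 2 channels and >= 2 samples",
               class = "msdyn_parameter_error")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop_msdyn("fs must be a single positive number",
               class = "msdyn_parameter_error")
  if (is.null(channel_names)) channel_names <- paste0("Ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop_msdyn("one channel name per row required",
               class = "msdyn_parameter_error")
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != nrow(data) || ncol(positions) != 3)
      stop_msdyn("positions must be channels x 3",
                 class = "msdyn_parameter_error")
  }
  if (!all(bad_channels %in% channel_names))
    stop_msdyn("bad_channels must be a subset of channel_names",
               class = "msdyn_parameter_error")
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 positions = positions, reference = reference,
                 bad_channels = bad_channels),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %s reference\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$reference))
  if (length(x$bad_channels))
    cat("  bad channels:", paste(x$bad_channels, collapse = ", "), "\n")
  invisible(x)
}

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)

#' Re-reference a recording to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, the
#' reference in which scalp topographies are compared. Idempotent.
#'
#' @param rec an [eeg_recording()]
#' @return the recording with zero channel mean at every sample and
#'   `reference = "average"`
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec$reference <- "average"
  rec
}

#' Global field power of a recording
#'
#' GFP(t) is the spatial standard deviation of the scalp potential across all
#' channels at sample t (population form, divide by the channel count). For
#' average-referenced data this equals the RMS across channels.
#'
#' @param rec an [eeg_recording()]
#' @return an object of class `gfp_series`: list with `values` (per-sample
#'   GFP, microvolts) and `peak_indices` (empty until [detect_gfp_peaks()])
#' @export
compute_gfp <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$data
  v <- sqrt(colMeans(x^2) - colMeans(x)^2)
  v[v < 0] <- 0
  structure(list(values = as.numeric(v), peak_indices = integer(0),
                 fs = rec$fs),
            class = "gfp_series")
}

#' Locate GFP peaks
#'
#' Strict local maxima of the GFP series (greater than both neighbours;
#' endpoints excluded). On a plateau the first sample counts as the peak.
#' Only the topographies at these moments of maximal field strength enter
#' the clustering.
#'
#' @param gfp a `gfp_series` from [compute_gfp()]
#' @param max_peaks optional cap: keep the `max_peaks` largest peaks
#' @return the series with `peak_indices` filled (ascending sample indices)
#' @export
detect_gfp_peaks <- function(gfp, max_peaks = NULL) {
  stopifnot(inherits(gfp, "gfp_series"))
  v <- gfp$values
  n <- length(v)
  if (n < 3)
    stop_msdyn("need >= 3 samples to detect peaks",
               class = "msdyn_parameter_error")
  i <- 2:(n - 1)
  # strict rise into the sample; plateau allowed to the right until a drop
  cand <- i[v[i] > v[i - 1]]
  is_peak <- vapply(cand, function(t) {
    j <- t
    while (j < n && v[j + 1] == v[t]) j <- j + 1
    j < n && v[j + 1] < v[t]
  }, logical(1))
  pk <- cand[is_peak]
  if (!is.null(max_peaks) && length(pk) > max_peaks)
    pk <- sort(pk[order(v[pk], decreasing = TRUE)[seq_len(max_peaks)]])
  gfp$peak_indices <- as.integer(pk)
  gfp
}

#' Extract the scalp maps at GFP peaks
#'
#' @param rec an [eeg_recording()]
#' @param gfp a peak-annotated `gfp_series`; computed on the fly if missing
#' @return peaks x channels matrix of raw (unnormalised) topographies
#' @export
gfp_peak_maps <- function(rec, gfp = NULL) {
  if (is.null(gfp)) gfp <- detect_gfp_peaks(compute_gfp(rec))
  if (!length(gfp$peak_indices))
    stop_msdyn("no GFP peaks found", class = "msdyn_parameter_error")
  t(rec$data[, gfp$peak_indices, drop = FALSE])
}
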