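#' Read an EEG recording from disk
#'
#' Two on-disk layouts are supported: a delimited-text channels x samples
#' matrix with a YAML sidecar carrying the sampling rate (and optionally
#' channel names and positions), or a standard 16-bit EDF file.
#'
#' @param path file path (`.edf` for EDF; anything else is treated as a
#'   delimited matrix)
#' @param format `"auto"`, `"matrix"` or `"edf"`
#' @param sidecar path to the YAML sidecar for matrix input; defaults to
#'   `path` with a `.yaml` extension
#' @return an [eeg_recording()] with `reference = "original"`
#' @export
read_recording <- function(path, format = c("auto", "matrix", "edf"),
                           sidecar = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_msdyn("file not found: ", path, class = "msdyn_format_error")
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  if (format == "edf") return(read_edf(path))
  if (is.null(sidecar)) sidecar <- paste0(sub("\\.[^.]+$", "", path), ".yaml")
  if (!file.exists(sidecar))
    stop_msdyn("sidecar not found: ", sidecar, class = "msdyn_format_error")
  meta <- yaml::read_yaml(sidecar)
  if (is.null(meta$fs))
    stop_msdyn("sidecar lacks required key 'fs'", class = "msdyn_format_error")
  dat <- tryCatch(
    as.matrix(utils::read.table(path, header = FALSE, sep = "",
                                colClasses = "numeric")),
    error = function(e) stop_msdyn("non-numeric matrix payload: ",
                                   conditionMessage(e),
                                   class = "msdyn_parse_error"))
  pos <- if (!is.null(meta$positions))
    matrix(unlist(meta$positions), ncol = 3, byrow = TRUE) else NULL
  eeg_recording(dat, fs = meta$fs,
                channel_names = if (!is.null(meta$channel_names))
                  as.character(meta$channel_names) else NULL,
                positions = pos)
}

#' Write a recording as delimited matrix plus YAML sidecar
#'
#' @param rec an [eeg_recording()]
#' @param path output path for the whitespace-delimited matrix
#' @param sidecar sidecar path; defaults to `path` with `.yaml`
#' @return `path`, invisibly
#' @export
write_recording_matrix <- function(rec, path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- paste0(sub("\\.[^.]+$", "", path), ".yaml")
  utils::write.table(rec$data, path, row.names = FALSE, col.names = FALSE)
  meta <- list(fs = rec$fs, channel_names = as.list(rec$channel_names))
  if (!is.null(rec$positions))
    meta$positions <- lapply(seq_len(nrow(rec$positions)),
                             function(i) as.numeric(rec$positions[i, ]))
  yaml::write_yaml(meta, sidecar)
  invisible(path)
}

# --- minimal standard EDF (16-bit) support -------------------------------
# Fixed-width ASCII header of 256 bytes + 256 per signal, then int16
# little-endian samples grouped in data records. All signals must share one
# sampling rate for use as an eeg_recording.

pad <- function(s, n) formatC(substr(s, 1, n), width = -n)

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) rawToChar(readBin(con, "raw", n))
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)            # patient, recording, date, time
  as.integer(rd(8))                       # header length
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1)
    stop_msdyn("malformed EDF header", class = "msdyn_parse_error")
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  for (i in seq_len(ns)) rd(80)           # transducer
  for (i in seq_len(ns)) rd(8)            # dimension
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)           # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (any(is.na(spr)) || any(spr < 1) || is.na(dur) || dur <= 0)
    stop_msdyn("malformed EDF signal headers", class = "msdyn_parse_error")
  fs <- spr / dur
  if (length(unique(fs)) != 1)
    stop_msdyn("EDF signals disagree on sampling rate",
               class = "msdyn_format_error")
  out <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2, endian = "little")
      out[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <-
        pmin_[s] + (dig - dmin_[s]) * scale[s]
    }
  }
  eeg_recording(out, fs = fs[1], channel_names = labels)
}

#' Write a recording to a 16-bit EDF file
#'
#' One-second data records; the sampling rate must be a whole number and the
#' sample count is truncated to whole records. Amplitudes are quantised to
#' the signal's physical range over 16 bits.
#'
#' @param rec an [eeg_recording()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_edf <- function(rec, path) {
  if (rec$fs != round(rec$fs))
    stop_msdyn("EDF writer requires an integer sampling rate",
               class = "msdyn_parameter_error")
  spr <- as.integer(rec$fs)
  n_rec <- n_samples(rec) %/% spr
  if (n_rec < 1)
    stop_msdyn("recording shorter than one EDF record",
               class = "msdyn_parameter_error")
  x <- rec$data[, seq_len(n_rec * spr), drop = FALSE]
  ns <- nrow(x)
  pmin_ <- apply(x, 1, min); pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  dmin_ <- -32768; dmax_ <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, n) writeBin(charToRaw(pad(s, n)), con)
  wr("0", 8); wr("X", 80); wr("X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256L + 256L * ns), 8); wr("", 44)
  wr(as.character(n_rec), 8); wr("1", 8); wr(as.character(ns), 4)
  for (nm in rec$channel_names) wr(nm, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (v in pmin_) wr(sprintf("%.3f", v), 8)
  for (v in pmax_) wr(sprintf("%.3f", v), 8)
  for (i in seq_len(ns)) wr(as.character(dmin_), 8)
  for (i in seq_len(ns)) wr(as.character(dmax_), 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(as.character(spr), 8)
  for (i in seq_len(ns)) wr("", 32)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (s in seq_len(ns)) {
      dig <- round(dmin_ + (x[s, idx] - pmin_[s]) /
                     (pmax_[s] - pmin_[s]) * (dmax_ - dmin_))
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
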