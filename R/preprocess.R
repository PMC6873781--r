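#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) 4th-order Butterworth band-pass, applied per
#' channel. Phase preservation matters here: microstate analysis compares
#' instantaneous topographies, which a causal filter would skew.
#'
#' @param rec an [eeg_recording()]
#' @param low,high band edges in Hz, `0 < low < high < fs/2`
#' @param order Butterworth order (default 4)
#' @return the filtered recording
#' @export
bandpass_filter <- function(rec, low, high, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(low > 0 && low < high && high < nyq))
    stop_msdyn("band edges must satisfy 0 < low < high < fs/2",
               class = "msdyn_parameter_error")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  rec$data <- t(apply(rec$data, 1, function(ch)
    signal::filtfilt(bf, ch)))
  rownames(rec$data) <- rec$channel_names
  rec
}

#' Anti-aliased downsampling
#'
#' Zero-phase Chebyshev-I anti-alias filtering (cutoff at 0.8 of the new
#' Nyquist frequency, as in classical decimation) followed by cubic-spline
#' evaluation on the new time grid. Upsampling is refused. The output length
#' is `round(n * target_fs / fs)`.
#'
#' @param rec an [eeg_recording()]
#' @param target_fs new sampling rate in Hz, `<= fs`
#' @return the resampled recording with `fs = target_fs`
#' @export
resample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs > rec$fs)
    stop_msdyn("no upsampling: target_fs must be <= fs",
               class = "msdyn_parameter_error")
  if (target_fs == rec$fs) return(rec)
  ratio <- target_fs / rec$fs
  cf <- signal::cheby1(8, 0.05, 0.8 * ratio)
  n_out <- round(n_samples(rec) * ratio)
  t_old <- (seq_len(n_samples(rec)) - 1) / rec$fs
  t_new <- (seq_len(n_out) - 1) / target_fs
  y <- t(apply(rec$data, 1, function(ch) {
    f <- signal::filtfilt(cf, ch)
    stats::spline(t_old, f, xout = t_new)$y
  }))
  rownames(y) <- rec$channel_names
  rec$data <- y
  rec$fs <- target_fs
  rec
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces flagged channels with the spherical-spline estimate computed from
#' the remaining channels (spline order m = 4, Legendre expansion to degree
#' 7, ridge regularisation 1e-5). Good channels are left untouched.
#'
#' @param rec an [eeg_recording()] with `positions` set
#' @param bad channel names to rebuild; defaults to `rec$bad_channels`
#' @param m spline order
#' @param max_degree Legendre truncation degree
#' @param lambda regularisation added to the spline system diagonal
#' @return the recording with interpolated channels and `bad_channels`
#'   cleared
#' @export
interpolate_channels <- function(rec, bad = rec$bad_channels, m = 4,
                                 max_degree = 7, lambda = 1e-5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!length(bad)) return(rec)
  if (is.null(rec$positions))
    stop_msdyn("channel positions required for spherical-spline interpolation",
               class = "msdyn_capability_error")
  if (!all(bad %in% rec$channel_names))
    stop_msdyn("unknown channel in 'bad'", class = "msdyn_parameter_error")
  good <- setdiff(rec$channel_names, bad)
  if (length(good) < 2)
    stop_msdyn("need >= 2 good channels to interpolate",
               class = "msdyn_parameter_error")
  gi <- match(good, rec$channel_names)
  bi <- match(bad, rec$channel_names)
  P <- rec$positions / sqrt(rowSums(rec$positions^2))
  Ggg <- .spline_g(tcrossprod(P[gi, , drop = FALSE]), m, max_degree)
  Gbg <- .spline_g(P[bi, , drop = FALSE] %*% t(P[gi, , drop = FALSE]),
                   m, max_degree)
  ng <- length(gi)
  A <- rbind(cbind(Ggg + diag(lambda, ng), rep(1, ng)),
             c(rep(1, ng), 0))
  rhs <- rbind(rec$data[gi, , drop = FALSE], 0)
  sol <- solve(A, rhs)
  rec$data[bi, ] <- Gbg %*% sol[seq_len(ng), , drop = FALSE] +
    matrix(sol[ng + 1, ], nrow = length(bi), ncol = n_samples(rec),
           byrow = TRUE)
  rec$bad_channels <- setdiff(rec$bad_channels, bad)
  rec
}

# Perrin et al. spline kernel g(cos_angle), Legendre series to max_degree
.spline_g <- function(cosang, m, max_degree) {
  cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
  g <- matrix(0, nrow(cosang), ncol(cosang))
  Plm1 <- matrix(1, nrow(cosang), ncol(cosang))  # P_0
  Pl <- cosang                                    # P_1
  for (l in seq_len(max_degree)) {
    g <- g + (2 * l + 1) / (l^m * (l + 1)^m) * Pl
    # recurrence to P_{l+1}
    Pnext <- ((2 * l + 1) * cosang * Pl - l * Plm1) / (l + 1)
    Plm1 <- Pl; Pl <- Pnext
  }
  g / (4 * pi)
}
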