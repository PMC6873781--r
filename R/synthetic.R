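#' Specification of a synthetic two-group EEG cohort
#'
#' The generator emulates the structure microstate analysis assumes in
#' eyes-closed resting EEG: a sequence of quasi-stable scalp topographies
#' drawn from a small set of template maps, carried by an alpha-band
#' oscillation with segment-wise random phase and polarity, plus spatially
#' white sensor noise; two groups of subjects with an optional planted
#' increase of one class's entry rate in the patient group.
#'
#' @param n_channels electrodes (default 32; use 204 for full-montage runs)
#' @param fs sampling rate, Hz
#' @param duration seconds of data per subject
#' @param k_true number of planted template maps
#' @param mean_dwell expected segment duration, ms (must exceed one sample)
#' @param snr signal-to-noise amplitude (RMS) ratio
#' @param alpha_freq carrier frequency, Hz
#' @param group_effect multiplicative increase of class-1 entry probability
#'   in patients (0.35 means +35%)
#' @param n_per_group subjects per group
#' @param seed master seed for the cohort
#' @return a `synthetic_spec` list
#' @export
synthetic_spec <- function(n_channels = 32, fs = 125, duration = 120,
                           k_true = 5, mean_dwell = 80, snr = 5,
                           alpha_freq = 10, group_effect = 0.35,
                           n_per_group = 17, seed = 1) {
  if (k_true < 2) stop_msdyn("k_true must be >= 2",
                             class = "msdyn_parameter_error")
  if (mean_dwell <= 1000 / fs)
    stop_msdyn("mean_dwell must exceed one sample period",
               class = "msdyn_parameter_error")
  if (snr <= 0) stop_msdyn("snr must be > 0", class = "msdyn_parameter_error")
  if (n_per_group < 2) stop_msdyn("n_per_group must be >= 2",
                                  class = "msdyn_parameter_error")
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Planted template maps
#'
#' `k` mutually orthogonal, zero-mean, unit-norm channel vectors obtained by
#' orthonormalising random Gaussian vectors inside the average-reference
#' subspace.
#'
#' @param n_channels number of channels
#' @param k number of maps, `k < n_channels`
#' @param seed integer seed
#' @return k x n_channels matrix
#' @export
make_template_maps <- function(n_channels, k, seed = 1) {
  if (k >= n_channels)
    stop_msdyn("need k < n_channels", class = "msdyn_parameter_error")
  with_seed(seed, {
    X <- matrix(stats::rnorm(n_channels * k), n_channels, k)
    X <- X - matrix(colMeans(X), n_channels, k, byrow = TRUE)
    Q <- qr.Q(qr(X))
    t(Q)
  })
}

# transition matrix of the planted chain: self-transition tuned to the dwell
# time; on leaving, entries uniform over the other classes except class 1,
# whose entry weight is scaled by (1 + group_effect) for patients.
.transition_matrix <- function(spec, group) {
  k <- spec$k_true
  dwell_samples <- spec$mean_dwell * spec$fs / 1000
  p_stay <- 1 - 1 / dwell_samples
  P <- matrix(0, k, k)
  base <- 1 / (k - 1)
  for (i in seq_len(k)) {
    w <- rep(base, k); w[i] <- 0
    if (group == "patient" && i != 1) {
      # class-1 entry probability is multiplied outright; the remaining mass
      # is spread over the other available classes
      w[1] <- min(0.99, base * (1 + spec$group_effect))
      rest <- setdiff(seq_len(k), c(1L, i))
      w[rest] <- (1 - w[1]) / length(rest)
    }
    w <- w / sum(w)
    P[i, ] <- (1 - p_stay) * w
    P[i, i] <- p_stay
  }
  P
}

#' Simulate a ground-truth microstate label sequence
#'
#' First-order Markov chain over the planted classes with geometric dwell
#' times matching `mean_dwell`; patient subjects get the class-1 entry
#' probability multiplied by `1 + group_effect` (renormalised).
#'
#' @param spec a [synthetic_spec()]
#' @param group `"patient"` or `"control"`
#' @param seed integer seed
#' @return integer label vector of length `duration * fs`
#' @export
simulate_label_sequence <- function(spec, group = c("control", "patient"),
                                    seed = 1) {
  group <- match.arg(group)
  n <- round(spec$duration * spec$fs)
  k <- spec$k_true
  P <- .transition_matrix(spec, group)
  p_stay <- P[1, 1]
  # jump-chain cumulative entry probabilities per current class
  cum_jump <- vapply(seq_len(k), function(i) {
    w <- P[i, ]; w[i] <- 0
    cumsum(w / sum(w))
  }, numeric(k))
  with_seed(seed, {
    m <- ceiling(n / (spec$mean_dwell * spec$fs / 1000) * 1.5) + 50
    lens <- stats::rgeom(m, prob = 1 - p_stay) + 1L
    while (sum(lens) < n)
      lens <- c(lens, stats::rgeom(m, prob = 1 - p_stay) + 1L)
    m <- length(lens)
    u <- stats::runif(m)
    cls <- integer(m)
    cls[1] <- sample.int(k, 1)
    for (i in 2:m)
      cls[i] <- findInterval(u[i], cum_jump[, cls[i - 1]],
                             left.open = TRUE) + 1L
    rep.int(cls, lens)[seq_len(n)]
  })
}

#' Synthesise an EEG recording from a label sequence
#'
#' Each sample is its class's template map scaled by an alpha-frequency
#' sinusoid with per-segment random phase and random polarity (exercising
#' the polarity invariance of the analysis), plus spatially white Gaussian
#' noise scaled so that the signal-to-noise RMS amplitude ratio equals
#' `spec$snr`. The output is average-referenced and carries a
#' Fibonacci-sphere montage.
#'
#' @param spec a [synthetic_spec()]
#' @param templates k x channels map matrix (see [make_template_maps()])
#' @param labels integer label sequence
#' @param seed integer seed
#' @return an [eeg_recording()]
#' @export
simulate_recording <- function(spec, templates, labels, seed = 1) {
  if (max(labels) > nrow(templates))
    stop_msdyn("label outside template range", class = "msdyn_parameter_error")
  n <- length(labels)
  C <- ncol(templates)
  r <- rle(labels)
  nseg <- length(r$lengths)
  with_seed(seed, {
    phase <- stats::runif(nseg, 0, 2 * pi)
    sign_ <- sample(c(-1, 1), nseg, replace = TRUE)
    tt <- seq_len(n) / spec$fs
    a <- sin(2 * pi * spec$alpha_freq * tt +
               rep.int(phase, r$lengths)) * rep.int(sign_, r$lengths)
    X <- templates[labels, , drop = FALSE] * a    # n x C
    rms_sig <- sqrt(mean(X^2))
    noise_sd <- rms_sig / spec$snr
    X <- X + matrix(stats::rnorm(n * C, sd = noise_sd), n, C)
    rec <- eeg_recording(t(X), fs = spec$fs,
                         positions = sphere_positions(C))
    average_reference(rec)
  })
}

#' Simulate a full two-group cohort
#'
#' Generates per-subject ground-truth label sequences, optionally the EEG
#' recordings themselves, clinical scores with the structure of a euthymic
#' bipolar-versus-control sample (near-zero mood ratings in both groups,
#' anxiety scores shifted upward in patients, STAI clamped to its 20-80
#' range), and the true per-subject temporal parameters computed from the
#' planted labels.
#'
#' @param spec a [synthetic_spec()]
#' @param recordings if `FALSE`, skip EEG synthesis and return label
#'   sequences only (fast mode for statistics-level simulations)
#' @return a `synthetic_cohort`: list with `templates`, `subjects`
#'   (data.frame of subject/group/seed), `labels` (list), `recordings`
#'   (list or `NULL`), `scores` (clinical table), `true_params` (long
#'   per-subject ms_temporal_stats table, boundary-inclusive)
#' @export
simulate_cohort <- function(spec, recordings = TRUE) {
  n_tot <- 2 * spec$n_per_group
  seeds <- child_seeds(spec$seed, 2 * n_tot + 2)
  templates <- make_template_maps(spec$n_channels, spec$k_true,
                                  seed = seeds[1])
  subjects <- data.frame(
    subject = sprintf("S%02d", seq_len(n_tot)),
    group = rep(c("patient", "control"), each = spec$n_per_group),
    stringsAsFactors = FALSE)
  labels <- vector("list", n_tot)
  recs <- if (recordings) vector("list", n_tot) else NULL
  tp <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    labels[[i]] <- simulate_label_sequence(spec, subjects$group[i],
                                           seed = seeds[1 + i])
    if (recordings)
      recs[[i]] <- simulate_recording(spec, templates, labels[[i]],
                                      seed = seeds[1 + n_tot + i])
    st <- temporal_parameters(
      segmentation_from_labels(labels[[i]], spec$fs, spec$k_true),
      boundary_mode = "inclusive")
    st$subject <- subjects$subject[i]
    st$group <- subjects$group[i]
    tp[[i]] <- st
  }
  names(labels) <- subjects$subject
  if (recordings) names(recs) <- subjects$subject
  scores <- .simulate_scores(subjects, seed = seeds[2 * n_tot + 2])
  structure(list(spec = spec, templates = templates, subjects = subjects,
                 labels = labels, recordings = recs, scores = scores,
                 true_params = do.call(rbind, tp)),
            class = "synthetic_cohort")
}

# clinical scaffolding: truncated normals with means/SDs typical of a
# euthymic bipolar sample vs controls; integer scores, STAI clamped to 20-80
.simulate_scores <- function(subjects, seed) {
  rtnorm <- function(n, mean, sd, lo, hi)
    pmin(hi, pmax(lo, round(stats::rnorm(n, mean, sd))))
  with_seed(seed, {
    pat <- subjects$group == "patient"
    n <- nrow(subjects)
    data.frame(
      subject = subjects$subject,
      group = subjects$group,
      age = ifelse(pat, rtnorm(n, 35.9, 11.9, 18, 75),
                   rtnorm(n, 36.6, 14.5, 18, 75)),
      education = sample(1:3, n, replace = TRUE),
      MADRS = ifelse(pat, rtnorm(n, 2.3, 2.9, 0, 11),
                     rtnorm(n, 1.4, 1.6, 0, 11)),
      YMRS = ifelse(pat, rtnorm(n, 0.8, 1.4, 0, 5),
                    rtnorm(n, 0.9, 1.4, 0, 5)),
      STAI_state = ifelse(pat, rtnorm(n, 36.9, 15.2, 20, 80),
                          rtnorm(n, 26.7, 4.8, 20, 80)),
      STAI_trait = ifelse(pat, rtnorm(n, 42.9, 13.3, 20, 80),
                          rtnorm(n, 27.4, 5.2, 20, 80)),
      stringsAsFactors = FALSE)
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d + %d subjects, %d channels, %g s @ %g Hz, k=%d%s\n",
              x$spec$n_per_group, x$spec$n_per_group, x$spec$n_channels,
              x$spec$duration, x$spec$fs, x$spec$k_true,
              if (is.null(x$recordings)) " (labels only)" else ""))
  invisible(x)
}
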