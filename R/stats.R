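#' Mann-Whitney U test with normal approximation
#'
#' Rank-sum U with midrank handling of ties, Z from the tie-corrected normal
#' approximation with continuity correction, and a two-sided normal p-value —
#' the form in which nonparametric group comparisons are conventionally
#' reported (U, Z, p). `U` counts pairs `x_i > y_j` plus half the ties, so
#' the sign of Z is positive when `x` tends to exceed `y`.
#'
#' @param x,y numeric samples (non-empty)
#' @return list with `U`, `Z`, `p`
#' @export
mann_whitney_z <- function(x, y) {
  if (!length(x) || !length(y))
    stop_msdyn("both samples must be non-empty",
               class = "msdyn_parameter_error")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, Z = 0, p = 1))
  d <- U - mu
  Z <- if (d == 0) 0 else (d - 0.5 * sign(d)) / sqrt(sigma2)
  list(U = U, Z = Z, p = min(1, 2 * stats::pnorm(-abs(Z))))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Sorts the p-values, takes `q_(i) = min_{j >= i} p_(j) * m / j` capped at
#' 1, and maps the adjusted values back to the input order. The family size
#' `m` defaults to the number of p-values supplied.
#'
#' @param p p-values in `[0, 1]`
#' @param m family size (>= `length(p)`)
#' @return adjusted p-values in input order
#' @export
bh_fdr <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1 | is.na(p)))
    stop_msdyn("p-values must lie in [0, 1]", class = "msdyn_parameter_error")
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  q <- rev(cummin(rev(ps * (m / seq_len(n)))))   # m/j == 1 exactly at j == m
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of midranks; two-sided p from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y paired numeric samples, length >= 3
#' @return list with `rho`, `p`, `n`
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop_msdyn("need paired samples of equal length >= 3",
               class = "msdyn_parameter_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_msdyn("constant input: correlation undefined",
               class = "msdyn_undefined_correlation_error")
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Levene's test for homogeneity of variances
#'
#' One-way ANOVA on absolute deviations from the group means. Returns the
#' convention `W = 0, p = 1` when every observation sits exactly on its group
#' mean.
#'
#' @param values numeric vector of observations
#' @param groups factor (or coercible) of group membership, >= 2 groups with
#'   >= 2 values each
#' @return list with `W` (F statistic), `p`
#' @export
levene_test <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop_msdyn("need >= 2 groups with >= 2 values each",
               class = "msdyn_parameter_error")
  dev <- abs(values - stats::ave(values, groups))
  if (all(dev < .Machine$double.eps * max(1, abs(values))))
    return(list(W = 0, p = 1))
  within <- dev - stats::ave(dev, groups)
  if (all(abs(within) < 1e-12 * max(1, max(dev)))) {
    gm <- tapply(dev, groups, mean)
    if (max(gm) - min(gm) < 1e-12 * max(1, max(dev)))
      return(list(W = 0, p = 1))   # every group equally dispersed
    return(list(W = Inf, p = 0))   # dispersions differ with zero noise
  }
  fit <- stats::aov(dev ~ groups)
  s <- summary(fit)[[1]]
  list(W = s[["F value"]][1], p = s[["Pr(>F)"]][1])
}

#' Two-sample Student's t-test (pooled variance)
#'
#' @param x,y numeric samples with >= 2 values each
#' @param welch use the Welch (unequal-variance) form instead
#' @return list with `t`, `p`, `df`
#' @export
students_t <- function(x, y, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    stop_msdyn("need >= 2 values per sample", class = "msdyn_parameter_error")
  res <- tryCatch(stats::t.test(x, y, var.equal = !welch),
                  error = function(e)
                    stop_msdyn("degenerate t-test: ", conditionMessage(e),
                               class = "msdyn_undefined_error"))
  list(t = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter))
}

#' Mean band power of a recording (Hanning-windowed Welch spectrum)
#'
#' Averages Hanning-windowed periodograms over 50%-overlapping windows
#' (default 2 s), sums the one-sided power over the requested band, and
#' averages across channels. Normalised so that the sum over all frequency
#' bins approximates the mean square amplitude (a pure sinusoid of amplitude
#' `a` carries total power `a^2/2`).
#'
#' @param rec an [eeg_recording()]
#' @param band two-element vector of band edges in Hz (default the alpha
#'   band, 8-14 Hz)
#' @param window_sec window length in seconds
#' @param overlap fractional window overlap
#' @return list with `band_power` (mean over channels), `total_power`,
#'   `per_channel` band power vector
#' @export
band_power <- function(rec, band = c(8, 14), window_sec = 2, overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs <= 2 * band[2])
    stop_msdyn("sampling rate must exceed twice the band's upper edge",
               class = "msdyn_parameter_error")
  nw <- round(window_sec * fs)
  n <- n_samples(rec)
  if (n < nw)
    stop_msdyn("recording shorter than one spectral window",
               class = "msdyn_parameter_error")
  step <- max(1, round(nw * (1 - overlap)))
  starts <- seq(1, n - nw + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nw - 1) / (nw - 1))   # Hanning
  wnorm <- nw * sum(w^2)
  freqs <- (0:(nw %/% 2)) * fs / nw
  in_band <- freqs >= band[1] & freqs <= band[2]
  spec <- matrix(0, n_channels(rec), length(freqs))
  for (s in starts) {
    seg <- rec$data[, s:(s + nw - 1), drop = FALSE]
    Y <- t(apply(seg, 1, function(ch) {
      f <- stats::fft(ch * w)
      p <- Mod(f)^2 / wnorm
      half <- p[seq_along(freqs)]
      # fold negative frequencies onto the positive side
      if (nw %% 2 == 0) half[2:(length(freqs) - 1)] <-
          2 * half[2:(length(freqs) - 1)]
      else half[2:length(freqs)] <- 2 * half[2:length(freqs)]
      half
    }))
    spec <- spec + Y
  }
  spec <- spec / length(starts)
  per_channel <- rowSums(spec[, in_band, drop = FALSE])
  list(band_power = mean(per_channel), total_power = mean(rowSums(spec)),
       per_channel = per_channel)
}
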