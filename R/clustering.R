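#' Spatial correlation between two scalp maps
#'
#' Pearson correlation across channels. Microstate comparisons use its
#' absolute value, because a topography and its polarity-reversed twin are
#' generated by the same configuration of sources.
#'
#' @param a,b numeric channel vectors of equal length
#' @return signed correlation in `[-1, 1]`
#' @export
spatial_correlation <- function(a, b) {
  if (length(a) != length(b))
    stop_msdyn("maps have different channel counts",
               class = "msdyn_dimension_error")
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop_msdyn("zero-variance map: correlation undefined",
               class = "msdyn_undefined_correlation_error")
  max(-1, min(1, sum(a * b) / (na * nb)))
}

# Center rows (average-reference space) and return the centred matrix plus
# row norms; rows with zero norm are flagged.
.center_rows <- function(X) {
  X <- X - rowMeans(X)
  nrm <- sqrt(rowSums(X^2))
  list(X = X, norm = nrm)
}

# |correlation| matrix between rows of X (maps) and rows of A (unit, zero
# mean templates); zero-variance rows get correlation 0 to everything.
.abs_corr <- function(Xc, nrm, A) {
  S <- Xc %*% t(A)
  ok <- nrm > 0
  S[ok, ] <- S[ok, , drop = FALSE] / nrm[ok]
  S[!ok, ] <- 0
  abs(S)
}

# dominant right singular vector of a set of maps (rows); polarity-proof
# template estimate. Sign fixed so the largest-|entry| channel is positive.
.dominant_map <- function(Xc) {
  v <- svd(Xc, nu = 0, nv = 1)$v[, 1]
  v <- v - mean(v)
  v <- v / sqrt(sum(v^2))
  if (v[which.max(abs(v))] < 0) v <- -v
  v
}

# GEV of an assignment: gfp^2-weighted mean squared |corr| to the assigned
# template, over total gfp^2 (gfp^2 proportional to squared row norm).
.assignment_gev <- function(nrm, corr_win) {
  w <- nrm^2
  if (sum(w) == 0) return(0)
  sum(w * corr_win^2) / sum(w)
}

#' Polarity-invariant modified k-means clustering of scalp maps
#'
#' Clusters topographies (typically GFP-peak maps) into `k` template maps,
#' treating a map and its negation as identical. Assignment maximises the
#' squared spatial correlation to a template; the template update is the
#' dominant eigenvector of the assigned maps' cross-product matrix, which is
#' invariant to the sign of every input. The best of `n_restarts` seeded
#' random initialisations by global explained variance (GEV) is returned.
#'
#' @param maps maps x channels numeric matrix (average-referenced rows)
#' @param k number of templates, `1 <= k <= nrow(maps)`
#' @param n_restarts random restarts (default 100)
#' @param seed integer seed for reproducible initialisation, or `NULL`
#' @param max_iter iteration cap per restart
#' @param tol convergence tolerance on GEV change
#' @return a `microstate_model`: list with `maps` (k x channels unit-norm
#'   templates), `k`, `gev`, `level`, `assignment` (input-map labels) and
#'   `labels_meta` (class tags, `NA` until labelled)
#' @export
modified_kmeans <- function(maps, k, n_restarts = 100, seed = NULL,
                            max_iter = 500, tol = 1e-8) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (k < 1 || k > n)
    stop_msdyn("k must be in [1, number of maps]",
               class = "msdyn_parameter_error")
  cr <- .center_rows(maps)
  Xc <- cr$X; nrm <- cr$norm
  if (all(nrm == 0))
    stop_msdyn("all maps have zero variance", class = "msdyn_parameter_error")
  seeds <- child_seeds(if (is.null(seed)) sample.int(1e6, 1) else seed,
                       n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- .mk_once(Xc, nrm, k, seeds[r], max_iter, tol)
    if (is.null(best) || fit$gev > best$gev) best <- fit
  }
  structure(list(maps = best$A, k = k, gev = best$gev, level = "subject",
                 assignment = best$assign,
                 labels_meta = rep(NA_character_, k)),
            class = "microstate_model")
}

.mk_once <- function(Xc, nrm, k, seed, max_iter, tol) {
  n <- nrow(Xc)
  init <- with_seed(seed, sample(which(nrm > 0), k))
  A <- Xc[init, , drop = FALSE] / nrm[init]
  gev_old <- -Inf; assign_old <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    S <- .abs_corr(Xc, nrm, A)
    assign <- max.col(S, ties.method = "first")
    corr_win <- S[cbind(seq_len(n), assign)]
    # re-seed empty clusters from the currently worst-fitted map
    for (j in seq_len(k)) {
      if (!any(assign == j)) {
        worst <- which.min(replace(corr_win, nrm == 0, Inf))
        assign[worst] <- j
        corr_win[worst] <- 1
      }
    }
    for (j in seq_len(k))
      A[j, ] <- .dominant_map(Xc[assign == j, , drop = FALSE])
    S <- .abs_corr(Xc, nrm, A)
    assign_new <- max.col(S, ties.method = "first")
    corr_new <- S[cbind(seq_len(n), assign_new)]
    gev <- .assignment_gev(nrm, corr_new)
    if (identical(assign_new, assign_old) || abs(gev - gev_old) < tol) {
      return(list(A = A, gev = gev, assign = assign_new))
    }
    gev_old <- gev; assign_old <- assign_new
  }
  list(A = A, gev = gev_old, assign = assign_old)
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> %d maps x %d channels, level=%s, GEV=%.3f\n",
              x$k, ncol(x$maps), x$level, x$gev))
  if (!all(is.na(x$labels_meta)))
    cat("  classes:", paste(x$labels_meta, collapse = " "), "\n")
  invisible(x)
}
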