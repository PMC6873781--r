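#' Choose the number of microstate maps by a multi-criterion vote
#'
#' Fits [modified_kmeans()] for every candidate K and scores each solution
#' with a bank of cluster-validity criteria adapted to the polarity-invariant
#' geometry (dissimilarity `d = sqrt(1 - r^2)` with `r` the spatial
#' correlation). Each criterion casts one vote — the K it considers optimal —
#' and the chosen K is the median vote (ties broken toward the smaller K).
#'
#' Default criterion bank: explained-variance (GEV) elbow, the
#' cross-validation criterion, Krzanowski-Lai, Calinski-Harabasz,
#' Davies-Bouldin, mean silhouette, and the within-cluster dispersion (W)
#' elbow.
#'
#' @param maps maps x channels matrix (e.g. pooled GFP-peak maps)
#' @param candidate_ks integer vector of K values to consider (>= 2)
#' @param seed integer seed
#' @param n_restarts restarts per K passed to [modified_kmeans()]
#' @param silhouette_cap subsample size cap for the O(n^2) silhouette
#' @return a `k_selection`: list with `chosen_k`, `votes` (named per
#'   criterion), `criterion_scores` (criteria x K matrix), `models` (fitted
#'   model per candidate K)
#' @export
choose_k_meta_criterion <- function(maps, candidate_ks = 2:8, seed = NULL,
                                    n_restarts = 20, silhouette_cap = 1000) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  candidate_ks <- sort(unique(as.integer(candidate_ks)))
  if (min(candidate_ks) < 2 || max(candidate_ks) > n - 1)
    stop_msdyn("candidate_ks must lie within [2, n_maps - 1]",
               class = "msdyn_parameter_error")
  if (length(candidate_ks) == 1) {
    return(structure(list(chosen_k = candidate_ks, votes = integer(0),
                          criterion_scores = NULL, models = NULL,
                          candidate_ks = candidate_ks),
                     class = "k_selection"))
  }
  cr <- .center_rows(maps)
  Xc <- cr$X; nrm <- cr$norm
  C <- ncol(maps)
  tot_ss <- sum(nrm^2)
  # fit one K beyond each end where possible, for the Krzanowski-Lai ratio
  fit_ks <- sort(unique(c(candidate_ks,
                          max(1L, min(candidate_ks) - 1L),
                          min(n - 1L, max(candidate_ks) + 1L))))
  seeds <- child_seeds(if (is.null(seed)) sample.int(1e6, 1) else seed,
                       length(fit_ks))
  fits <- Map(function(k, s) modified_kmeans(Xc, k, n_restarts = n_restarts,
                                             seed = s),
              fit_ks, seeds)
  names(fits) <- fit_ks
  gev <- vapply(fits, `[[`, 0, "gev")
  W <- (1 - gev) * tot_ss                     # unexplained sum of squares
  ki <- match(candidate_ks, fit_ks)

  votes <- c(
    gev_elbow = candidate_ks[.elbow(candidate_ks, gev[ki])],
    cv        = candidate_ks[which.min(.cv_criterion(W[ki], candidate_ks, n, C))],
    kl        = .kl_vote(fit_ks, W, candidate_ks, C),
    ch        = candidate_ks[which.max((tot_ss - W[ki]) / (candidate_ks - 1) /
                                         (W[ki] / (n - candidate_ks)))],
    db        = candidate_ks[which.min(vapply(ki, function(i)
                  .davies_bouldin(Xc, nrm, fits[[i]]), 0))],
    silhouette = candidate_ks[which.max(vapply(ki, function(i)
                  .mean_silhouette(Xc, nrm, fits[[i]], silhouette_cap, seed), 0))],
    w_elbow   = candidate_ks[.elbow(candidate_ks, -W[ki])]
  )
  med <- stats::median(votes)
  chosen <- if (med %in% candidate_ks) as.integer(med) else
    max(candidate_ks[candidate_ks <= med])
  scores <- rbind(gev = gev[ki], W = W[ki],
                  cv = .cv_criterion(W[ki], candidate_ks, n, C))
  colnames(scores) <- candidate_ks
  structure(list(chosen_k = chosen, votes = votes, criterion_scores = scores,
                 models = fits[as.character(candidate_ks)],
                 candidate_ks = candidate_ks),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection> chosen K = %d from {%s}\n", x$chosen_k,
              paste(x$candidate_ks, collapse = ", ")))
  if (length(x$votes)) {
    cat("  votes:\n")
    print(x$votes)
  }
  invisible(x)
}

# elbow = point of maximal perpendicular distance from the chord joining the
# curve's endpoints (curve assumed increasing-and-saturating)
.elbow <- function(ks, y) {
  x1 <- ks[1]; y1 <- y[1]; x2 <- ks[length(ks)]; y2 <- y[length(y)]
  dx <- x2 - x1; dy <- y2 - y1
  d <- abs(dy * ks - dx * y + x2 * y1 - y2 * x1) / sqrt(dx^2 + dy^2)
  which.max(d)
}

# predictive-residual criterion: residual variance inflated by the modified
# degrees-of-freedom factor ((C-1)/(C-1-K))^2
.cv_criterion <- function(W, ks, n, C) {
  sigma2 <- W / (n * (C - 1))
  fac <- ((C - 1) / pmax(C - 1 - ks, 1))^2
  sigma2 * fac
}

.kl_vote <- function(fit_ks, W, candidate_ks, C) {
  diff_k <- function(k) {
    i <- match(k, fit_ks); im1 <- match(k - 1, fit_ks)
    if (is.na(i) || is.na(im1)) return(NA_real_)
    (k - 1)^(2 / C) * W[im1] - k^(2 / C) * W[i]
  }
  kl <- vapply(candidate_ks, function(k) {
    d1 <- diff_k(k); d2 <- diff_k(k + 1)
    if (is.na(d1) || is.na(d2) || abs(d2) < .Machine$double.eps) NA_real_
    else abs(d1) / abs(d2)
  }, 0)
  ok <- which(!is.na(kl))
  if (!length(ok)) return(candidate_ks[1])
  candidate_ks[ok[which.max(kl[ok])]]
}

.davies_bouldin <- function(Xc, nrm, fit) {
  k <- fit$k
  S <- .abs_corr(Xc, nrm, fit$maps)
  corr_win <- S[cbind(seq_len(nrow(Xc)), fit$assignment)]
  s <- vapply(seq_len(k), function(j) {
    idx <- fit$assignment == j
    if (!any(idx)) return(0)
    mean(sqrt(pmax(0, 1 - corr_win[idx]^2)))
  }, 0)
  Mt <- abs(fit$maps %*% t(fit$maps))
  D <- sqrt(pmax(1 - Mt^2, 0))   # matrix first: pmax keeps its dims
  r <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j)
      (s[i] + s[j]) / max(D[i, j], 1e-12), 0))
  }, 0)
  mean(r)
}

.mean_silhouette <- function(Xc, nrm, fit, cap, seed) {
  n <- nrow(Xc)
  idx <- seq_len(n)
  if (n > cap) idx <- sort(with_seed(if (is.null(seed)) 0 else seed + 1,
                                     sample(n, cap)))
  ok <- idx[nrm[idx] > 0]
  U <- Xc[ok, , drop = FALSE] / nrm[ok]
  Dm <- sqrt(pmax(1 - (U %*% t(U))^2, 0))
  lab <- fit$assignment[ok]
  m <- length(ok)
  sil <- vapply(seq_len(m), function(i) {
    same <- lab == lab[i]; same[i] <- FALSE
    a <- if (any(same)) mean(Dm[i, same]) else 0
    b <- Inf
    for (j in setdiff(unique(lab), lab[i]))
      b <- min(b, mean(Dm[i, lab == j]))
    if (!is.finite(b)) return(0)
    (b - a) / max(a, b, 1e-12)
  }, 0)
  mean(sil)
}
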