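# Brute-force oracles, kept independent of the package internals: everything
# here works from first principles with base R.

# Mann-Whitney U by direct pair counting: #(x_i > y_j) + 0.5 #(x_i == y_j)
oracle_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# exact two-sided permutation p-value of U over all group assignments
oracle_u_exact_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pool), n1)
  us <- apply(idx, 2, function(i) oracle_u(pool[i], pool[-i]))
  u_obs <- oracle_u(x, y)
  mu <- n1 * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# Benjamini-Hochberg by the definition q_i = min_{j >= i} p_(j) * m / j
oracle_bh <- function(p, m = length(p)) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    js <- i:n
    q[i] <- min(1, min(p[o][js] * m / js))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# Spearman rho via the rank formula 1 - 6 sum(d^2) / (n (n^2 - 1)),
# valid when there are no ties
oracle_spearman_noties <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# best achievable 2-cluster GEV by exhaustive bipartition search; template of
# a part is the dominant right singular vector, fit is |Pearson| across
# channels, weights are the squared centred map norms (proportional to GFP^2)
oracle_bipartition_gev <- function(maps) {
  X <- maps - rowMeans(maps)
  n <- nrow(X)
  w <- rowSums(X^2)
  gev_of <- function(in1) {
    parts <- list(which(in1), which(!in1))
    if (!length(parts[[1]]) || !length(parts[[2]])) return(-Inf)
    corr <- numeric(n)
    for (p in parts) {
      v <- svd(X[p, , drop = FALSE], nu = 0, nv = 1)$v[, 1]
      corr[p] <- abs(apply(X[p, , drop = FALSE], 1,
                           function(r) stats::cor(r, v)))
    }
    sum(w * corr^2) / sum(w)
  }
  best <- -Inf
  for (code in 1:(2^(n - 1) - 1)) {          # map 1 fixed in part 1
    in1 <- c(TRUE, as.logical(bitwAnd(code, 2^(0:(n - 2)))))
    best <- max(best, gev_of(in1))
  }
  best
}

# quick builders -----------------------------------------------------------

# microstate model wrapper around a given template matrix
model_from_maps <- function(maps) {
  maps <- maps - rowMeans(maps)
  maps <- maps / sqrt(rowSums(maps^2))
  structure(list(maps = maps, k = nrow(maps), gev = NA_real_,
                 level = "global", assignment = NULL,
                 labels_meta = LETTERS[seq_len(nrow(maps))]),
            class = "microstate_model")
}

# sinusoid-carrier recording following a given label path over templates
toy_recording <- function(templates, labels, fs = 125, freq = 10,
                          noise_sd = 0, seed = 1) {
  set.seed(seed)
  n <- length(labels)
  a <- sin(2 * pi * freq * seq_len(n) / fs + 0.3)
  X <- templates[labels, , drop = FALSE] * a +
    matrix(rnorm(n * ncol(templates), sd = noise_sd), n, ncol(templates))
  average_reference(eeg_recording(t(X), fs = fs))
}
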