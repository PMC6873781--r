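#' Combine subject-level microstate models at group or global level
#'
#' Pools the template maps of all input models and re-clusters them with
#' [modified_kmeans()], the standard two-stage (subject then group/global)
#' derivation of a shared microstate basis. Class tags (A, B, ...) are
#' assigned by greedy maximal-|correlation| matching against a canonical
#' template set when one is supplied, otherwise in order of decreasing
#' cluster size.
#'
#' @param subject_models list of `microstate_model` objects sharing a channel
#'   count
#' @param k number of templates at this level
#' @param seed integer seed
#' @param level `"group"` or `"global"`
#' @param n_restarts restarts for the pooled clustering
#' @param canonical optional tags x channels matrix of reference
#'   topographies with rownames as tags (see [canonical_templates()])
#' @return a `microstate_model` at the requested level, maps ordered by
#'   their class tags
#' @export
multilevel_clustering <- function(subject_models, k, seed = NULL,
                                  level = c("global", "group"),
                                  n_restarts = 50, canonical = NULL) {
  level <- match.arg(level)
  ncs <- vapply(subject_models, function(m) ncol(m$maps), 0L)
  if (length(unique(ncs)) != 1)
    stop_msdyn("subject models disagree on channel count",
               class = "msdyn_dimension_error")
  pooled <- do.call(rbind, lapply(subject_models, `[[`, "maps"))
  model <- modified_kmeans(pooled, k, n_restarts = n_restarts, seed = seed)
  model$level <- level
  # order maps: canonical match if available, else by cluster size
  if (!is.null(canonical)) {
    model <- label_maps(model, canonical)
  } else {
    sz <- tabulate(model$assignment, nbins = k)
    ord <- order(sz, decreasing = TRUE)
    model$maps <- model$maps[ord, , drop = FALSE]
    model$assignment <- match(model$assignment, ord)
    model$labels_meta <- LETTERS[seq_len(k)]
  }
  model
}

#' Tag model maps against canonical topographies
#'
#' Greedy assignment: the (map, canonical) pair with the largest absolute
#' spatial correlation is matched first, then both are removed, and so on.
#' Maps left over (K larger than the canonical set) are tagged with further
#' letters in cluster order. Used for reporting only; fitting never sees the
#' canonical maps.
#'
#' @param model a `microstate_model`
#' @param canonical tags x channels matrix with rownames as tags
#' @return the model with `labels_meta` set and maps reordered by tag
#' @export
label_maps <- function(model, canonical) {
  if (ncol(canonical) != ncol(model$maps))
    stop_msdyn("canonical maps have a different channel count",
               class = "msdyn_dimension_error")
  k <- model$k
  R <- abs(stats::cor(t(model$maps), t(canonical)))
  tags <- rep(NA_character_, k)
  Rw <- R
  for (i in seq_len(min(k, nrow(canonical)))) {
    ij <- arrayInd(which.max(Rw), dim(Rw))
    tags[ij[1]] <- rownames(canonical)[ij[2]]
    Rw[ij[1], ] <- -Inf; Rw[, ij[2]] <- -Inf
  }
  extra <- which(is.na(tags))
  if (length(extra))
    tags[extra] <- LETTERS[nrow(canonical) + seq_along(extra)]
  ord <- order(tags)
  model$maps <- model$maps[ord, , drop = FALSE]
  if (!is.null(model$assignment))
    model$assignment <- match(model$assignment, ord)
  model$labels_meta <- tags[ord]
  model
}

#' Procedural canonical microstate topographies
#'
#' Idealised versions of the classical resting-state map geometries, built
#' from electrode positions: A — left-posterior to right-anterior gradient;
#' B — right-posterior to left-anterior gradient; C — anterior-posterior
#' gradient; D — fronto-central focal maximum; E — parieto-occipital focal
#' maximum. These are approximations intended solely for attaching the
#' conventional letters to data-driven maps. Coordinates: x right, y
#' anterior, z superior.
#'
#' @param positions channels x 3 unit-sphere electrode coordinates
#' @return 5 x channels matrix with rownames `A`-`E`, rows zero-mean and
#'   unit-norm
#' @export
canonical_templates <- function(positions) {
  P <- as.matrix(positions)
  stopifnot(ncol(P) == 3)
  P <- P / sqrt(rowSums(P^2))
  focal <- function(center, width = 0.8) {
    d2 <- rowSums(sweep(P, 2, center)^2)
    exp(-d2 / (2 * width^2))
  }
  M <- rbind(
    A = P[, 1] + P[, 2],                     # left-post (-x,-y) to right-ant (+x,+y)
    B = P[, 2] - P[, 1],                     # right-post to left-ant
    C = P[, 2],                              # anterior-posterior axis
    D = focal(c(0, 0.3, 0.95)),              # fronto-central peak
    E = focal(c(0, -0.7, 0.7))               # parieto-occipital peak
  )
  M <- M - rowMeans(M)
  M / sqrt(rowSums(M^2))
}
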