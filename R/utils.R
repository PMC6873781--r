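#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package functions do not
#' disturb the caller's random stream. A `NULL` seed leaves the stream alone.
#'
#' @param seed integer seed or `NULL`
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive n child seeds (< 2^31) from one master seed, reproducibly.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Quasi-uniform electrode positions on the unit sphere
#'
#' Fibonacci-lattice points, used as a stand-in montage for synthetic
#' recordings and for spherical-spline interpolation tests.
#'
#' @param n number of electrodes
#' @return `n` x 3 matrix of unit vectors
#' @export
sphere_positions <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta), y = sin(phi) * sin(theta), z = cos(phi))
}

# argmax with ties resolved to the smallest index (deterministic winner rule)
which_max_first <- function(x) which.max(x)

stop_msdyn <- function(..., class) {
  stop(structure(class = c(class, "msdyn_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
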