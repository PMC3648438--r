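#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the previous
#' RNG state afterwards so callers' random streams are not disturbed. A `NULL`
#' seed evaluates `code` against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive reproducible child seeds from a master seed
#'
#' Spawns `n` integer seeds from one master seed so that per-replicate random
#' streams are independent and the whole run is reproducible from the master
#' seed alone.
#'
#' @param master_seed integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

# squared Euclidean distances between rows of A and rows of B
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

# round half up, the convention used for class-count arithmetic
round_half_up <- function(x) floor(x + 0.5)
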