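#' Pixelverse environment configuration
#'
#' The Pixelverse is an `n x n` grid of binary cells. Between decisions the
#' grid evolves stochastically: each cell flips its state (0 <-> 1)
#' independently with probability `flip_prob` per step.
#'
#' @param n Grid side length in cells. Positive integer. Default 3, giving a
#'   state space of `2^9 = 512` configurations.
#' @param flip_prob Per-cell, per-step flip probability in `[0, 1]`.
#'   Default 0.30.
#' @return An object of class `env_config`.
#' @examples
#' cfg <- env_config()
#' cfg$n
#' @export
env_config <- function(n = 3L, flip_prob = 0.30) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, !is.na(n), n >= 1L)
  stopifnot(is.numeric(flip_prob), length(flip_prob) == 1L,
            flip_prob >= 0, flip_prob <= 1)
  structure(list(n = n, flip_prob = flip_prob), class = "env_config")
}

#' @export
print.env_config <- function(x, ...) {
  cat(sprintf("Pixelverse config: %d x %d grid, flip_prob = %g (%s states)\n",
              x$n, x$n, x$flip_prob,
              format(grid_state_count(x$n), big.mark = ",")))
  invisible(x)
}

# internal validity check for grid values
check_grid <- function(grid) {
  stopifnot(is.matrix(grid), nrow(grid) == ncol(grid),
            all(grid %in% c(0L, 1L)))
  invisible(grid)
}

#' Draw a random Pixelverse grid
#'
#' Each cell is an independent Bernoulli(0.5) draw, the maximum-entropy
#' distribution over the `2^(n^2)` configurations. Used both for run
#' initialisation and for the `reset` action. Consumes the global RNG
#' stream; seed with [set.seed()] for reproducibility.
#'
#' @param config An [env_config()].
#' @return An `n x n` integer matrix with entries in `{0, 1}`.
#' @export
random_grid <- function(config = env_config()) {
  matrix(stats::rbinom(config$n^2, 1L, 0.5), nrow = config$n)
}

#' Stochastic grid transition
#'
#' Flips each cell independently with probability `config$flip_prob`. The
#' input grid is not modified; a new grid is returned.
#'
#' @param grid An `n x n` binary integer matrix.
#' @param config An [env_config()].
#' @return The transitioned grid, same shape as the input.
#' @export
transition <- function(grid, config = env_config()) {
  check_grid(grid)
  flips <- matrix(stats::rbinom(length(grid), 1L, config$flip_prob),
                  nrow = nrow(grid))
  abs(grid - flips)
}

#' Compress a grid to its row-count signature
#'
#' The signature of a grid is the ordered tuple of per-row active-cell
#' counts `(r_1, ..., r_n)`, indexed top row to bottom row. Compression is
#' deterministic and many-to-one: at `n = 3` the 512 grids map onto
#' `4^3 = 64` distinct signatures.
#'
#' @param grid An `n x n` binary integer matrix.
#' @return An integer vector of length `n`.
#' @seealso [signature_key()] for the serialized form.
#' @export
compress <- function(grid) {
  check_grid(grid)
  as.integer(rowSums(grid))
}

#' Stability oracle
#'
#' Externally specified good/bad labelling of grids: a grid is good (+1)
#' iff it has three or fewer active cells, bad (-1) otherwise. The agent
#' never learns or adapts this rule. Note the rule depends only on the
#' total active count, so at any `n` it is measurable with respect to the
#' row-count signature.
#'
#' @param grid An `n x n` binary integer matrix.
#' @return `+1L` or `-1L`.
#' @export
classify <- function(grid) {
  check_grid(grid)
  if (sum(grid) <= 3L) 1L else -1L
}

#' Number of distinct grid configurations
#'
#' `2^(n^2)`, computed (not enumerated): 512 at `n = 3`,
#' 68,719,476,736 at `n = 6`.
#'
#' @param n Grid side length.
#' @return A double (exact for `n <= 7`, where `2^(n^2) < 2^53`).
#' @export
grid_state_count <- function(n) {
  2^(as.numeric(n)^2)
}

#' Enumerate every grid at small n
#'
#' Brute-force enumeration of all `2^(n^2)` binary grids, used by tests and
#' analytic cross-checks (e.g. counting distinct signatures, verifying that
#' the oracle is signature-measurable). Guarded to `n <= 4` (65,536 grids).
#'
#' @param n Grid side length, at most 4.
#' @return A list of `n x n` integer matrices.
#' @export
enumerate_grids <- function(n = 3L) {
  n <- as.integer(n)
  stopifnot(n >= 1L, n <= 4L)
  ncells <- n^2
  lapply(seq_len(2^ncells) - 1L, function(code) {
    bits <- as.integer(intToBits(code)[seq_len(ncells)])
    matrix(bits, nrow = n)
  })
}

#' Serialize / parse a signature
#'
#' Signatures are serialized as dash-joined integers, e.g. `(2, 0, 3)`
#' becomes `"2-0-3"`. The string form is used as the memory key in all
#' agents and in run logs.
#'
#' @param sig An integer vector of row counts.
#' @return `signature_key()`: a character scalar. `parse_signature()`: an
#'   integer vector.
#' @export
signature_key <- function(sig) {
  paste(as.integer(sig), collapse = "-")
}

#' @rdname signature_key
#' @param key A character scalar like `"2-0-3"`.
#' @export
parse_signature <- function(key) {
  as.integer(strsplit(key, "-", fixed = TRUE)[[1L]])
}
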