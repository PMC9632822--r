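#' Sample effective growth-rate vectors uniformly on the unit sphere
#'
#' Environmental uncertainty is modelled by effective growth-rate vectors
#' `theta` distributed uniformly (isotropically) on the unit
#' `(dim - 1)`-sphere. Sampling normalizes independent standard Gaussian
#' coordinates, which is exactly isotropic. An optional box constraint (one
#' closed interval per species, e.g. `[-0.9, 1]`) restricts the environment;
#' constrained draws are produced by rejection, preserving uniformity on the
#' sphere-box intersection.
#'
#' @param dim Dimension (number of species), `>= 1`.
#' @param n Number of draws, `>= 1`.
#' @param seed Integer seed; identical calls are reproducible.
#' @param constraint `NULL`, or per-coordinate bounds: a length-2 vector
#'   `c(lo, hi)` recycled to every species, or a `dim x 2` matrix of rows
#'   `c(lo, hi)`.
#' @param max_tries Cap on rejection attempts per requested point before
#'   erroring (guards against constraints excluding the whole sphere).
#' @return An `n x dim` matrix with unit-norm rows and attributes `seed` and
#'   `constraint`; also `acceptance`, the rejection acceptance fraction
#'   (`1` when unconstrained).
#' @examples
#' th <- sample_theta(3, 5, seed = 1)
#' rowSums(th^2)
#' @export
sample_theta <- function(dim, n, seed, constraint = NULL,
                         max_tries = 1e6) {
  stopifnot(dim >= 1, n >= 1)
  box <- NULL
  if (!is.null(constraint)) {
    box <- matrix(as.numeric(constraint), ncol = 2,
                  nrow = dim, byrow = is.null(dim(constraint)))
    if (any(box[, 1] > box[, 2])) {
      stop("constraint intervals must satisfy lo <= hi", call. = FALSE)
    }
  }
  withr::with_seed(seed, {
    if (is.null(box)) {
      th <- gaussian_sphere(n, dim)
      accept <- 1
    } else {
      out <- matrix(NA_real_, n, dim)
      got <- 0L
      drawn <- 0L
      accepted <- 0L
      # first batch of exactly n: with a non-binding box the output then
      # matches the unconstrained sampler draw-for-draw at the same seed
      batch <- n
      while (got < n) {
        if (drawn >= max_tries * n) {
          stop("constraint box rejected all of ", drawn,
               " sphere draws; it may exclude the whole sphere",
               call. = FALSE)
        }
        cand <- gaussian_sphere(batch, dim)
        ok <- rowSums(sweep(cand, 2, box[, 1], `>=`) &
                        sweep(cand, 2, box[, 2], `<=`)) == dim
        drawn <- drawn + batch
        accepted <- accepted + sum(ok)
        keep <- which(ok)[seq_len(min(sum(ok), n - got))]
        if (length(keep)) {
          out[(got + 1L):(got + length(keep)), ] <- cand[keep, , drop = FALSE]
          got <- got + length(keep)
        }
        batch <- max(n, 1000L)
      }
      th <- out
      accept <- accepted / drawn
    }
    attr(th, "seed") <- seed
    attr(th, "constraint") <- box
    attr(th, "acceptance") <- accept
    th
  })
}

gaussian_sphere <- function(n, dim) {
  g <- matrix(stats::rnorm(n * dim), n, dim)
  g / sqrt(rowSums(g^2))
}
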