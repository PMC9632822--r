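#' Project the columns of an interaction matrix onto a pair's plane
#'
#' The feasibility cone of the full pool lives in `|S|` dimensions; its
#' shadow on the `(theta_i, theta_j)` plane of a pair `Z = {i, j}` is the
#' conical hull of the projected columns `b_l = (a_il, a_jl)` of `A`. This
#' returns those `|S|` two-dimensional generators in column order.
#'
#' @param A An `interaction_matrix`.
#' @param Z A pair of species (indices or labels).
#' @return A `2 x |S|` matrix; row 1 holds the `theta_i` coordinates, row 2
#'   the `theta_j` coordinates, columns named by species.
#' @examples
#' project_columns(interaction_matrix(diag(3)), c(1, 2))
#' @export
project_columns <- function(A, Z) {
  idx <- resolve_members(A, Z)
  if (length(idx) != 2) {
    stop("projection is defined on a pair; got ", length(idx), " species",
         call. = FALSE)
  }
  B <- unclass(as.matrix(A))[idx, , drop = FALSE]
  rownames(B) <- species_labels(A)[idx]
  B
}

#' Spherical fraction of a planar conical hull
#'
#' Measures the fraction of the unit circle covered by the conical hull of a
#' set of 2-D generators. Generators of norm `<= tol` are dropped (they add
#' nothing to a conical hull). The hull covers the whole plane (fraction 1)
#' exactly when no closed half-plane contains all generators, detected via
#' the largest circular gap `g` between consecutive generator angles:
#' `g > pi` gives fraction `(2*pi - g) / (2*pi)`, `g = pi` (within `tol`)
#' the boundary half-plane case 0.5, and `g < pi` the full plane.
#'
#' @param generators 2-row matrix (or list of 2-vectors) of cone generators.
#' @param tol Numeric tolerance for dropping near-zero generators and for
#'   the half-plane boundary.
#' @return A `planar_cone`: list with `generators` (kept columns),
#'   `fraction`, `boundary_rays` (the two extreme rays when fraction < 1,
#'   else `NULL`), and `boundary` flag for the half-plane case.
#' @examples
#' cone_fraction_2d(cbind(c(1, 0), c(0, 1)))$fraction  # quarter plane
#' @export
cone_fraction_2d <- function(generators, tol = 1e-12) {
  if (is.list(generators)) generators <- do.call(cbind, generators)
  G <- as.matrix(generators)
  if (nrow(G) != 2) stop("generators must be 2-vectors", call. = FALSE)
  norms <- sqrt(colSums(G^2))
  keep <- which(norms > tol)
  if (!length(keep)) stop("projection degenerate: all generators are zero",
                          call. = FALSE)
  G <- G[, keep, drop = FALSE]
  ang <- atan2(G[2, ], G[1, ])
  # deterministic order: by angle, ties by original column index
  ord <- order(ang, seq_along(ang))
  ang <- ang[ord]
  gaps <- c(diff(ang), 2 * pi - (ang[length(ang)] - ang[1]))
  g <- max(gaps)
  at <- which.max(gaps)
  boundary <- abs(g - pi) <= tol
  if (boundary) {
    fraction <- 0.5
  } else if (g > pi) {
    fraction <- (2 * pi - g) / (2 * pi)
  } else {
    fraction <- 1
  }
  rays <- NULL
  if (fraction < 1) {
    # extreme rays flank the largest gap
    lo <- if (at == length(ang)) ang[1] else ang[at + 1]
    hi <- ang[at]
    rays <- cbind(c(cos(lo), sin(lo)), c(cos(hi), sin(hi)))
    colnames(rays) <- c("from", "to")
  }
  structure(list(generators = G, fraction = fraction,
                 boundary_rays = rays, boundary = boundary),
            class = "planar_cone")
}

#' @export
print.planar_cone <- function(x, ...) {
  cat(sprintf("Planar cone: %d generators, fraction %.6g%s\n",
              ncol(x$generators), x$fraction,
              if (x$boundary) " (half-plane boundary)" else ""))
  invisible(x)
}

#' @export
tidy.planar_cone <- function(x, ...) {
  tibble::tibble(fraction = x$fraction,
                 n_generators = ncol(x$generators),
                 boundary = x$boundary)
}

#' Projection of the pool's feasibility cone onto a pair plane
#'
#' `Proj(Z, S)` is the normalized measure of the shadow of the full
#' feasibility cone on the pair's `(theta_i, theta_j)` plane: the range of
#' pair environments under which coexistence of the pair is *possible* for
#' some environments of the remaining species.
#'
#' @inheritParams project_columns
#' @param tol Passed to [cone_fraction_2d()].
#' @return A `planar_cone`.
#' @export
projection_cone <- function(A, Z, tol = 1e-12) {
  cone_fraction_2d(project_columns(A, Z), tol = tol)
}

#' Projection contribution of third-party species
#'
#' `PC(Z, S) = Proj(Z, S) / F(Z)`: how much the third-party species expand
#' the range of pair environments compatible with *possible* pairwise
#' coexistence, relative to the pair's feasibility in isolation. Because the
#' pair's own cone is contained in the projection, `PC >= 1` always.
#'
#' @inheritParams project_columns
#' @return A one-row tibble: `pair`, `F_iso`, `Proj`, `PC`, `boundary`.
#' @examples
#' projection_contribution(interaction_matrix(diag(4)), c(1, 2))$PC  # 1
#' @export
projection_contribution <- function(A, Z) {
  idx <- resolve_members(A, Z)
  cone <- projection_cone(A, idx)
  f_iso <- pair_feasibility_analytic(subsystem(A, idx))
  tibble::tibble(
    pair = composition_key(species_labels(A), idx),
    F_iso = f_iso$value,
    Proj = cone$fraction,
    PC = cone$fraction / f_iso$value,
    boundary = cone$boundary
  )
}
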