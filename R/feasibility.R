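#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

# Small record for a normalized feasibility measure.
feas_estimate <- function(value, std_error = 0,
                          method = c("angle2d", "solid_angle3d",
                                     "montecarlo", "orthant"),
                          warning = NULL) {
  structure(
    list(value = value, std_error = std_error,
         method = match.arg(method), warning = warning),
    class = "feas_estimate"
  )
}

#' @export
print.feas_estimate <- function(x, ...) {
  cat(sprintf("Feasibility %.6g (std. error %.3g, method %s)\n",
              x$value, x$std_error, x$method))
  if (!is.null(x$warning)) cat("warning:", x$warning, "\n")
  invisible(x)
}

#' @export
tidy.feas_estimate <- function(x, ...) {
  tibble::tibble(value = x$value, std_error = x$std_error, method = x$method)
}

#' Feasibility of a species pair in isolation (closed form)
#'
#' For a two-species gLV system the feasibility domain is the planar cone
#' spanned by the two columns of `A`, so its normalized spherical measure is
#' the angle between the unit-normalized columns divided by `2*pi`. This is
#' the classical pairwise coexistence probability under environmental
#' uncertainty (proportional to niche overlap in competition systems).
#'
#' @param A2 A 2x2 interaction matrix (columns must be linearly independent).
#' @return A `feas_estimate` with `method = "angle2d"` and zero standard
#'   error.
#' @examples
#' pair_feasibility_analytic(interaction_matrix(diag(2)))$value  # 0.25
#' @export
pair_feasibility_analytic <- function(A2) {
  A2 <- unclass(as.matrix(A2))
  if (!all(dim(A2) == c(2, 2))) {
    stop("pair feasibility needs a 2x2 matrix, got ",
         nrow(A2), "x", ncol(A2), call. = FALSE)
  }
  n1 <- sqrt(sum(A2[, 1]^2))
  n2 <- sqrt(sum(A2[, 2]^2))
  if (n1 == 0 || n2 == 0) stop("degenerate cone: zero column", call. = FALSE)
  d <- sum(A2[, 1] * A2[, 2]) / (n1 * n2)
  if (abs(d) >= 1 - 1e-14) {
    stop("degenerate cone: columns are linearly dependent", call. = FALSE)
  }
  feas_estimate(acos(d) / (2 * pi), 0, "angle2d")
}

# Solid-angle fraction of a simplicial cone in d <= 3, closed form.
# Columns of G are the generators; order-independent.
solid_angle_fraction <- function(G) {
  d <- nrow(G)
  if (d == 1) return(0.5)
  U <- sweep(G, 2, sqrt(colSums(G^2)), `/`)
  if (d == 2) {
    dot <- min(1, max(-1, sum(U[, 1] * U[, 2])))
    return(acos(dot) / (2 * pi))
  }
  # van Oosterom-Strackee triangle solid angle
  num <- abs(det(U))
  den <- 1 + sum(U[, 1] * U[, 2]) + sum(U[, 1] * U[, 3]) +
    sum(U[, 2] * U[, 3])
  omega <- 2 * atan2(num, den)
  omega / (4 * pi)
}

#' Normalized spherical measure of a simplicial cone
#'
#' Computes the fraction of the unit sphere contained in the cone spanned by
#' the columns of `generators`. By rotation invariance of the isotropic
#' Gaussian, this equals the orthant probability `P(G^{-1} z > 0)` for
#' `z ~ N(0, I)`, which is how the Monte-Carlo estimator works in any
#' dimension. In `d = 2` the planar angle and in `d = 3` the triangle
#' solid angle give closed forms (zero standard error), used by default and
#' available as independent cross-checks of the Monte-Carlo route.
#'
#' @param generators Square numeric matrix whose columns span the cone;
#'   must be non-singular.
#' @param n Number of Monte-Carlo draws (ignored by closed forms).
#' @param seed Integer seed for the Monte-Carlo draws.
#' @param method `"auto"` (closed form for `d <= 3`, Monte Carlo otherwise),
#'   `"montecarlo"`, or `"closed"`.
#' @return A `feas_estimate`; `method` records the estimator used. A
#'   condition number above `1e12` attaches a warning to the estimate.
#' @examples
#' cone_feasibility(diag(3))$value  # one orthant: 1/8
#' @export
cone_feasibility <- function(generators, n = 1e5, seed = 1L,
                             method = c("auto", "montecarlo", "closed")) {
  method <- match.arg(method)
  G <- unclass(as.matrix(generators))
  d <- nrow(G)
  stopifnot(d == ncol(G))
  kap <- tryCatch(kappa(G, exact = FALSE), error = function(e) Inf)
  if (!is.finite(kap)) stop("singular generator matrix", call. = FALSE)
  warn <- if (kap > 1e12) {
    sprintf("ill-conditioned generators (condition number %.3g)", kap)
  }
  if (method == "closed" && d > 3) {
    stop("closed-form solid angles are available for d <= 3 only",
         call. = FALSE)
  }
  if (method != "montecarlo" && d <= 3) {
    est <- feas_estimate(solid_angle_fraction(G), 0,
                         if (d <= 2) "angle2d" else "solid_angle3d")
    est$warning <- warn
    return(est)
  }
  Ginv <- tryCatch(solve(G), error = function(e) {
    stop("singular generator matrix", call. = FALSE)
  })
  p <- withr::with_seed(seed, {
    z <- matrix(stats::rnorm(n * d), n, d)
    x <- z %*% t(Ginv)
    mean(rowSums(x > 0) == d)
  })
  feas_estimate(p, sqrt(p * (1 - p) / n), "montecarlo", warning = warn)
}

# Generators of the non-invadable region of composition C (index vector,
# possibly empty) inside pool of size d: columns a_j for j in C, -e_k for
# k outside C.
composition_generators <- function(A, members) {
  A <- unclass(as.matrix(A))
  d <- nrow(A)
  G <- -diag(d)
  if (length(members)) G[, members] <- A[, members]
  G
}

#' Assign a growth-rate vector to its non-invadable composition
#'
#' For a gLV pool with matrix `A` and a given environment `theta`, finds the
#' species composition `C` whose equilibrium is feasible and non-invadable:
#' `N_C = A[C;C]^{-1} theta_C > tol` and, for every outsider `k`,
#' `sum_{j in C} a_kj N_j - theta_k > tol` (negative invasion growth rate).
#' The empty composition matches when every `theta_i < -tol`. The search
#' enumerates all `2^|S|` subsets, so it is transparent but exponential;
#' practical for pools up to ~15 species.
#'
#' For globally stable systems exactly one composition matches. Draws on a
#' region boundary (within `tol`) or in systems without global stability can
#' match zero or several compositions; these return a diagnostic status
#' rather than an error so that partition estimates can count them as
#' unresolved.
#'
#' @param A An `interaction_matrix`.
#' @param theta Numeric growth-rate vector of length `|S|`.
#' @param tol Positivity / non-invadability margin (default `1e-12`).
#' @return A list with `status` (`"unique"`, `"none"`, or `"multiple"`),
#'   `members` (integer indices of the matched composition when unique;
#'   `integer(0)` is the empty composition), `candidates` (list of all
#'   matches), and `skipped` (count of subsets with singular sub-matrix).
#' @examples
#' assign_composition(interaction_matrix(diag(2)), c(0.6, -0.8))$members
#' @export
assign_composition <- function(A, theta, tol = 1e-12) {
  Am <- unclass(as.matrix(A))
  d <- nrow(Am)
  if (length(theta) != d) {
    stop("theta has length ", length(theta), " but pool has ", d,
         " species", call. = FALSE)
  }
  matches <- list()
  skipped <- 0L
  for (code in 0:(2^d - 1)) {
    members <- which(bitwAnd(code, 2^(seq_len(d) - 1)) > 0)
    outside <- setdiff(seq_len(d), members)
    if (length(members)) {
      Nc <- tryCatch(solve(Am[members, members, drop = FALSE], theta[members]),
                     error = function(e) NULL)
      if (is.null(Nc)) { skipped <- skipped + 1L; next }
      if (any(Nc <= tol)) next
    } else {
      Nc <- numeric(0)
    }
    if (length(outside)) {
      inv <- if (length(members)) {
        Am[outside, members, drop = FALSE] %*% Nc - theta[outside]
      } else {
        -theta[outside]
      }
      if (any(inv <= tol)) next
    }
    matches[[length(matches) + 1L]] <- members
  }
  status <- if (length(matches) == 1L) "unique"
            else if (length(matches) == 0L) "none" else "multiple"
  list(status = status,
       members = if (status == "unique") matches[[1]] else NULL,
       candidates = matches,
       skipped = skipped)
}

composition_key <- function(labels, members) {
  if (!length(members)) "(empty)" else paste(labels[members], collapse = "+")
}

#' Partition of the growth-rate sphere into composition regions
#'
#' Splits the sphere of environments `theta` into the non-invadable
#' feasibility regions of all `2^|S|` species compositions and measures each
#' region's normalized spherical mass `F(C, S)`. For globally stable systems
#' the regions are disjoint and the masses (plus the empty-composition mass,
#' which is the negative orthant, `2^-|S|`) sum to one.
#'
#' Two estimators are available: `"exact"` (closed-form planar/solid angles,
#' pools of up to 3 species, zero standard error) and `"montecarlo"` (shared
#' isotropic `theta` sample classified by [assign_composition()]; masses are
#' counts over `n`, so conservation holds exactly as a count identity).
#' Monte-Carlo draws matching zero or several compositions are reported as
#' `unresolved`, never silently dropped; more than 1% unresolved attaches a
#' warning that the system may not be globally stable.
#'
#' @param A An `interaction_matrix`.
#' @param n Monte-Carlo sample size.
#' @param seed Integer seed.
#' @param constraint Optional per-species bounds passed to [sample_theta()]
#'   (Monte-Carlo mode only).
#' @param method `"auto"` (exact when `|S| <= 3` and unconstrained),
#'   `"exact"`, or `"montecarlo"`.
#' @param tol Boundary tolerance for [assign_composition()].
#' @return A `composition_partition` object; see [tidy.composition_partition()]
#'   for the per-composition table and `glance()` for totals.
#' @examples
#' partition_mc(interaction_matrix(diag(3)))  # eight octants of mass 1/8
#' @export
partition_mc <- function(A, n = 1e4, seed = 1L, constraint = NULL,
                         method = c("auto", "exact", "montecarlo"),
                         tol = 1e-12) {
  method <- match.arg(method)
  Am <- unclass(as.matrix(A))
  d <- nrow(Am)
  labels <- species_labels(interaction_matrix(Am, rownames(Am)))
  if (method == "auto") {
    method <- if (d <= 3 && is.null(constraint)) "exact" else "montecarlo"
  }
  if (method == "exact" && d > 3) {
    stop("exact partition available for pools of at most 3 species",
         call. = FALSE)
  }
  if (method == "exact" && !is.null(constraint)) {
    stop("constrained environments require the Monte-Carlo partition",
         call. = FALSE)
  }
  codes <- 0:(2^d - 1)
  member_sets <- lapply(codes, function(code) {
    which(bitwAnd(code, 2^(seq_len(d) - 1)) > 0)
  })
  keys <- vapply(member_sets, function(m) composition_key(labels, m), "")

  if (method == "exact") {
    vals <- vapply(member_sets, function(m) {
      solid_angle_fraction(composition_generators(Am, m))
    }, 0)
    masses <- tibble::tibble(
      composition = keys,
      members = member_sets,
      size = lengths(member_sets),
      count = NA_integer_,
      value = vals,
      std_error = 0
    )
    res <- list(pool = labels, masses = masses, n_samples = NA_integer_,
                seed = NA_integer_, unresolved = 0L, method = "exact",
                tol = tol, warning = NULL)
    class(res) <- "composition_partition"
    return(res)
  }

  th <- sample_theta(d, n, seed, constraint = constraint)
  # classify all draws against each subset at once
  nsub <- length(codes)
  match_mat <- matrix(FALSE, n, nsub)
  for (s in seq_len(nsub)) {
    members <- member_sets[[s]]
    outside <- setdiff(seq_len(d), members)
    ok <- rep(TRUE, n)
    Nc <- NULL
    if (length(members)) {
      sub <- Am[members, members, drop = FALSE]
      Nc <- tryCatch(solve(sub, t(th[, members, drop = FALSE])),
                     error = function(e) NULL)
      if (is.null(Nc)) next  # singular sub-matrix: candidate skipped
      ok <- colSums(Nc > tol) == length(members)
    }
    if (length(outside)) {
      inv <- if (length(members)) {
        Am[outside, members, drop = FALSE] %*% Nc -
          t(th[, outside, drop = FALSE])
      } else {
        -t(th[, outside, drop = FALSE])
      }
      ok <- ok & colSums(inv > tol) == length(outside)
    }
    match_mat[, s] <- ok
  }
  nmatch <- rowSums(match_mat)
  unresolved <- sum(nmatch != 1L)
  uniq <- nmatch == 1L
  assigned <- as.integer(match_mat[uniq, , drop = FALSE] %*% seq_len(nsub))
  counts <- tabulate(assigned, nbins = nsub)
  p <- counts / n
  masses <- tibble::tibble(
    composition = keys,
    members = member_sets,
    size = lengths(member_sets),
    count = counts,
    value = p,
    std_error = sqrt(p * (1 - p) / n)
  )
  warn <- NULL
  if (unresolved / n > 0.01) {
    warn <- sprintf(
      "%.2f%% of draws matched zero or multiple compositions; system may not be globally stable",
      100 * unresolved / n)
  }
  res <- list(pool = labels, masses = masses, n_samples = as.integer(n),
              seed = seed, unresolved = unresolved, method = "montecarlo",
              tol = tol, warning = warn)
  class(res) <- "composition_partition"
  res
}

#' @export
print.composition_partition <- function(x, ...) {
  cat("Composition partition of a ", length(x$pool), "-species pool (",
      x$method, ")\n", sep = "")
  if (x$method == "montecarlo") {
    cat("  draws:", x$n_samples, " unresolved:", x$unresolved, "\n")
  }
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  print(dplyr::arrange(dplyr::select(x$masses, -"members"),
                       dplyr::desc(.data$value)), ...)
  invisible(x)
}

#' Tidy a composition partition
#'
#' @param x A `composition_partition`.
#' @param ... Unused.
#' @return A tibble with one row per composition: `composition`, `size`,
#'   `count` (NA in exact mode), `value` (`F(C, S)`), `std_error`.
#' @export
tidy.composition_partition <- function(x, ...) {
  dplyr::select(x$masses, -"members")
}

#' @export
glance.composition_partition <- function(x, ...) {
  emp <- x$masses$value[x$masses$size == 0]
  tibble::tibble(
    pool_size = length(x$pool),
    method = x$method,
    n_samples = x$n_samples,
    unresolved = x$unresolved,
    total_mass = sum(x$masses$value),
    empty_mass = emp
  )
}

#' Mass of a single composition in a partition
#' @param partition A `composition_partition`.
#' @param members Composition as indices or labels (may be `integer(0)` for
#'   the empty composition).
#' @return A `feas_estimate`.
#' @export
composition_mass <- function(partition, members) {
  idx <- partition_members_index(partition, members)
  row <- which(vapply(partition$masses$members, identical, TRUE, idx))
  feas_estimate(partition$masses$value[row], partition$masses$std_error[row],
                if (partition$method == "exact") {
                  if (length(partition$pool) <= 2) "angle2d" else "solid_angle3d"
                } else "montecarlo")
}

partition_members_index <- function(partition, members) {
  if (is.character(members)) {
    idx <- match(members, partition$pool)
    if (anyNA(idx)) {
      stop("unknown species: ",
           paste(members[is.na(idx)], collapse = ", "), call. = FALSE)
    }
  } else {
    idx <- as.integer(members)
  }
  if (any(idx < 1 | idx > length(partition$pool))) {
    stop("composition is not a subset of the pool", call. = FALSE)
  }
  sort(unique(idx))
}

#' Probability that a pair (or subset) coexists within the full pool
#'
#' Sums the masses of every composition region containing `Z`:
#' `P(Z, S) = sum over Z subset of C subset of S of F(C, S)`, the probability
#' under environmental uncertainty that the pool settles on a community in
#' which all members of `Z` persist.
#'
#' @param partition A `composition_partition` of the pool.
#' @param Z Nonempty subset of the pool, as indices or labels.
#' @return A `feas_estimate` (binomial standard error aggregated over the
#'   summed counts in Monte-Carlo mode).
#' @examples
#' p <- partition_mc(interaction_matrix(diag(3)))
#' pair_probability(p, c(1, 2))$value  # 2/8
#' @export
pair_probability <- function(partition, Z) {
  idx <- partition_members_index(partition, Z)
  if (!length(idx)) stop("Z must be nonempty", call. = FALSE)
  keep <- vapply(partition$masses$members, function(m) all(idx %in% m), TRUE)
  value <- sum(partition$masses$value[keep])
  if (partition$method == "exact") {
    return(feas_estimate(value, 0,
                         if (length(partition$pool) <= 2) "angle2d"
                         else "solid_angle3d"))
  }
  n <- partition$n_samples
  se <- sqrt(value * (1 - value) / n)
  feas_estimate(value, se, "montecarlo")
}

#' Long-term effect of third-party species on pairwise coexistence
#'
#' The long-term effect `LE(Z, S) = P(Z, S) / F(Z)` compares the probability
#' that the pair `Z` persists (in any composition) within the full pool
#' against its coexistence probability in isolation, both under isotropic
#' environmental uncertainty. `LE > 1` means the third-party species raise
#' the pair's long-run coexistence probability; `LE < 1` means they lower it.
#'
#' @param A Interaction matrix of the full pool.
#' @param Z A pair, as two indices or labels.
#' @param partition Optional precomputed `composition_partition` of `A`;
#'   computed on the fly otherwise.
#' @inheritParams partition_mc
#' @return A one-row tibble: `F_iso`, `P_pool`, `LE`, plus the partition's
#'   standard error on `P_pool`.
#' @examples
#' A <- interaction_matrix(diag(3))
#' long_term_effect(A, c(1, 2))$LE  # identity pool: exactly 1
#' @export
long_term_effect <- function(A, Z, partition = NULL, n = 1e5, seed = 1L,
                             method = c("auto", "exact", "montecarlo")) {
  if (is.null(partition)) {
    partition <- partition_mc(A, n = n, seed = seed,
                              method = match.arg(method))
  }
  idx <- resolve_members(A, Z)
  if (length(idx) != 2) stop("Z must be a pair of species", call. = FALSE)
  f_iso <- pair_feasibility_analytic(subsystem(A, idx))
  p <- pair_probability(partition, idx)
  tibble::tibble(
    pair = composition_key(species_labels(A), idx),
    F_iso = f_iso$value,
    P_pool = p$value,
    P_std_error = p$std_error,
    LE = p$value / f_iso$value
  )
}
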