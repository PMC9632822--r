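#' Construct a per-capita interaction matrix
#'
#' The interaction matrix `A` of a generalized Lotka-Volterra (gLV) system
#' holds the per-capita effect `a_ij` of species `j` on species `i`. Under the
#' growth law `f_i = theta_i - sum_j a_ij N_j` a positive entry is a harmful
#' (competitive) effect. Diagonal entries are intraspecific self-regulation
#' and must be strictly positive.
#'
#' @param values Square numeric matrix; entry `[i, j]` is the per-capita
#'   effect of species `j` on species `i`.
#' @param labels Optional character vector of species identifiers; defaults to
#'   existing dimnames or `"sp1"`, `"sp2"`, ...
#' @return An `interaction_matrix`: a numeric matrix with species labels as
#'   dimnames and class `c("interaction_matrix", "matrix", "array")`.
#' @examples
#' interaction_matrix(rbind(c(1, 0.22), c(0.22, 1)), c("Lp", "Lb"))
#' @export
interaction_matrix <- function(values, labels = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("matrix not square: ", nrow(values), " rows by ", ncol(values),
         " columns", call. = FALSE)
  }
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values))) {
    stop("interaction matrix entries must be finite numbers", call. = FALSE)
  }
  if (any(diag(values) <= 0)) {
    stop("diagonal (intraspecific) entries must be strictly positive",
         call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- rownames(values)
    if (is.null(labels)) labels <- paste0("sp", seq_len(nrow(values)))
  }
  if (length(labels) != nrow(values)) {
    stop("need ", nrow(values), " species labels, got ", length(labels),
         call. = FALSE)
  }
  dimnames(values) <- list(as.character(labels), as.character(labels))
  class(values) <- c("interaction_matrix", "matrix", "array")
  values
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat("Interaction matrix (", nrow(x), " species: ",
      paste(species_labels(x), collapse = ", "), ")\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Species labels of an interaction matrix
#' @param A An `interaction_matrix`.
#' @return Character vector of species identifiers.
#' @export
species_labels <- function(A) rownames(A)

#' Extract the sub-matrix of a species subset
#'
#' Restricting a gLV system to a composition `C` uses the sub-matrix
#' `A[C; C]` of interactions among the members of `C` only.
#'
#' @param A An `interaction_matrix`.
#' @param members Integer indices or character labels of the subset.
#' @return The `interaction_matrix` of the subsystem, labels preserved.
#' @export
subsystem <- function(A, members) {
  idx <- resolve_members(A, members)
  interaction_matrix(unclass(A)[idx, idx, drop = FALSE],
                     species_labels(A)[idx])
}

# labels or 1-based indices -> sorted integer indices
resolve_members <- function(A, members) {
  if (is.character(members)) {
    idx <- match(members, species_labels(A))
    if (anyNA(idx)) {
      stop("unknown species: ", paste(members[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
  } else {
    idx <- as.integer(members)
    if (any(idx < 1L | idx > nrow(A))) {
      stop("species indices must lie in 1..", nrow(A), call. = FALSE)
    }
  }
  sort(unique(idx))
}

#' Per-capita gLV growth rates
#'
#' Evaluates `f_i = theta_i - sum_j a_ij N_j`, the per-capita growth rate of
#' each species at densities `N` under effective growth rates `theta`. The
#' full time derivative used by the dynamics is `N_i * f_i`.
#'
#' @param N Nonnegative numeric vector of species densities.
#' @param theta Numeric vector of effective growth rates, same length as `N`.
#' @param A Interaction matrix of matching dimension.
#' @return Numeric vector of per-capita growth rates.
#' @examples
#' A <- interaction_matrix(diag(2))
#' percapita_growth(c(0, 0), c(0.3, -0.1), A)  # empty community: f = theta
#' @export
percapita_growth <- function(N, theta, A) {
  d <- nrow(A)
  if (length(N) != d || length(theta) != d) {
    stop("dimension mismatch: A is ", d, "x", d, ", N has length ", length(N),
         ", theta has length ", length(theta), call. = FALSE)
  }
  as.numeric(theta - unclass(A) %*% N)
}

#' Sufficient global-stability certificates for a gLV interaction matrix
#'
#' Two standard sufficient (not necessary) conditions under which the gLV
#' system with matrix `A` admits a globally stable equilibrium structure, so
#' that the non-invadable composition regions partition the growth-rate
#' sphere:
#' * `diagonally_dominant`: `a_ii > sum_{j != i} |a_ij|` for every row;
#' * `lyapunov_diagonal`: `A + t(A)` is positive definite (Volterra-Lyapunov
#'   condition with identity weighting).
#'
#' Both are certificates only: a `FALSE` verdict does not prove instability.
#'
#' @param A An `interaction_matrix` (any square numeric matrix is accepted).
#' @return A one-row tibble with logical columns `diagonally_dominant` and
#'   `lyapunov_diagonal`.
#' @examples
#' stability_verdict(interaction_matrix(diag(3)))
#' @export
stability_verdict <- function(A) {
  A <- unclass(as.matrix(A))
  dd <- all(diag(A) > rowSums(abs(A)) - abs(diag(A)))
  ev <- eigen(A + t(A), symmetric = TRUE, only.values = TRUE)$values
  tibble::tibble(
    diagonally_dominant = dd,
    lyapunov_diagonal = all(ev > 0)
  )
}

#' Read / write an interaction matrix as CSV
#'
#' The on-disk format is a plain numeric CSV, optionally carrying species
#' labels as a header row plus a leading label column. `write_interaction_matrix()`
#' followed by `read_interaction_matrix()` reproduces values to full precision
#' and labels exactly.
#'
#' @param path File path.
#' @return `read_interaction_matrix()` returns an `interaction_matrix`.
#' @export
read_interaction_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  cells <- strsplit(first, ",", fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(cells[cells != ""])))
  raw <- utils::read.csv(path, header = has_header, check.names = FALSE,
                         stringsAsFactors = FALSE)
  labels <- NULL
  if (has_header) {
    # first column carries row labels when it is non-numeric
    if (anyNA(suppressWarnings(as.numeric(raw[[1]])))) {
      labels <- as.character(raw[[1]])
      raw <- raw[, -1, drop = FALSE]
    } else {
      labels <- names(raw)
    }
  }
  m <- as.matrix(raw)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))), arr.ind = TRUE)
    stop("non-numeric cells in ", path, " at rows ",
         paste(unique(bad[, 1]), collapse = ","), call. = FALSE)
  }
  if (anyNA(m)) stop("NaN/NA cells in ", path, call. = FALSE)
  if (nrow(m) != ncol(m)) {
    stop("matrix not square: ", path, " has ", nrow(m), " rows and ",
         ncol(m), " columns", call. = FALSE)
  }
  interaction_matrix(m, labels)
}

#' @rdname read_interaction_matrix
#' @param A An `interaction_matrix` to write.
#' @param labels Write the species labels as header row / first column
#'   (default `TRUE`).
#' @export
write_interaction_matrix <- function(A, path, labels = TRUE) {
  m <- unclass(as.matrix(A))
  # %.17g round-trips doubles exactly through text
  body <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  if (labels) {
    lines <- c(paste(c("species", rownames(m)), collapse = ","),
               paste(rownames(m), body, sep = ","))
  } else {
    lines <- body
  }
  writeLines(lines, path)
  invisible(path)
}
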