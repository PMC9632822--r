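#' Random system embedding a fixed pair with random third-party species
#'
#' Generates an interaction matrix for a pool in which a fixed 2x2 pair
#' block sits at indices {1, 2} and every interaction involving the
#' remaining (third-party) species — both rows and columns — is drawn from
#' `N(0, sigma^2)`. Diagonal entries are 1. This is the design used to study
#' a fixed pair of symmetrically competing species (`a_12 = a_21 = 0.22`)
#' assembled with many random sets of third-party species.
#'
#' @param dim Pool size, `>= 3`.
#' @param pair_block 2x2 numeric matrix for the fixed pair (default the
#'   symmetric 0.22 competition block with unit diagonal).
#' @param sigma Standard deviation of third-party interaction draws
#'   (default 1).
#' @param seed Integer seed; generation is deterministic per seed.
#' @param enforce One of `"none"` (default), `"dominance"`, `"lyapunov"`:
#'   redraw the whole matrix until the corresponding certificate of
#'   [stability_verdict()] holds.
#' @param max_redraws Redraw cap before erroring when `enforce != "none"`.
#' @param labels Optional species labels.
#' @return An `interaction_matrix`.
#' @examples
#' random_third_party_system(3, sigma = 1, seed = 7)
#' @export
random_third_party_system <- function(dim = 3,
                                      pair_block = matrix(c(1, 0.22, 0.22, 1), 2),
                                      sigma = 1, seed = 1L,
                                      enforce = c("none", "dominance", "lyapunov"),
                                      max_redraws = 1e4, labels = NULL) {
  enforce <- match.arg(enforce)
  stopifnot(dim >= 3, all(dim(pair_block) == c(2, 2)))
  withr::with_seed(seed, {
    for (try in seq_len(max_redraws)) {
      A <- diag(dim)
      A[1:2, 1:2] <- pair_block
      third <- 3:dim
      A[third, ] <- matrix(stats::rnorm(length(third) * dim, 0, sigma),
                           length(third), dim)
      A[, third] <- matrix(stats::rnorm(dim * length(third), 0, sigma),
                           dim, length(third))
      # redraw overwrote the block rows/cols; restore fixed structure
      A[1:2, 1:2] <- pair_block
      diag(A) <- 1
      if (recipe_ok(A, enforce)) {
        return(interaction_matrix(A, labels))
      }
    }
    stop("could not satisfy '", enforce, "' within ", max_redraws,
         " redraws", call. = FALSE)
  })
}

recipe_ok <- function(A, enforce) {
  if (enforce == "none") return(TRUE)
  v <- stability_verdict(A)
  if (enforce == "dominance") v$diagonally_dominant else v$lyapunov_diagonal
}

#' Random full system and its sign-flipped twin
#'
#' Draws an interaction matrix with unit diagonal and `N(0, sigma^2)`
#' off-diagonals, redrawing until the requested stability certificate holds,
#' and returns it together with the matrix whose off-diagonal signs are all
#' inverted (same magnitudes). With the sign convention that positive
#' `a_ij` is harmful, the member of the pair with positive mean off-diagonal
#' is the competitive ("negative-dominated", mean effect `-<a_ij> < 0`)
#' system and its twin the cooperative one.
#'
#' @param dim Pool size.
#' @param sigma Off-diagonal standard deviation (default 0.25).
#' @param seed Integer seed.
#' @inheritParams random_third_party_system
#' @return A list with elements `matrix`, `flipped`, and `mean_effect`
#'   (`-mean(a_ij)` over off-diagonals of `matrix`).
#' @export
random_full_system <- function(dim = 5, sigma = 0.25, seed = 1L,
                               enforce = c("dominance", "lyapunov", "none"),
                               max_redraws = 1e4, labels = NULL) {
  enforce <- match.arg(enforce)
  stopifnot(dim >= 2)
  withr::with_seed(seed, {
    for (try in seq_len(max_redraws)) {
      A <- matrix(stats::rnorm(dim * dim, 0, sigma), dim, dim)
      diag(A) <- 1
      if (recipe_ok(A, enforce)) {
        off <- A[row(A) != col(A)]
        flipped <- -A
        diag(flipped) <- 1
        return(list(matrix = interaction_matrix(A, labels),
                    flipped = interaction_matrix(flipped, labels),
                    mean_effect = -mean(off)))
      }
    }
    stop("could not satisfy '", enforce, "' within ", max_redraws,
         " redraws", call. = FALSE)
  })
}

#' Canonical worked-example interaction matrices
#'
#' Small fixed matrices used throughout the documentation and tests:
#' * `pair22`: the symmetric competition pair, off-diagonals 0.22;
#' * `three_species`: a diagonally dominant 3-species system
#'   (off-diagonals 0.22/0.56/0.37);
#' * `unstable_a`, `unstable_b`, `unstable_c`: 3-species systems with large
#'   interspecific effects that are not globally stable (`c` mixes strong
#'   harmful and beneficial effects);
#' * `identity_2`, `identity_3`, `identity_5`: non-interacting pools.
#'
#' @return Named list of `interaction_matrix` objects.
#' @export
canonical_fixtures <- function() {
  list(
    pair22 = interaction_matrix(rbind(c(1, 0.22), c(0.22, 1))),
    three_species = interaction_matrix(rbind(c(1, 0.22, 0.56),
                                             c(0.22, 1, 0.37),
                                             c(0.56, 0.37, 1))),
    unstable_a = interaction_matrix(rbind(c(1, 0.22, 1.56),
                                          c(0.22, 1, 1.37),
                                          c(0.7, 0.8, 1))),
    unstable_b = interaction_matrix(rbind(c(1, 1.22, 1.56),
                                          c(1.22, 1, 1.37),
                                          c(1.7, 1.8, 1))),
    unstable_c = interaction_matrix(rbind(c(1, 1.22, 1.56),
                                          c(-1.22, 1, 1.37),
                                          c(1.7, -1.8, 1))),
    identity_2 = interaction_matrix(diag(2)),
    identity_3 = interaction_matrix(diag(3)),
    identity_5 = interaction_matrix(diag(5))
  )
}

treatment_labels <- function(labels) {
  pairs <- utils::combn(labels, 2, simplify = FALSE)
  c(paste0("mono:", labels),
    vapply(pairs, function(p) paste0("pair:", p[1], "+", p[2]), ""),
    "poly:all")
}

treatment_members <- function(treatment, labels) {
  if (startsWith(treatment, "mono:")) {
    sub("^mono:", "", treatment)
  } else if (startsWith(treatment, "pair:")) {
    strsplit(sub("^pair:", "", treatment), "+", fixed = TRUE)[[1]]
  } else if (treatment == "poly:all") {
    labels
  } else {
    stop("unrecognized treatment: ", treatment, call. = FALSE)
  }
}

#' Generate a synthetic community experiment table
#'
#' Emulates the design of replicated gnotobiotic community experiments (five
#' taxa, one final-density readout per species per replicate): monoculture
#' treatments for every species, co-culture treatments for every pair, and a
#' poly-culture of the full pool, each replicated `reps` times, with
#' multiplicative log-normal measurement noise.
#'
#' Two generation modes:
#' * `"dynamics"`: per replicate and treatment an environment `theta` is
#'   drawn on the unit `|S|`-sphere (optionally box-constrained), the
#'   treatment's subsystem is integrated with the RK4 protocol from uniform
#'   initial abundances, and final densities are recorded (runs hitting the
#'   divergence cap are counted in attribute `"n_diverged"`).
#' * `"equilibrium"`: deterministic final states at the non-invadable gLV
#'   equilibrium for a fixed `theta` (default all 1), the reference case in
#'   which interaction inference is exact at zero noise.
#'
#' @param A An `interaction_matrix` (labels become the species names).
#' @param reps Replicates per treatment (default 48).
#' @param noise_sd Standard deviation of log-normal multiplicative noise on
#'   final densities (0 = noiseless).
#' @param seed Integer seed.
#' @param mode `"dynamics"` or `"equilibrium"`.
#' @param config [sim_config()] for the dynamics mode.
#' @param theta Fixed growth-rate vector for the equilibrium mode (default
#'   `rep(1, |S|)`).
#' @param constraint Optional per-species bounds for the sphere draws.
#' @return A tibble with columns `replicate`, `treatment`, `species`,
#'   `density` — one row per species of each treatment of each replicate.
#' @export
synthetic_experiment <- function(A, reps = 48, noise_sd = 0, seed = 1L,
                                 mode = c("dynamics", "equilibrium"),
                                 config = sim_config(),
                                 theta = NULL, constraint = NULL) {
  mode <- match.arg(mode)
  stopifnot(reps >= 1)
  labels <- species_labels(A)
  d <- nrow(A)
  treatments <- treatment_labels(labels)
  n_diverged <- 0L

  rows <- withr::with_seed(seed, {
    out <- list()
    for (tr in treatments) {
      mem <- treatment_members(tr, labels)
      idx <- match(mem, labels)
      sub <- subsystem(A, idx)
      if (mode == "dynamics") {
        th_full <- gaussian_sphere_constrained(reps, d, constraint)
        th <- th_full[, idx, drop = FALSE]
        n0 <- draw_init(reps, length(idx), config)
        res <- glv_batch(sub, th, n0, config)
        final <- res$final
        n_diverged <- n_diverged + sum(res$diverged)
      } else {
        th_fix <- if (is.null(theta)) rep(1, d) else theta
        eq <- equilibrium_state(sub, th_fix[idx])
        final <- matrix(eq, reps, length(idx), byrow = TRUE)
      }
      if (noise_sd > 0) {
        final <- final * exp(matrix(stats::rnorm(length(final), 0, noise_sd),
                                    nrow(final)))
      }
      out[[tr]] <- tibble::tibble(
        replicate = rep(seq_len(reps), each = length(idx)),
        treatment = tr,
        species = rep(mem, times = reps),
        density = as.numeric(t(final))
      )
    }
    out
  })
  tab <- dplyr::bind_rows(rows)
  attr(tab, "n_diverged") <- n_diverged
  tab
}

gaussian_sphere_constrained <- function(n, d, constraint) {
  if (is.null(constraint)) return(gaussian_sphere(n, d))
  box <- matrix(as.numeric(constraint), ncol = 2, nrow = d,
                byrow = is.null(dim(constraint)))
  out <- matrix(NA_real_, n, d)
  got <- 0L
  tries <- 0L
  while (got < n) {
    if (tries > 1e6) stop("constraint rejected all draws", call. = FALSE)
    cand <- gaussian_sphere(max(n, 1000L), d)
    ok <- rowSums(sweep(cand, 2, box[, 1], `>=`) &
                    sweep(cand, 2, box[, 2], `<=`)) == d
    keep <- which(ok)[seq_len(min(sum(ok), n - got))]
    if (length(keep)) {
      out[(got + 1L):(got + length(keep)), ] <- cand[keep, , drop = FALSE]
      got <- got + length(keep)
    }
    tries <- tries + 1L
  }
  out
}

# non-invadable equilibrium densities for a fixed theta (zero for absent
# species); used by the equilibrium generation mode
equilibrium_state <- function(A, theta) {
  res <- assign_composition(A, theta)
  N <- numeric(nrow(A))
  if (res$status == "unique" && length(res$members)) {
    N[res$members] <- solve(unclass(A)[res$members, res$members, drop = FALSE],
                            theta[res$members])
  }
  N
}
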