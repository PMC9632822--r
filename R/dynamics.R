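#' Simulation protocol settings
#'
#' Bundles the fixed-step integration protocol used for short-term
#' (finite-time) coexistence frequencies: classic 4th-order Runge-Kutta with
#' total time 200 and step 0.01, an extinction threshold of `1e-6` applied to
#' final abundances only, and initial abundances drawn uniformly on (0, 1)
#' per species per draw (or a common constant).
#'
#' @param total_time Integration horizon (default 200).
#' @param step Fixed step size (default 0.01).
#' @param extinction_threshold Final abundance below which a species is
#'   classified statistically extinct (default `1e-6`).
#' @param n_reps Default number of environment draws for frequency
#'   estimation.
#' @param seed Integer seed for initial conditions.
#' @param init_mode `"uniform01"` or `"constant"`.
#' @param init_value Common initial abundance when `init_mode = "constant"`.
#' @param div_threshold Abundance beyond which a trajectory is declared
#'   diverged (non-globally-stable systems can blow up).
#' @return A `sim_config` list.
#' @export
sim_config <- function(total_time = 200, step = 0.01,
                       extinction_threshold = 1e-6, n_reps = 1000,
                       seed = 1L, init_mode = c("uniform01", "constant"),
                       init_value = 0.5, div_threshold = 1e12) {
  stopifnot(total_time > 0, step > 0, step <= total_time,
            extinction_threshold > 0, n_reps >= 1)
  structure(list(total_time = total_time, step = step,
                 extinction_threshold = extinction_threshold,
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 init_mode = match.arg(init_mode), init_value = init_value,
                 div_threshold = div_threshold),
            class = "sim_config")
}

# initial-condition matrix for n draws of d species, consuming the current
# RNG stream (callers wrap in withr::with_seed)
draw_init <- function(n, d, config) {
  if (config$init_mode == "uniform01") {
    matrix(stats::runif(n * d), n, d)
  } else {
    matrix(config$init_value, n, d)
  }
}

# batch RK4 over rows of theta/n0; returns list(final, diverged)
glv_batch <- function(A, theta, n0, config) {
  rk4_glv_batch_cpp(unclass(as.matrix(A)), theta, n0,
                    config$total_time, config$step, config$div_threshold)
}

#' Integrate one gLV trajectory with fixed-step RK4
#'
#' @param A An `interaction_matrix`.
#' @param theta Numeric growth-rate vector.
#' @param N0 Nonnegative initial abundances.
#' @param config A [sim_config()].
#' @return A list: `final_state` (named abundances at `total_time`),
#'   `survivors` (indices with final abundance at or above the extinction
#'   threshold), `diverged` flag (trajectory hit the abundance cap), and
#'   `time`.
#' @examples
#' A <- interaction_matrix(matrix(1))
#' rk4_integrate(A, theta = 1, N0 = 0.5, sim_config())$final_state  # ~1
#' @export
rk4_integrate <- function(A, theta, N0, config = sim_config()) {
  d <- nrow(A)
  if (length(theta) != d || length(N0) != d) {
    stop("dimension mismatch: A is ", d, "x", d, ", theta has length ",
         length(theta), ", N0 has length ", length(N0), call. = FALSE)
  }
  if (any(N0 < 0)) stop("initial abundances must be nonnegative",
                        call. = FALSE)
  res <- glv_batch(A, matrix(theta, 1), matrix(N0, 1), config)
  final <- drop(res$final)
  names(final) <- species_labels(A)
  list(final_state = final,
       survivors = which(final >= config$extinction_threshold),
       diverged = res$diverged[1],
       time = config$total_time)
}

#' Simulated pairwise coexistence frequencies
#'
#' Estimates, per pair `Z`, the finite-time coexistence frequency within the
#' full pool (`Sim(Z, S)`) and in isolation (`Sim(Z)`) over a shared sample
#' of environments. Each `theta` draw is integrated once for the full pool;
#' for the isolation runs the pair's own `theta` components are reused
#' (controlling for the environment) with the 2x2 sub-matrix and fresh pair
#' initial conditions from the same seed stream. A pair coexists in a run
#' when both members' final abundances reach the extinction threshold.
#' Runs that hit the divergence cap (finite-time blow-up, possible only
#' without a globally stable equilibrium) are counted in `n_diverged`;
#' blown-up species saturate at the cap, so they classify as present while
#' competitive exclusion of the others still completes.
#'
#' @param A An `interaction_matrix`.
#' @param pairs List of pairs (each two indices or labels), or `NULL` for
#'   all pairs in the pool.
#' @param thetas Environment sample from [sample_theta()] (`n x |S|`), or an
#'   integer number of draws to sample internally with `config$seed`.
#' @param config A [sim_config()].
#' @return A tibble with one row per pair: `pair`, `Sim_pool`, `Sim_iso`,
#'   `SE` (short-term effect `Sim_pool / Sim_iso`), `SE_std_error`
#'   (delta-method binomial error), `n_pool`, `n_iso` (effective draws),
#'   `n_diverged`.
#' @export
simulate_frequencies <- function(A, pairs = NULL, thetas = NULL,
                                 config = sim_config()) {
  d <- nrow(A)
  labels <- species_labels(A)
  if (is.null(pairs)) {
    pairs <- utils::combn(d, 2, simplify = FALSE)
  }
  if (!length(pairs)) stop("empty pair list", call. = FALSE)
  pairs <- lapply(pairs, function(z) {
    idx <- resolve_members(A, z)
    if (length(idx) != 2) stop("each pair must have two species",
                               call. = FALSE)
    idx
  })
  if (is.null(thetas)) thetas <- config$n_reps
  if (is.numeric(thetas) && length(thetas) == 1) {
    thetas <- sample_theta(d, thetas, config$seed)
  }
  if (ncol(thetas) != d) {
    stop("thetas drawn in dimension ", ncol(thetas), " but pool has ", d,
         " species", call. = FALSE)
  }
  n <- nrow(thetas)
  eta <- config$extinction_threshold

  # one seed stream for all initial conditions: full pool first, then pairs
  inits <- withr::with_seed(config$seed, {
    c(list(full = draw_init(n, d, config)),
      lapply(pairs, function(z) draw_init(n, 2, config)))
  })
  full <- glv_batch(A, thetas, inits$full, config)
  full_alive <- full$final >= eta

  rows <- lapply(seq_along(pairs), function(k) {
    z <- pairs[[k]]
    sub <- unclass(A)[z, z, drop = FALSE]
    iso <- glv_batch(sub, thetas[, z, drop = FALSE], inits[[k + 1L]], config)
    n_pool <- n
    n_iso <- n
    sim_pool <- mean(full_alive[, z[1]] & full_alive[, z[2]])
    alive_iso <- iso$final >= eta
    sim_iso <- mean(alive_iso[, 1] & alive_iso[, 2])
    se <- if (isTRUE(sim_iso > 0)) sim_pool / sim_iso else NA_real_
    se_sd <- if (isTRUE(sim_iso > 0) && isTRUE(sim_pool > 0)) {
      se * sqrt((1 - sim_pool) / (sim_pool * n_pool) +
                  (1 - sim_iso) / (sim_iso * n_iso))
    } else NA_real_
    tibble::tibble(
      pair = composition_key(labels, z),
      i = labels[z[1]], j = labels[z[2]],
      Sim_pool = sim_pool, Sim_iso = sim_iso,
      SE = se, SE_std_error = se_sd,
      n_pool = n_pool, n_iso = n_iso,
      n_diverged = sum(full$diverged) + sum(iso$diverged)
    )
  })
  dplyr::bind_rows(rows)
}

#' Finite-time composition frequencies of the full pool
#'
#' Integrates the full pool for each environment draw and tabulates the
#' surviving composition (species with final abundance at or above the
#' extinction threshold). As the horizon grows these frequencies converge to
#' the analytic partition masses of [partition_mc()] for globally stable
#' systems.
#'
#' @inheritParams simulate_frequencies
#' @return A tibble: `composition`, `size`, `count`, `freq`; draws that hit
#'   the divergence cap are counted in attribute `"n_diverged"`.
#' @export
simulate_composition_frequencies <- function(A, thetas = NULL,
                                             config = sim_config()) {
  d <- nrow(A)
  labels <- species_labels(A)
  if (is.null(thetas)) thetas <- config$n_reps
  if (is.numeric(thetas) && length(thetas) == 1) {
    thetas <- sample_theta(d, thetas, config$seed)
  }
  n <- nrow(thetas)
  n0 <- withr::with_seed(config$seed, draw_init(n, d, config))
  res <- glv_batch(A, thetas, n0, config)
  alive <- res$final >= config$extinction_threshold
  key <- apply(alive, 1, function(a) composition_key(labels, which(a)))
  tab <- table(key)
  out <- tibble::tibble(
    composition = names(tab),
    count = as.integer(tab),
    freq = as.integer(tab) / n
  )
  out$size <- vapply(out$composition, function(k) {
    if (k == "(empty)") 0L else length(strsplit(k, "+", fixed = TRUE)[[1]])
  }, 0L)
  out <- out[, c("composition", "size", "count", "freq")]
  attr(out, "n_diverged") <- sum(res$diverged)
  out
}

#' Short-term effect of third-party species
#'
#' `SE(Z, S) = Sim(Z, S) / Sim(Z)`: the ratio of simulated finite-time
#' pairwise coexistence frequencies with and without third-party species.
#' When the isolation frequency is zero the effect is undefined and the raw
#' frequencies are returned with `undefined = TRUE` rather than an error.
#'
#' @param freqs Frequency table from [simulate_frequencies()].
#' @param Z Optional pair (indices into the pool labels, or label vector) to
#'   select a single row; default all rows.
#' @return The selected rows with columns `SE`, `SE_std_error`, and an
#'   `undefined` flag.
#' @export
short_term_effect <- function(freqs, Z = NULL) {
  out <- freqs
  if (!is.null(Z)) {
    if (is.numeric(Z)) {
      stop("pass Z as species labels, e.g. c(\"sp1\", \"sp2\")",
           call. = FALSE)
    }
    keep <- (out$i %in% Z) & (out$j %in% Z)
    if (!any(keep)) stop("pair not found in frequency table", call. = FALSE)
    out <- out[keep, ]
  }
  dplyr::mutate(out, undefined = !is.na(.data$Sim_iso) & .data$Sim_iso == 0)
}

#' Buffering effect
#'
#' `BE(Z, S) = SE(Z, S) / LE(Z, S)`: the transient benefit (`> 1`) or
#' disadvantage (`< 1`) of third-party species relative to the long-term
#' expectation. Equals 1 when simulated frequencies exceed their analytic
#' counterparts in equal proportion with and without third-party species.
#'
#' @param SE Short-term effect value(s).
#' @param LE Long-term effect value(s), strictly positive.
#' @return Numeric `SE / LE`.
#' @export
buffering_effect <- function(SE, LE) {
  if (any(LE <= 0, na.rm = TRUE)) {
    stop("long-term effect must be strictly positive", call. = FALSE)
  }
  SE / LE
}
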