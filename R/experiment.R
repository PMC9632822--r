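#' Read / write a replicate experiment table
#'
#' The experiment CSV has columns `replicate`, `treatment`, `species`,
#' `density`, with treatments encoded `"mono:Lp"`, `"pair:Lp+Lb"`,
#' `"poly:all"`. Densities are final (end-of-trial) values in any consistent
#' unit.
#'
#' @param path CSV file path.
#' @return A tibble with the four columns above.
#' @export
read_experiment_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  validate_experiment_table(tab)
}

#' @rdname read_experiment_table
#' @param table Experiment tibble to write.
#' @export
write_experiment_table <- function(table, path) {
  readr::write_csv(validate_experiment_table(table), path)
  invisible(path)
}

validate_experiment_table <- function(table) {
  need <- c("replicate", "treatment", "species", "density")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("experiment table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(table$density < 0, na.rm = TRUE) || anyNA(table$density)) {
    stop("densities must be nonnegative and non-missing", call. = FALSE)
  }
  tibble::as_tibble(table)
}

# find the treatment string holding exactly the species set Z
find_treatment <- function(table, Z, kind = c("pair", "poly", "mono")) {
  kind <- match.arg(kind)
  trs <- unique(table$treatment[startsWith(table$treatment, paste0(kind, ":"))])
  labels <- unique(table$species)
  for (tr in trs) {
    if (setequal(treatment_members(tr, labels), Z)) return(tr)
  }
  stop("no ", kind, " treatment for {", paste(Z, collapse = ", "), "}",
       call. = FALSE)
}

#' Replicate coexistence frequency of a species subset
#'
#' Within one treatment, classifies each species in each replicate as
#' persisting or statistically extinct: extinct when its relative abundance
#' (density over the replicate's total density) is below `rel_threshold`.
#' The frequency is the fraction of replicates in which every member of `Z`
#' persists. Replicates with zero total density count as all-extinct and
#' are reported in `n_zero_total`.
#'
#' @param table Experiment tibble (see [read_experiment_table()]).
#' @param Z Character vector of species labels to track.
#' @param treatment Treatment string (e.g. `"poly:all"`), or one of the
#'   shortcuts `"pair"` / `"poly"` which resolve the treatment containing
#'   exactly / the pool of `Z`.
#' @param rel_threshold Relative-abundance extinction threshold in (0, 1);
#'   default 0.01 (1%), with 0.10 the standard robustness alternative.
#' @return A one-row tibble: `treatment`, `numerator`, `denominator`,
#'   `frequency`, `n_zero_total`.
#' @export
coexistence_frequency <- function(table, Z, treatment,
                                  rel_threshold = 0.01) {
  stopifnot(rel_threshold > 0, rel_threshold < 1)
  table <- validate_experiment_table(table)
  if (treatment == "pair") treatment <- find_treatment(table, Z, "pair")
  if (treatment == "poly") {
    treatment <- unique(table$treatment[startsWith(table$treatment, "poly:")])
    if (length(treatment) != 1) stop("need exactly one poly treatment",
                                     call. = FALSE)
  }
  rows <- table[table$treatment == treatment, ]
  if (!nrow(rows)) stop("no replicates for treatment ", treatment,
                        call. = FALSE)
  present <- unique(rows$species)
  miss <- setdiff(Z, present)
  if (length(miss)) {
    stop("treatment ", treatment, " does not contain: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  per_rep <- rows |>
    dplyr::group_by(.data$replicate) |>
    dplyr::mutate(total = sum(.data$density)) |>
    dplyr::ungroup() |>
    dplyr::mutate(persists = .data$total > 0 &
                    .data$density / pmax(.data$total, .Machine$double.xmin) >=
                      rel_threshold)
  zero_total <- per_rep |>
    dplyr::distinct(.data$replicate, .data$total) |>
    dplyr::summarise(k = sum(.data$total == 0)) |>
    dplyr::pull(.data$k)
  ok <- per_rep |>
    dplyr::filter(.data$species %in% Z) |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(all_in = all(.data$persists)) |>
    dplyr::pull(.data$all_in)
  tibble::tibble(
    treatment = treatment,
    numerator = sum(ok),
    denominator = length(ok),
    frequency = sum(ok) / length(ok),
    n_zero_total = zero_total
  )
}

#' Experimental effect of third-party species on pairwise coexistence
#'
#' `EE(Z, S) = freq(Z in poly-culture) / freq(Z in pair co-culture)`: the
#' replicate-based analogue of the simulated short-term effect. When the
#' pair never coexists in co-culture the effect is undefined and both raw
#' frequencies are returned with `undefined = TRUE`.
#'
#' @inheritParams coexistence_frequency
#' @return A one-row tibble: `pair`, `freq_pool`, `freq_iso`, `EE`,
#'   `undefined`, plus the replicate counts.
#' @export
experimental_effect <- function(table, Z, rel_threshold = 0.01) {
  if (length(Z) != 2) stop("Z must be a pair of species labels",
                           call. = FALSE)
  pool <- coexistence_frequency(table, Z, "poly", rel_threshold)
  iso <- coexistence_frequency(table, Z, "pair", rel_threshold)
  undefined <- iso$frequency == 0
  tibble::tibble(
    pair = paste(Z, collapse = "+"),
    freq_pool = pool$frequency,
    freq_iso = iso$frequency,
    n_pool = pool$denominator,
    n_iso = iso$denominator,
    EE = if (undefined) NA_real_ else pool$frequency / iso$frequency,
    undefined = undefined
  )
}

#' Experimental buffering effect
#'
#' `EBE(Z, S) = EE(Z, S) / LE(Z, S)`: the experimental effect relative to
#' the analytic long-term expectation.
#'
#' @param EE Experimental effect value(s).
#' @param LE Long-term effect value(s), strictly positive.
#' @return Numeric `EE / LE`.
#' @export
experimental_buffering <- function(EE, LE) buffering_effect(EE, LE)

#' Infer a pairwise interaction matrix from final-density experiments
#'
#' Steady-state inference from monoculture and pairwise co-culture mean
#' final densities, with intraspecific effects normalized to `a_ii = 1`.
#' Densities of species `i` are first scaled by its monoculture mean
#' (`theta_hat_i`, the gLV monoculture carrying capacity when `a_ii = 1`).
#' Then, writing `n_i(j)` for the normalized mean density of `i` in the
#' `(i, j)` co-culture,
#' `a_ij = (1 - n_i(j)) / n_j(i)`, which is exact at the gLV pairwise
#' equilibrium when monoculture equilibria share a common scale.
#'
#' @param table Experiment tibble with every monoculture and every pairwise
#'   co-culture.
#' @return An `interaction_matrix` with unit diagonal; attributes
#'   `theta_hat` (monoculture means) and `report` (a tibble of the means
#'   and replicate counts used).
#' @export
infer_interactions <- function(table) {
  table <- validate_experiment_table(table)
  mono_tr <- unique(table$treatment[startsWith(table$treatment, "mono:")])
  labels <- vapply(mono_tr, function(tr) sub("^mono:", "", tr), "")
  if (!length(labels)) stop("no monoculture treatments found", call. = FALSE)
  sp_all <- unique(table$species)
  miss <- setdiff(sp_all, labels)
  if (length(miss)) {
    stop("missing monoculture for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  labels <- sp_all[sp_all %in% labels]  # pool order = order of appearance
  d <- length(labels)
  mono_mean <- vapply(labels, function(sp) {
    rows <- table[table$treatment == paste0("mono:", sp) &
                    table$species == sp, ]
    mean(rows$density)
  }, 0)
  if (any(mono_mean <= 0)) {
    stop("zero mean monoculture density for: ",
         paste(labels[mono_mean <= 0], collapse = ", "), call. = FALSE)
  }
  A <- diag(d)
  report <- list()
  for (i in seq_len(d)) {
    for (j in seq_len(d)) {
      if (i == j) next
      tr <- find_treatment(table, c(labels[i], labels[j]), "pair")
      rows <- table[table$treatment == tr, ]
      ni <- mean(rows$density[rows$species == labels[i]]) / mono_mean[i]
      nj <- mean(rows$density[rows$species == labels[j]]) / mono_mean[j]
      if (nj == 0) {
        stop("species ", labels[j], " has zero mean co-culture density ",
             "with ", labels[i], "; a_", i, j, " undefined", call. = FALSE)
      }
      aij <- (1 - ni) / nj
      A[i, j] <- aij
      report[[length(report) + 1L]] <- tibble::tibble(
        i = labels[i], j = labels[j], treatment = tr,
        n_reps = length(unique(rows$replicate)),
        mean_i_co = ni * mono_mean[i], mean_j_co = nj * mono_mean[j],
        a_ij = aij
      )
    }
  }
  out <- interaction_matrix(A, labels)
  attr(out, "theta_hat") <- mono_mean
  attr(out, "report") <- dplyr::bind_rows(report)
  out
}

#' Mean interaction summary
#'
#' Reports the mean off-diagonal interaction as a *mean effect*
#' `-<a_ij>`: negative values indicate a competition-dominated
#' (harm-dominated) system under the convention that positive `a_ij`
#' reduces growth.
#'
#' @param A An `interaction_matrix`.
#' @return A one-row tibble: `mean_a_offdiag`, `mean_effect`.
#' @export
mean_interaction <- function(A) {
  m <- unclass(as.matrix(A))
  off <- m[row(m) != col(m)]
  tibble::tibble(mean_a_offdiag = mean(off), mean_effect = -mean(off))
}
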