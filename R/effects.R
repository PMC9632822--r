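#' All system-level effects for the pairs of a pool
#'
#' One-stop computation of the per-pair effect record for an interaction
#' matrix: pair feasibility in isolation `F(Z)`, projection `Proj(Z, S)` and
#' projection contribution `PC`, pool coexistence probability `P(Z, S)` and
#' long-term effect `LE`, and (optionally) simulated frequencies with the
#' short-term effect `SE` and buffering effect `BE = SE / LE`. The full-pool
#' dynamics are integrated once per environment draw and shared across
#' pairs.
#'
#' @param A An `interaction_matrix`.
#' @param pairs List of pairs (indices or labels), default all pairs.
#' @param partition Optional precomputed `composition_partition`; otherwise
#'   exact (pools of up to 3) or Monte Carlo with `n_partition` draws.
#' @param n_partition Monte-Carlo partition sample size.
#' @param simulate Compute `SE`/`BE` by simulation (default `TRUE`).
#' @param n_draws Environment draws for the simulated frequencies.
#' @param seed Integer seed; the partition, the environment sample, and the
#'   initial conditions use seeds derived from it.
#' @param config [sim_config()] integration protocol (its `seed` is
#'   overridden by the derived seed).
#' @param constraint Optional per-species growth-rate bounds, applied to
#'   both the partition and the simulation environments.
#' @return A tibble with one row per pair (`pair`, `i`, `j`, `F_iso`,
#'   `Proj`, `PC`, `P_pool`, `LE`, and when simulated `Sim_pool`, `Sim_iso`,
#'   `SE`, `SE_std_error`, `BE`, `n_pool`, `n_iso`, `n_diverged`).
#' @examples
#' system_effects(interaction_matrix(diag(3)), n_draws = 100, seed = 1)
#' @export
system_effects <- function(A, pairs = NULL, partition = NULL,
                           n_partition = 1e5, simulate = TRUE,
                           n_draws = 1000, seed = 1L,
                           config = sim_config(), constraint = NULL) {
  d <- nrow(A)
  if (is.null(pairs)) pairs <- utils::combn(d, 2, simplify = FALSE)
  pairs <- lapply(pairs, function(z) resolve_members(A, z))
  if (is.null(partition)) {
    method <- if (d <= 3 && is.null(constraint)) "exact" else "montecarlo"
    partition <- partition_mc(A, n = n_partition, seed = seed,
                              constraint = constraint, method = method)
  }
  analytic <- dplyr::bind_rows(lapply(pairs, function(z) {
    pc <- projection_contribution(A, z)
    le <- long_term_effect(A, z, partition = partition)
    dplyr::bind_cols(
      tibble::tibble(i = species_labels(A)[z[1]],
                     j = species_labels(A)[z[2]]),
      pc[, c("pair", "F_iso", "Proj", "PC")],
      le[, c("P_pool", "P_std_error", "LE")]
    )
  }))
  analytic <- dplyr::relocate(analytic, "pair")
  if (!simulate) return(analytic)
  thetas <- sample_theta(d, n_draws, seed + 1L, constraint = constraint)
  config$seed <- seed + 2L
  freqs <- simulate_frequencies(A, pairs, thetas, config)
  out <- dplyr::left_join(analytic,
                          dplyr::select(freqs, -"i", -"j"), by = "pair")
  dplyr::mutate(out, BE = buffering_effect(.data$SE, .data$LE))
}

#' Cartographic classification of pairwise effect records
#'
#' Classifies each pair by the quadrant of its long-term effect (beneficial
#' `LE > 1` vs detrimental `LE < 1`) against its buffering effect
#' (`BE > 1` buffered vs `BE < 1` unbuffered; the experimental `EBE` can be
#' supplied instead via `be_col`). Values within `tol` of 1 on either axis
#' are labelled `"boundary"`.
#'
#' @param records Tibble of effect records with the `LE` and buffering
#'   columns present.
#' @param be_col Name of the buffering column (default `"BE"`; use
#'   `"EBE"` for experimental records).
#' @param tol Width of the boundary band around 1.
#' @return `records` with a `quadrant` column; attribute
#'   `"quadrant_counts"` holds the per-quadrant tally (also via
#'   [cartography_counts()]).
#' @export
classify_cartography <- function(records, be_col = "BE", tol = 1e-9) {
  if (!"LE" %in% names(records) || !be_col %in% names(records)) {
    stop("records must carry LE and ", be_col, " columns; missing for: ",
         paste(records$pair[!stats::complete.cases(records)],
               collapse = ", "), call. = FALSE)
  }
  le <- records$LE
  be <- records[[be_col]]
  if (anyNA(le) || anyNA(be)) {
    stop("missing LE/", be_col, " for pairs: ",
         paste(records$pair[is.na(le) | is.na(be)], collapse = ", "),
         call. = FALSE)
  }
  lab_le <- ifelse(le > 1, "long-term beneficial", "long-term detrimental")
  lab_be <- ifelse(be > 1, "short-term buffered", "short-term unbuffered")
  quadrant <- paste(lab_le, lab_be, sep = " / ")
  quadrant[abs(le - 1) <= tol | abs(be - 1) <= tol] <- "boundary"
  out <- dplyr::mutate(records, quadrant = quadrant)
  counts <- dplyr::count(out, .data$quadrant, name = "n")
  attr(out, "quadrant_counts") <- counts
  out
}

#' @rdname classify_cartography
#' @export
cartography_counts <- function(records) {
  cc <- attr(records, "quadrant_counts")
  if (is.null(cc)) cc <- dplyr::count(records, .data$quadrant, name = "n")
  cc
}

#' Plot the cartographic map of long-term vs buffering effects
#'
#' @param records Output of [classify_cartography()] (or any tibble with
#'   `LE`, the buffering column, and optionally `F_iso` for point size).
#' @inheritParams classify_cartography
#' @return A ggplot object: one point per pair on log-log axes with the
#'   `LE = 1` and `BE = 1` reference lines.
#' @export
plot_cartography <- function(records, be_col = "BE") {
  p <- ggplot2::ggplot(records,
                       ggplot2::aes(x = .data$LE, y = .data[[be_col]]))
  if ("F_iso" %in% names(records)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(size = .data$F_iso),
                                 alpha = 0.7)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7)
  }
  p +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "long-term effect LE(Z,S)",
                  y = paste0("buffering effect ", be_col, "(Z,S)"),
                  size = "F(Z) in isolation")
}

#' Plot the distributions of system-level effects
#'
#' @param records Effect tibble from [system_effects()].
#' @param indicators Which columns to show.
#' @return A ggplot object: one jittered strip per indicator with the
#'   reference line at 1.
#' @export
plot_effect_distributions <- function(records,
                                      indicators = c("PC", "LE", "SE", "BE")) {
  indicators <- intersect(indicators, names(records))
  long <- tidyr::pivot_longer(records, cols = dplyr::all_of(indicators),
                              names_to = "indicator", values_to = "value")
  long$indicator <- factor(long$indicator, levels = indicators)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$indicator, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "effect (ratio to isolation)")
}

#' @export
autoplot.composition_partition <- function(object, ...) {
  tab <- tidy(object)
  tab <- tab[order(-tab$value), ]
  tab$composition <- factor(tab$composition, levels = tab$composition)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$composition,
                                    y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$std_error,
                                        ymax = .data$value + .data$std_error),
                           width = 0.2) +
    ggplot2::labs(x = "composition", y = "F(C, S)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Serialize a composition partition to JSON
#'
#' @param partition A `composition_partition`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_partition_json <- function(partition, path) {
  masses <- stats::setNames(
    lapply(seq_len(nrow(partition$masses)), function(r) {
      list(value = partition$masses$value[r],
           std_error = partition$masses$std_error[r])
    }),
    partition$masses$composition
  )
  obj <- list(pool = partition$pool, method = partition$method,
              n_samples = partition$n_samples, seed = partition$seed,
              unresolved = partition$unresolved, masses = masses)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the end-to-end effects pipeline from a configuration file
#'
#' Reproducible driver over the package's functions: reads a YAML or JSON
#' configuration describing the interaction matrix (a CSV file, or a seeded
#' random recipe), optional experiment table, and the analysis settings;
#' computes the per-pair effect records, the composition partition, and the
#' cartographic classification; optionally writes `effects.csv`,
#' `partition.json`, and `report.json` to an output directory.
#'
#' Configuration fields: `seed`; `matrix` (path) or `recipe` (list with
#' `type` `"third_party"`/`"full"`/`"canonical"` and its parameters);
#' `n_draws`; `n_partition`; `simulate`; `constraint`; `total_time`,
#' `step`, `extinction_threshold`; `experiment` (path to an experiment CSV)
#' with `rel_threshold`.
#'
#' @param config Path to a YAML/JSON file, or an equivalent named list.
#' @param out_dir Optional output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return A list with `effects` (classified tibble), `partition`, `config`,
#'   and when experimental data were supplied, `experimental` effects.
#' @export
run_effects_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  seed <- as.integer(config$seed %||% 1L)
  say <- function(...) if (!quiet) message(...)

  A <- if (!is.null(config$matrix)) {
    read_interaction_matrix(config$matrix)
  } else if (!is.null(config$recipe)) {
    r <- config$recipe
    switch(r$type %||% "third_party",
      third_party = random_third_party_system(
        dim = r$dim %||% 3, sigma = r$sigma %||% 1,
        seed = r$seed %||% seed,
        enforce = r$enforce %||% "none"),
      full = random_full_system(
        dim = r$dim %||% 5, sigma = r$sigma %||% 0.25,
        seed = r$seed %||% seed,
        enforce = r$enforce %||% "dominance")[[
          if (isTRUE(r$flipped)) "flipped" else "matrix"]],
      canonical = canonical_fixtures()[[r$name]],
      stop("unknown recipe type: ", r$type, call. = FALSE)
    )
  } else {
    stop("config must name a 'matrix' file or a 'recipe'", call. = FALSE)
  }
  say("pool of ", nrow(A), " species: ",
      paste(species_labels(A), collapse = ", "))

  cfg <- sim_config(
    total_time = config$total_time %||% 200,
    step = config$step %||% 0.01,
    extinction_threshold = config$extinction_threshold %||% 1e-6,
    n_reps = config$n_draws %||% 1000,
    seed = seed
  )
  method <- if (nrow(A) <= 3 && is.null(config$constraint)) "exact"
            else "montecarlo"
  partition <- partition_mc(A, n = as.integer(config$n_partition %||% 1e5),
                            seed = seed, constraint = config$constraint,
                            method = method)
  if (!is.null(partition$warning)) say("partition: ", partition$warning)
  effects <- system_effects(
    A, partition = partition,
    simulate = !isFALSE(config$simulate),
    n_draws = as.integer(config$n_draws %||% 1000),
    seed = seed, config = cfg, constraint = config$constraint
  )

  experimental <- NULL
  if (!is.null(config$experiment)) {
    tab <- read_experiment_table(config$experiment)
    thr <- config$rel_threshold %||% 0.01
    experimental <- dplyr::bind_rows(lapply(seq_len(nrow(effects)),
      function(r) {
        experimental_effect(tab, c(effects$i[r], effects$j[r]), thr)
      }))
    effects <- dplyr::left_join(effects,
                                dplyr::select(experimental, "pair", "EE"),
                                by = "pair")
    effects$EBE <- experimental_buffering(effects$EE, effects$LE)
  }
  be_col <- if (!is.null(experimental)) "EBE" else if ("BE" %in% names(effects)) "BE" else NULL
  if (!is.null(be_col)) effects <- classify_cartography(effects, be_col)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    csv <- dplyr::mutate(effects, dplyr::across(dplyr::where(is.numeric),
                                                ~ signif(.x, 6)))
    readr::write_csv(csv, file.path(out_dir, "effects.csv"))
    write_partition_json(partition, file.path(out_dir, "partition.json"))
    jsonlite::write_json(
      list(seed = seed, pool = species_labels(A),
           n_draws = cfg$n_reps,
           unresolved = partition$unresolved,
           quadrant_counts = cartography_counts(effects),
           effects = effects),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("wrote effects.csv, partition.json, report.json to ", out_dir)
  }
  list(effects = effects, partition = partition, config = config,
       experimental = experimental)
}
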