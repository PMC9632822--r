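# tiny hand-built table: 4 replicates, two species
toy_table <- function() {
  tibble::tibble(
    replicate = rep(1:4, each = 2),
    treatment = "pair:a+b",
    species = rep(c("a", "b"), 4),
    density = c(1, 1,   1, 0.005,   0, 0,   0.5, 0.2)
  )
}

test_that("coexistence frequency counts replicates above the threshold", {
  tab <- toy_table()
  # rep1: both at 0.5 rel; rep2: b at 0.5% rel -> extinct; rep3: zero total
  # counts as all-extinct; rep4: both well above 1%
  f <- coexistence_frequency(tab, c("a", "b"), "pair:a+b", 0.01)
  expect_equal(f$numerator, 2)
  expect_equal(f$denominator, 4)
  expect_equal(f$frequency, 0.5)
  expect_equal(f$n_zero_total, 1)
  # a lone surviving species always has relative abundance 1
  solo <- tibble::tibble(replicate = 1, treatment = "mono:a",
                         species = "a", density = 1e-9)
  expect_equal(coexistence_frequency(solo, "a", "mono:a", 0.1)$frequency, 1)
  expect_error(coexistence_frequency(tab, c("a", "b"), "pair:x+y", 0.01),
               "no replicates")
})

test_that("raising the extinction threshold never raises the frequency", {
  A <- canonical_fixtures()$identity_5
  labs <- species_labels(A)
  tab <- synthetic_experiment(A, reps = 24, noise_sd = 0.3, seed = 5)
  thresholds <- c(0.01, 0.02, 0.05, 0.1, 0.2)
  for (Z in list(labs[1:2], labs[c(2, 5)])) {
    freqs <- vapply(thresholds, function(tr) {
      coexistence_frequency(tab, Z, "poly:all", tr)$frequency
    }, 0)
    expect_true(all(diff(freqs) <= 0))
  }
})

test_that("experimental effect is the poly/pair frequency ratio", {
  tab <- dplyr::bind_rows(
    tibble::tibble(replicate = rep(1:48, each = 2), treatment = "pair:a+b",
                   species = rep(c("a", "b"), 48),
                   density = rep(c(1, 1), 48) *
                     rep(c(rep(1, 12), rep(0, 36)), each = 2)),
    tibble::tibble(replicate = rep(1:48, each = 2), treatment = "poly:all",
                   species = rep(c("a", "b"), 48),
                   density = rep(c(1, 1), 48) *
                     rep(c(rep(1, 24), rep(0, 24)), each = 2))
  )
  ee <- experimental_effect(tab, c("a", "b"))
  expect_equal(ee$freq_iso, 0.25)
  expect_equal(ee$freq_pool, 0.5)
  expect_equal(ee$EE, 2)
  expect_error(experimental_effect(toy_table(), c("a", "b")), "poly")
  expect_equal(experimental_buffering(1.2, 0.8), 1.5)
  expect_equal(experimental_buffering(0.7, 0.7), 1)
})

test_that("interaction inference reproduces the worked arithmetic", {
  mk <- function(sp, tr, dens) {
    tibble::tibble(replicate = seq_along(dens), treatment = tr,
                   species = sp, density = dens)
  }
  tab <- dplyr::bind_rows(
    mk("a", "mono:a", rep(1, 4)), mk("b", "mono:b", rep(1, 4)),
    tibble::tibble(replicate = rep(1:4, each = 2), treatment = "pair:a+b",
                   species = rep(c("a", "b"), 4),
                   density = rep(c(0.5, 0.5), 4))
  )
  A <- infer_interactions(tab)
  expect_equal(unclass(A)["a", "b"], 1)   # (1 - 0.5) / 0.5
  expect_equal(unclass(A)["b", "a"], 1)
  expect_equal(attr(A, "theta_hat"), c(a = 1, b = 1))
  # no effect: co-culture density equals monoculture
  tab2 <- dplyr::bind_rows(
    mk("a", "mono:a", rep(2, 4)), mk("b", "mono:b", rep(3, 4)),
    tibble::tibble(replicate = rep(1:4, each = 2), treatment = "pair:a+b",
                   species = rep(c("a", "b"), 4),
                   density = rep(c(2, 3), 4))
  )
  A2 <- infer_interactions(tab2)
  expect_equal(unclass(A2)["a", "b"], 0)
  expect_equal(unclass(A2)["b", "a"], 0)
  expect_error(infer_interactions(dplyr::filter(tab, treatment != "mono:b")),
               "monoculture")
})

test_that("inference recovers the generating matrix from noiseless
           equilibria and improves with replication", {
  A <- random_full_system(5, sigma = 0.25, seed = 3)$matrix
  tab0 <- synthetic_experiment(A, reps = 4, noise_sd = 0, seed = 1,
                               mode = "equilibrium")
  Ahat <- infer_interactions(tab0)
  expect_lt(max(abs(unclass(Ahat) - unclass(A))), 1e-9)
  # with 10% log-normal noise the error shrinks as replicates grow 12 -> 48
  err <- function(reps, s) {
    tab <- synthetic_experiment(A, reps = reps, noise_sd = 0.1, seed = s,
                                mode = "equilibrium")
    Ah <- unclass(infer_interactions(tab))
    stats::median(abs(Ah - unclass(A))[row(Ah) != col(Ah)])
  }
  e12 <- mean(vapply(1:5, function(s) err(12, s), 0))
  e48 <- mean(vapply(1:5, function(s) err(48, s), 0))
  expect_lt(e48, e12)
})

test_that("experiment tables round-trip through CSV", {
  tab <- synthetic_experiment(canonical_fixtures()$identity_3, reps = 3,
                              seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_experiment_table(tab, path)
  back <- read_experiment_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12, ignore_attr = TRUE)
  bad <- dplyr::mutate(tab, density = -density - 1)
  expect_error(write_experiment_table(bad, path), "nonnegative")
})

test_that("replicate experiments and direct simulation estimate the same
           effect", {
  # same matrix, same number of trials: EE from the synthetic experiment
  # should agree with SE from simulate_frequencies within binomial error
  A <- canonical_fixtures()$three_species
  labs <- species_labels(A)
  tab <- synthetic_experiment(A, reps = 400, noise_sd = 0, seed = 11)
  # matched extinction rules so both estimators target the same quantity:
  # totals are O(1), so a tiny relative threshold matches the absolute one
  ee <- experimental_effect(tab, labs[1:2], rel_threshold = 1e-5)
  f <- simulate_frequencies(A, list(c(1, 2)), thetas = 1000,
                            config = sim_config(seed = 12))
  tol <- 4 * sqrt(ee$freq_pool * (1 - ee$freq_pool) / 400 +
                    f$Sim_pool * (1 - f$Sim_pool) / 1000)
  expect_within(ee$freq_pool, f$Sim_pool, tol)
  expect_within(ee$EE, f$SE, 4 * f$SE_std_error + 0.1)
})
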