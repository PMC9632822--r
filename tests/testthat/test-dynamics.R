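fx <- canonical_fixtures()

test_that("single-species runs match the logistic closed form", {
  A1 <- interaction_matrix(matrix(1))
  r <- rk4_integrate(A1, theta = 1, N0 = 0.5)
  expect_equal(unname(r$final_state), 1, tolerance = 1e-9)
  expect_equal(unname(r$survivors), 1L)
  # negative growth: decays below the extinction threshold over T = 200
  r2 <- rk4_integrate(A1, theta = -0.5, N0 = 0.5)
  expect_lt(unname(r2$final_state), 1e-6)
  expect_length(r2$survivors, 0)
  # closed-form transient across random positive (theta, a) pairs
  cases <- withr::with_seed(5, cbind(runif(100, 0.2, 2), runif(100, 0.2, 2)))
  cfg <- sim_config(total_time = 5, step = 0.01)
  for (k in seq_len(nrow(cases))) {
    th <- cases[k, 1]
    a <- cases[k, 2]
    got <- rk4_integrate(interaction_matrix(matrix(a)), th, 0.5, cfg)
    want <- logistic_closed_form(th, a, 0.5, 5)
    expect_equal(unname(got$final_state), want, tolerance = 1e-6)
  }
})

test_that("two-species runs settle on the interior equilibrium", {
  # globally stable symmetric competition: N* = A^-1 theta
  r <- rk4_integrate(fx$pair22, c(1, 1), c(0.5, 0.3))
  expect_equal(unname(r$final_state), rep(1 / 1.22, 2), tolerance = 1e-6)
  expect_equal(unname(r$survivors), 1:2)
})

test_that("the batch integrator matches an independent R implementation", {
  A <- fx$three_species
  th <- sample_theta(3, 10, seed = 31)
  n0 <- withr::with_seed(32, matrix(runif(30), 10, 3))
  cfg <- sim_config(total_time = 2, step = 0.01)
  batch <- paircoex:::glv_batch(A, th, n0, cfg)
  for (r in 1:10) {
    ref <- rk4_reference(A, th[r, ], n0[r, ], 2, 0.01)
    expect_equal(unname(batch$final[r, ]), unname(ref), tolerance = 1e-12)
  }
})

test_that("abundances stay nonnegative and step-halving is converged", {
  A <- fx$three_species
  th <- sample_theta(3, 5, seed = 41)
  n0 <- withr::with_seed(42, matrix(runif(15), 5, 3))
  full <- paircoex:::glv_batch(A, th, n0, sim_config())
  expect_true(all(full$final >= 0))
  halved <- paircoex:::glv_batch(A, th, n0, sim_config(step = 0.005))
  expect_lt(max(abs(full$final - halved$final)), 1e-6)
})

test_that("trajectories hitting the cap are flagged diverged", {
  # strong mutualism: finite-time blow-up
  A <- interaction_matrix(rbind(c(1, -2), c(-2, 1)))
  r <- rk4_integrate(A, c(1, 1), c(0.5, 0.5))
  expect_true(r$diverged)
  expect_equal(unname(r$survivors), 1:2)  # blown-up species are present
})

test_that("decoupled pools give equal in-pool and isolation frequencies", {
  f <- simulate_frequencies(fx$identity_3, list(c(1, 2)),
                            thetas = 1000, config = sim_config(seed = 3))
  expect_within(f$Sim_pool, f$Sim_iso, binom4se(f$Sim_iso, 1000))
  expect_equal(f$n_diverged, 0L)
  expect_error(simulate_frequencies(fx$identity_3, list()), "empty")
})

test_that("short-term effect is the frequency ratio with diagnostics", {
  tab <- tibble::tibble(pair = c("a+b", "a+c"), i = c("a", "a"),
                        j = c("b", "c"), Sim_pool = c(0.3, 0.2),
                        Sim_iso = c(0.6, 0), SE = c(0.5, NA),
                        SE_std_error = c(0.05, NA),
                        n_pool = 100L, n_iso = 100L, n_diverged = 0L)
  se <- short_term_effect(tab, c("a", "b"))
  expect_equal(se$SE, 0.5)
  expect_false(se$undefined)
  expect_true(short_term_effect(tab, c("a", "c"))$undefined)
  expect_error(short_term_effect(tab, c("b", "c")), "not found")
})

test_that("buffering effect is SE / LE with a positivity guard", {
  expect_equal(buffering_effect(1.3, 1.3), 1)
  expect_equal(buffering_effect(0.3, 0.6), 0.5)
  expect_error(buffering_effect(1, 0), "positive")
})

test_that("finite-time coexistence dominates the analytic probabilities", {
  # Sim(Z,S) >= P(Z,S) and Sim(Z) >= F(Z): transient buffering
  A <- fx$three_species
  part <- partition_mc(A, method = "exact")
  f <- simulate_frequencies(A, list(c(1, 2)), thetas = 1000,
                            config = sim_config(seed = 6))
  P <- pair_probability(part, c(1, 2))$value
  Fz <- pair_feasibility_analytic(subsystem(A, c(1, 2)))$value
  expect_gte(f$Sim_pool, P - binom4se(P, 1000))
  expect_gte(f$Sim_iso, Fz - binom4se(Fz, 1000))
})

test_that("simulated compositions converge to the analytic partition", {
  A <- fx$three_species
  exact <- tidy(partition_mc(A, method = "exact"))
  th <- sample_theta(3, 2000, seed = 8)
  tv <- vapply(c(100, 200, 400, 800), function(tt) {
    sim <- simulate_composition_frequencies(A, th,
                                            sim_config(total_time = tt,
                                                       seed = 9))
    m <- merge(exact, sim, by = "composition", all.x = TRUE)
    m$freq[is.na(m$freq)] <- 0
    sum(abs(m$value - m$freq)) / 2
  }, 0)
  expect_true(all(diff(tv) < 0))
  # and the transient buffering gaps Sim - P and Sim_iso - F close with the
  # horizon, so short-term and long-term effects meet in the long run
  part <- partition_mc(A, method = "exact")
  P <- pair_probability(part, c(1, 2))$value
  Fz <- pair_feasibility_analytic(subsystem(A, c(1, 2)))$value
  f_at <- function(tt) {
    simulate_frequencies(A, list(c(1, 2)), th,
                         sim_config(total_time = tt, seed = 10))
  }
  f100 <- f_at(100)
  f800 <- f_at(800)
  expect_lt(f800$Sim_pool - P, f100$Sim_pool - P)
  expect_lt(f800$Sim_iso - Fz, f100$Sim_iso - Fz)
  expect_gte(f800$Sim_pool, P - binom4se(P, 2000))
  expect_gte(f800$Sim_iso, Fz - binom4se(Fz, 2000))
})
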