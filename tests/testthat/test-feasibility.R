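fx <- canonical_fixtures()

test_that("pair feasibility matches the planar angle and a Monte-Carlo check", {
  expect_equal(pair_feasibility_analytic(fx$identity_2)$value, 0.25)
  # symmetric 0.22 competition pair: acos(0.44/1.0484)/(2 pi)
  f22 <- pair_feasibility_analytic(fx$pair22)$value
  expect_equal(f22, acos(0.44 / 1.0484) / (2 * pi), tolerance = 1e-12)
  expect_equal(f22, 0.1810699, tolerance = 1e-6)
  mc <- cone_feasibility(unclass(fx$pair22), n = 2e5, seed = 5,
                         method = "montecarlo")
  expect_within(mc$value, f22, 4 * mc$std_error)
  # collapsing cone: overlap -> 1 drives feasibility to 0
  eps <- 1e-4
  near <- interaction_matrix(rbind(c(1, 1 - eps), c(1 - eps, 1)))
  expect_lt(pair_feasibility_analytic(near)$value, 0.003)
  expect_error(pair_feasibility_analytic(
    interaction_matrix(rbind(c(1, 1), c(1, 1)))), "degenerate")
})

test_that("cone measures agree between closed forms and the orthant MC", {
  expect_equal(cone_feasibility(diag(3))$value, 0.125)
  # 3-species diagonally dominant system: solid angle vs Monte Carlo
  cf <- cone_feasibility(unclass(fx$three_species))
  expect_equal(cf$method, "solid_angle3d")
  mc <- cone_feasibility(unclass(fx$three_species), n = 1e5, seed = 2,
                         method = "montecarlo")
  expect_within(mc$value, cf$value, 4 * mc$std_error + 1e-4)
  # rotated orthant in d = 5 keeps measure 2^-5
  Q <- qr.Q(qr(withr::with_seed(3, matrix(rnorm(25), 5, 5))))
  mc5 <- cone_feasibility(Q, n = 4e4, seed = 4)
  expect_within(mc5$value, 2^-5, binom4se(2^-5, 4e4))
  expect_error(cone_feasibility(matrix(0, 3, 3)), "singular")
})

test_that("closed-form and MC cone measures agree on random matrices", {
  for (s in 1:30) {
    d <- 2 + s %% 2
    G <- withr::with_seed(s, matrix(rnorm(d * d), d, d))
    if (abs(det(G)) < 1e-3) next
    cl <- cone_feasibility(G, method = "closed")$value
    mc <- cone_feasibility(G, n = 2e4, seed = s + 100,
                           method = "montecarlo")
    expect_within(mc$value, cl, binom4se(max(cl, 0.01), 2e4) + 1e-4)
  }
})

test_that("composition assignment reproduces hand-worked cases", {
  id2 <- fx$identity_2
  a <- assign_composition(id2, c(0.6, -0.8))
  expect_equal(a$status, "unique")
  expect_equal(a$members, 1L)
  expect_equal(assign_composition(id2, c(-0.6, -0.8))$members, integer(0))
  expect_equal(assign_composition(id2, c(0.6, 0.8))$members, 1:2)
  # strong symmetric competition: interior and both boundary equilibria are
  # simultaneously non-invadable -> bistability diagnostic
  bist <- interaction_matrix(rbind(c(1, 2), c(2, 1)))
  a2 <- assign_composition(bist, c(1, 1))
  expect_equal(a2$status, "multiple")
  expect_setequal(vapply(a2$candidates, paste, "", collapse = ","),
                  c("1", "2", "1,2"))
})

test_that("partition masses are orthants for non-interacting pools", {
  p <- partition_mc(fx$identity_3, method = "exact")
  expect_equal(tidy(p)$value, rep(0.125, 8))
  pm <- partition_mc(fx$identity_3, n = 8000, seed = 1,
                     method = "montecarlo")
  expect_equal(sum(tidy(pm)$value), 1)  # count identity
  expect_equal(pm$unresolved, 0L)
  expect_true(all(abs(tidy(pm)$value - 0.125) <= binom4se(0.125, 8000)))
})

test_that("exact and Monte-Carlo partitions agree on a 3-species system", {
  pe <- partition_mc(fx$three_species, method = "exact")
  expect_equal(sum(tidy(pe)$value), 1, tolerance = 1e-12)
  pm <- partition_mc(fx$three_species, n = 2e4, seed = 9,
                     method = "montecarlo")
  te <- tidy(pe)
  tm <- tidy(pm)
  expect_equal(te$composition, tm$composition)
  for (r in seq_len(nrow(te))) {
    expect_within(tm$value[r], te$value[r],
                  binom4se(max(te$value[r], 0.01), 2e4))
  }
  # the full-pool mass is the feasibility cone of A itself
  expect_equal(composition_mass(pe, 1:3)$value,
               cone_feasibility(unclass(fx$three_species))$value,
               tolerance = 1e-12)
})

test_that("partition conserves mass and flags bistable systems", {
  # diagonally dominant 5-species pools: unresolved-free count partition
  for (s in 1:6) {
    A <- random_full_system(5, sigma = 0.25, seed = s)$matrix
    p <- partition_mc(A, n = 3000, seed = s + 50, method = "montecarlo")
    expect_equal(sum(tidy(p)$value), 1)
    expect_equal(p$unresolved, 0L)
    expect_within(glance(p)$empty_mass, 2^-5, binom4se(2^-5, 3000))
  }
  # a system with multiple attractors accumulates unresolved draws
  bist <- interaction_matrix(rbind(c(1, 2), c(2, 1)))
  pb <- partition_mc(bist, n = 2000, seed = 1, method = "montecarlo")
  expect_gt(pb$unresolved, 0)
  expect_match(pb$warning, "not be globally stable")
})

test_that("composition masses never exceed isolated feasibility", {
  # F(C, S) <= F(C), equality only at C = S (exact 3-species check)
  A <- fx$three_species
  pe <- partition_mc(A, method = "exact")
  for (pair in list(1:2, c(1L, 3L), 2:3)) {
    fc <- pair_feasibility_analytic(subsystem(A, pair))$value
    expect_lt(composition_mass(pe, pair)$value, fc)
  }
  expect_equal(composition_mass(pe, 1:3)$value,
               cone_feasibility(unclass(A))$value, tolerance = 1e-12)
  # and the full-system feasibility shrinks with pool size (nested pools)
  for (s in 1:5) {
    A5 <- random_full_system(5, sigma = 0.25, seed = s + 10)$matrix
    f2 <- pair_feasibility_analytic(subsystem(A5, 1:2))$value
    f3 <- cone_feasibility(unclass(A5)[1:3, 1:3])$value
    f5 <- cone_feasibility(unclass(A5), n = 2e4, seed = s)
    expect_gt(f2, f3)
    expect_gt(f3, f5$value - 4 * f5$std_error)
  }
})

test_that("pair probability sums the right composition masses", {
  p3 <- partition_mc(fx$identity_3, method = "exact")
  expect_equal(pair_probability(p3, c(1, 2))$value, 0.25)
  # Z = full pool reduces to the single full-composition mass
  expect_equal(pair_probability(p3, 1:3)$value,
               composition_mass(p3, 1:3)$value)
  expect_error(pair_probability(p3, integer(0)), "nonempty")
  expect_error(pair_probability(p3, c(1, 7)), "subset")
  # P(Z, S) >= F(S) for every pair (summands include the full pool)
  A <- random_full_system(5, sigma = 0.25, seed = 2)$matrix
  p5 <- partition_mc(A, n = 3000, seed = 4, method = "montecarlo")
  full_mass <- composition_mass(p5, 1:5)$value
  for (pr in utils::combn(5, 2, simplify = FALSE)) {
    expect_gte(pair_probability(p5, pr)$value, full_mass)
  }
})

test_that("long-term effect is exactly 1 without interactions and tends to 1
           for weak ones", {
  expect_equal(long_term_effect(fx$identity_5, c(2, 4),
                                partition = partition_mc(
                                  fx$identity_5, n = 4000, seed = 1,
                                  method = "montecarlo"))$F_iso, 0.25)
  expect_equal(long_term_effect(fx$identity_3, c(1, 2))$LE, 1)
  # scaling all off-diagonal interactions toward zero pulls LE to 1
  # monotonically (exact three-species partition)
  base <- random_third_party_system(3, sigma = 1, seed = 21,
                                    enforce = "lyapunov")
  devs <- vapply(c(0.4, 0.2, 0.1), function(eps) {
    M <- unclass(base)
    Aeps <- M * eps
    diag(Aeps) <- 1
    abs(long_term_effect(interaction_matrix(Aeps), c(1, 2),
                         partition = partition_mc(interaction_matrix(Aeps),
                                                  method = "exact"))$LE - 1)
  }, 0)
  expect_true(all(diff(devs) < 0))
})
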