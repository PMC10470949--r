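test_that("reaction weights follow the GPR max/min rules", {
  m <- metabolic_model(
    id = "t",
    metabolites = data.frame(id = "A", name = "A", compartment = "c"),
    reactions = list(
      reaction("r_or", stoichiometry = c(A = 1), gpr = "G1 or G2"),
      reaction("r_and", stoichiometry = c(A = -1), gpr = "G1 and G2"),
      reaction("r_none", stoichiometry = c(A = -1)),
      reaction("r_unmatched", stoichiometry = c(A = -1), gpr = "G9")
    ),
    genes = c("G1", "G2", "G9"),
    objective = "r_or"
  )
  w <- reaction_weights(m, c(G1 = -0.5, G2 = 1.2))
  expect_equal(unname(w["r_or"]), 1.2)    # isozymes: highest fold difference
  expect_equal(unname(w["r_and"]), -0.5)  # complex: lowest fold difference
  expect_false("r_none" %in% names(w))
  expect_false("r_unmatched" %in% names(w))
})

test_that("subsystem scores are plain means with a minimum-size guard", {
  rw <- c(r1 = 1, r2 = 3, r3 = 0)
  expect_equal(subsystem_score(rw, c("r1", "r2"), min_reactions = 2), 2)
  expect_equal(subsystem_score(rw, names(rw), min_reactions = 3), 4 / 3)
  expect_error(subsystem_score(rw, c("r1", "r2"), min_reactions = 3),
               class = "hepaflux_skip_subsystem")
  # brute-force mean oracle on random memberships
  set.seed(9)
  rw2 <- stats::setNames(stats::rnorm(30), paste0("x", 1:30))
  for (i in 1:20) {
    mem <- sample(names(rw2), 10)
    expect_equal(subsystem_score(rw2, mem), sum(rw2[mem]) / 10)
  }
})

test_that("permutation null draws from the out-of-subsystem pool", {
  rw <- c(a = 0, b = 0, c = 0, d = 0, e = 0, m1 = 5, m2 = 5, m3 = 5)
  ns <- permutation_null(rw, c("m1", "m2", "m3"), n_permutations = 200, seed = 1)
  expect_length(ns, 200)
  expect_true(all(ns == 0))   # all-zero pool -> all-zero null
  # two-point pool with k = 1: null values live on the pool support
  rw2 <- c(p1 = -1, p2 = 1, m1 = 0.5)
  ns2 <- permutation_null(rw2, "m1", n_permutations = 500, seed = 2)
  expect_true(all(ns2 %in% c(-1, 1)))
  expect_lt(abs(mean(ns2)), 0.15)
  # reproducibility under the seed
  expect_identical(permutation_null(rw2, "m1", 100, seed = 7),
                   permutation_null(rw2, "m1", 100, seed = 7))
  # an empty pool is refused
  expect_error(permutation_null(rw2, names(rw2), 10, seed = 1),
               class = "hepaflux_degenerate_null_error")
})

test_that("null moments match the closed form for with-replacement means", {
  pool <- c(p1 = -2, p2 = -1, p3 = 0, p4 = 1.5, p5 = 3)
  k <- 2
  rw <- c(pool, m1 = 0, m2 = 0)
  ns <- permutation_null(rw, c("m1", "m2"), n_permutations = 1e5, seed = 31)
  mu <- mean(pool)
  sigma2 <- mean((pool - mu)^2) / k   # population variance of the mean
  expect_lt(abs(mean(ns) - mu), 0.02 * stats::sd(pool))
  expect_lt(abs(stats::var(ns) - sigma2) / sigma2, 0.02)
})

test_that("empirical test applies the add-one correction and calls direction", {
  nulls <- stats::rnorm(1000)
  hi <- max(nulls) + 1
  tt <- tides_test(hi, nulls)
  expect_equal(tt$p_pos, 1 / 1001)
  expect_equal(tt$p_two_sided, 2 / 1001)
  expect_identical(tt$direction, "positive")

  lo <- min(nulls) - 1
  tt2 <- tides_test(lo, nulls)
  expect_equal(tt2$p_neg, 1 / 1001)
  expect_identical(tt2$direction, "negative")

  mid <- stats::median(nulls)
  tt3 <- tides_test(mid, nulls)
  expect_gt(tt3$p_two_sided, 0.9)
  expect_identical(tt3$direction, "none")

  # ties count toward the extreme tail
  tt4 <- tides_test(1, rep(1, 100))
  expect_equal(tt4$p_pos, 1)
  expect_equal(tt4$p_neg, 1)
  expect_identical(tt4$direction, "none")
})

test_that("run_tides under a global null calls nothing significant", {
  m <- make_toy_model(1)
  gw <- stats::setNames(rep(0, length(m$genes)), m$genes)
  res <- run_tides(m, gw, n_permutations = 300, seed = 4)
  scored <- res[!res$skipped, ]
  expect_gt(nrow(scored), 0)
  expect_true(all(scored$score == 0))
  expect_true(all(scored$direction == "none"))
  expect_true(all(scored$p_two_sided > 0.99))
  # skipped subsystems are reported, not dropped
  expect_true(any(res$skipped))
  expect_true("Exchange/demand reactions" %in% res$subsystem[res$skipped])
})

test_that("contrast orientation flips scores and keeps p-values", {
  # Exact antisymmetry holds for single-gene GPRs; multi-gene rules
  # break it by construction, since the isozyme rule takes the highest
  # fold difference in either orientation (max(-x) = -min(x)).
  rxns <- lapply(1:12, function(i) {
    reaction(sprintf("r%02d", i), stoichiometry = c(A = (-1)^i),
             gpr = sprintf("G%02d", i),
             subsystem = c("S1", "S2", "S3")[(i - 1) %/% 4 + 1])
  })
  m <- metabolic_model(
    id = "flip",
    metabolites = data.frame(id = "A", name = "A", compartment = "c"),
    reactions = rxns, objective = "r01"
  )
  set.seed(77)
  gw <- stats::setNames(stats::rnorm(12), sprintf("G%02d", 1:12))
  a <- run_tides(m, gw, n_permutations = 500, seed = 9)
  b <- run_tides(m, -gw, n_permutations = 500, seed = 9)
  expect_equal(a$score, -b$score)
  # same seed draws the same pool positions, so the nulls negate too
  # and the two-sided p-values agree exactly
  expect_equal(a$p_two_sided, b$p_two_sided)
  dir_map <- c(positive = "negative", negative = "positive", none = "none")
  expect_identical(unname(dir_map[a$direction]), b$direction)
})

test_that("a planted subsystem is detected with the right direction", {
  m <- make_toy_model(1)
  subs <- subsystems(m)
  target <- "Glycolysis / Gluconeogenesis"
  target_genes <- unique(unlist(lapply(
    m$reactions[names(subs)[!is.na(subs) & subs == target]],
    function(r) gpr_genes(r$gpr)
  )))
  gw <- stats::setNames(rep(0, length(m$genes)), m$genes)
  gw[target_genes] <- 2
  res <- run_tides(m, gw, n_permutations = 1000, seed = 21)
  row <- res[res$subsystem == target, ]
  expect_false(row$skipped)
  expect_equal(row$score, 2)
  expect_lt(row$p_two_sided, 0.05)
  expect_identical(row$direction, "positive")
  # p-values live in (0, 1]
  expect_true(all(res$p_two_sided[!res$skipped] > 0))
  expect_true(all(res$p_two_sided[!res$skipped] <= 1))
})

test_that("models without subsystem labels are a configuration error", {
  m <- chain_model()
  expect_error(run_tides(m, c(G1 = 1)), class = "hepaflux_config_error")
})
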