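test_that("presence fractions are per-group keep-set frequencies", {
  keeps_A <- c(replicate(3, c("r1", "r2"), simplify = FALSE),
               replicate(7, "r2", simplify = FALSE))
  keeps_B <- replicate(10, c("r2", "r3"), simplify = FALSE)
  pt <- presence_table(lapply(keeps_A, fake_context),
                       lapply(keeps_B, fake_context))
  expect_equal(pt$frac_A[pt$reaction_id == "r1"], 0.3)
  expect_equal(pt$frac_B[pt$reaction_id == "r1"], 0)
  expect_equal(pt$frac_A[pt$reaction_id == "r2"], 1)
  expect_equal(pt$frac_B[pt$reaction_id == "r2"], 1)   # core metabolism
  expect_equal(attr(pt, "n_A"), 10)
  expect_error(presence_table(list(), lapply(keeps_B, fake_context)),
               class = "hepaflux_config_error")
})

test_that("presence histogram bins (0,1] with the top bin closed", {
  pt <- data.frame(
    reaction_id = c("a", "b", "c", "d"),
    subsystem = NA_character_,
    frac_A = c(0.05, 0.55, 1.0, 0),
    frac_B = c(0, 0, 0, 0.5)
  )
  h <- presence_histogram(pt, "A")
  expect_equal(sum(h), 3)            # the frac-0 reaction is excluded
  expect_equal(unname(h[1]), 1)      # 0.05 -> bin 1
  expect_equal(unname(h[6]), 1)      # 0.55 -> bin 6
  expect_equal(unname(h[10]), 1)     # 1.00 -> top bin
  # all mass in the top bin when everything is core
  pt2 <- data.frame(reaction_id = "x", subsystem = NA, frac_A = 1, frac_B = 1)
  expect_equal(unname(presence_histogram(pt2, "A")[10]), 1)
})

test_that("uniqueness requires min_frac presence and strict absence", {
  pt <- data.frame(
    reaction_id = c("uA", "soft", "low", "uB", "core"),
    subsystem = c("S1", "S1", "S2", "S2", "S3"),
    frac_A = c(0.2, 0.2, 0.05, 0.0, 1),
    frac_B = c(0.0, 0.01, 0.0, 0.3, 1)
  )
  ur <- unique_reactions(pt, min_frac = 0.1)
  expect_identical(ur$unique_A, "uA")     # (0.2, 0) qualifies
  expect_identical(ur$unique_B, "uB")
  expect_false("soft" %in% c(ur$unique_A, ur$unique_B))  # 0.01 > 0 in B
  expect_false("low" %in% ur$unique_A)                   # below min_frac
  expect_length(intersect(ur$unique_A, ur$unique_B), 0)
  expect_identical(ur$subsystem_counts_A$subsystem, "S1")
  expect_equal(ur$subsystem_counts_A$count, 1L)
})

test_that("presence and uniqueness match brute-force counting on random cohorts", {
  set.seed(404)
  rxn_pool <- sprintf("rx%02d", 1:25)
  for (i in 1:40) {
    nA <- sample(3:12, 1); nB <- sample(3:12, 1)
    keeps_A <- replicate(nA, sample(rxn_pool, sample(5:20, 1)), simplify = FALSE)
    keeps_B <- replicate(nB, sample(rxn_pool, sample(5:20, 1)), simplify = FALSE)
    pt <- presence_table(lapply(keeps_A, fake_context),
                         lapply(keeps_B, fake_context))
    want <- oracle_presence(keeps_A, keeps_B, min_frac = 0.1)
    expect_identical(pt$reaction_id, want$reaction_id)
    expect_equal(pt$frac_A, want$frac_A)
    expect_equal(pt$frac_B, want$frac_B)
    ur <- unique_reactions(pt, 0.1)
    expect_setequal(ur$unique_A, want$unique_A)
    expect_setequal(ur$unique_B, want$unique_B)
    expect_equal(unname(presence_histogram(pt, "A")),
                 oracle_histogram(want$frac_A))
    # order invariance
    ur2 <- unique_reactions(pt[sample(nrow(pt)), ], 0.1)
    expect_setequal(ur2$unique_A, ur$unique_A)
  }
})

test_that("flux contrasts separate, equate and report structure", {
  mk_fs <- function(values, rids) {
    structure(list(samples = matrix(values, ncol = length(rids),
                                    dimnames = list(NULL, rids)),
                   reaction_ids = rids, seed = 1L,
                   constraints = list(), lb = NULL, ub = NULL),
              class = "flux_sample_set")
  }
  # identical columns: p ~ 1, equal medians
  a <- mk_fs(rep(1:10, 2), c("r1", "r2"))
  fc <- flux_contrast(a, a, "r1")
  expect_gt(fc$p_two_sided, 0.9)
  expect_equal(fc$median_A, fc$median_B)

  # complete separation at n = 110: p < .001
  b1 <- mk_fs(rep(5, 110), "r1")
  b2 <- mk_fs(rep(0, 110), "r1")
  fc2 <- flux_contrast(b1, b2, "r1")
  expect_lt(fc2$p_two_sided, 0.001)

  # the printed exact example: A = {1,2,3}, B = {4,5,6}
  c1 <- mk_fs(c(1, 2, 3), "r1"); c2 <- mk_fs(c(4, 5, 6), "r1")
  fc3 <- flux_contrast(c1, c2, "r1")
  expect_equal(unname(fc3$U), 0)
  expect_equal(fc3$p_two_sided, 0.1)

  # structural difference: reaction absent from one set
  d <- mk_fs(rep(1, 5), "r9")
  fc4 <- flux_contrast(b1, d, "r1")
  expect_true(fc4$structural)
  expect_true(is.na(fc4$p_two_sided))
  expect_error(flux_contrast(d, d, "zz"),
               class = "hepaflux_missing_reaction_error")

  # symmetry: swapping groups preserves p, negates the median difference
  set.seed(6)
  e1 <- mk_fs(stats::rnorm(30, 1), "r1"); e2 <- mk_fs(stats::rnorm(30), "r1")
  f12 <- flux_contrast(e1, e2, "r1"); f21 <- flux_contrast(e2, e1, "r1")
  expect_equal(f12$p_two_sided, f21$p_two_sided)
  expect_equal(f12$median_A - f12$median_B, -(f21$median_A - f21$median_B))
})
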