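# Three single-gene reactions whose abundances are set directly, for
# checking the linear abundance-to-weight map.
weight_probe_model <- function() {
  metabolic_model(
    id = "probe",
    metabolites = data.frame(id = "A", name = "A", compartment = "c"),
    reactions = list(
      reaction("r1", stoichiometry = c(A = 1), gpr = "Ga"),
      reaction("r2", stoichiometry = c(A = -1), gpr = "Gb"),
      reaction("r3", stoichiometry = c(A = -1), gpr = "Gc"),
      reaction("r4", stoichiometry = c(A = -1))
    ),
    objective = "r1"
  )
}

test_that("transcript weights are linear in abundance, 0 at the top", {
  m <- weight_probe_model()
  w <- transcript_weights(m, c(Ga = 100, Gb = 50, Gc = 0))
  expect_equal(unname(w[c("r1", "r2", "r3")]), c(0, 0.5, 1))
  expect_equal(unname(w["r4"]), 0.5)   # unresolvable -> neutral default
  expect_equal(unname(w["r4"]),
               unname(transcript_weights(m, c(Ga = 1, Gb = 2, Gc = 3),
                                         default_weight = 0.5)["r4"]))
  # highest-abundance reaction gets exactly 0
  expect_identical(unname(w[which.max(c(100, 50, 0))]), 0)
  # equal abundances degrade to 0.5 everywhere with a warning
  expect_warning(w2 <- transcript_weights(m, c(Ga = 7, Gb = 7, Gc = 7)))
  expect_true(all(w2[c("r1", "r2", "r3")] == 0.5))
  # no model gene present is an error
  expect_error(transcript_weights(m, c(Zz = 1)),
               class = "hepaflux_config_error")
})

test_that("pruning drops the expensive parallel path and keeps biomass", {
  m <- two_path_model()
  m$reactions[["R_out"]]$ub <- 10
  w <- c(R_in = 0.2, P1 = 0.1, P2 = 0.9, R_out = 0.2)
  ctx <- prune(m, w, biomass_fraction = 0.5)
  expect_true("P1" %in% ctx$kept_reactions)
  expect_true("P2" %in% ctx$pruned_reactions)
  expect_true(ctx$feasible_at_040)
  expect_gte(ctx$kept_max_biomass, 0.5 * ctx$base_max_biomass - 1e-6)
  # flipped weights flip the kept branch
  w2 <- c(R_in = 0.2, P1 = 0.9, P2 = 0.1, R_out = 0.2)
  ctx2 <- prune(m, w2, biomass_fraction = 0.5)
  expect_true("P2" %in% ctx2$kept_reactions)
  expect_true("P1" %in% ctx2$pruned_reactions)
})

test_that("uniform weights reproduce parsimonious zero-flux pruning", {
  m <- make_toy_model(1)
  rids <- reaction_ids(m)
  w <- stats::setNames(rep(0.5, length(rids)), rids)
  ctx <- prune(m, w, biomass_fraction = 0.4)
  v <- minimize_weighted_flux(m, NULL, biomass_fraction = 0.4,
                              default_weight = 1)
  expect_setequal(ctx$kept_reactions, names(v)[abs(v) > 1e-6])
})

test_that("raising a pathway's abundance never gets it pruned (monotonicity)", {
  m <- two_path_model()
  m$reactions[["R_out"]]$lb <- 5
  for (a1 in c(10, 100, 1000)) {
    w <- transcript_weights(m, c(G1 = a1, G2 = 5))
    ctx <- prune(m, w, biomass_fraction = 0)
    expect_true("P1" %in% ctx$kept_reactions, info = paste("abundance", a1))
    expect_false("P2" %in% ctx$kept_reactions)
  }
})

test_that("contextual sampling respects the weighted-flux retention constraint", {
  m <- make_toy_model(1)
  truth <- synthetic_truth(3)
  sim <- simulate_expression(m, truth, n_male = 4, n_female = 4, seed = 3)
  ctx <- averaged_model(m, sim$expr, sim$labels, "female",
                        sample_fluxes = FALSE)
  ctx <- contextual_sample(ctx, n = 110, objective_fraction = 0.8, seed = 17)
  fs <- ctx$flux_samples
  expect_equal(nrow(fs$samples), 110)
  chk <- check_flux_samples(ctx$model, fs)
  expect_lt(chk$max_balance, 1e-6)
  expect_lt(chk$max_bound, 1e-6)
  expect_lt(chk$max_constraint, 1e-6)
  # recompute sum w'|v| per sample against the retained maximum
  rids <- reaction_ids(ctx$model)
  w_inv <- 1 - pmin(pmax(ctx$weights[rids], 0), 1)
  z_star <- attr(fs, "weighted_flux_max")
  per_sample <- as.numeric(abs(fs$samples[, rids]) %*% w_inv)
  expect_true(all(per_sample >= 0.8 * z_star - 1e-6))
  # biomass floor holds in every sample
  expect_true(all(fs$samples[, "BIOMASS"] >=
                  0.4 * ctx$base_max_biomass - 1e-6))
})

test_that("a collapsed objective polytope concentrates the samples", {
  m <- two_path_model()
  m$reactions[["R_out"]]$ub <- 10
  w <- c(R_in = 0.2, P1 = 0.1, P2 = 0.9, R_out = 0.2)
  ctx <- prune(m, w, biomass_fraction = 0.5)
  ctx <- contextual_sample(ctx, n = 30, objective_fraction = 1, seed = 5)
  v <- ctx$flux_samples$samples
  # at fraction 1 the weighted-flux constraint pins the optimum
  spread <- apply(v, 2, function(x) diff(range(x)))
  expect_lt(max(spread), 1e-6)
})

test_that("cohorts are deterministic, sex-aware, and report exclusions", {
  m <- make_toy_model(1)
  truth <- synthetic_truth(5)
  sim <- simulate_expression(m, truth, n_male = 5, n_female = 5, seed = 5,
                             n_crippled = 1)
  coh <- build_cohort(m, sim$expr, sim$labels, sample_fluxes = FALSE)
  expect_equal(nrow(coh$excluded), 1)
  expect_identical(coh$excluded$sample_id, sim$crippled)
  expect_equal(coh$retention$n_retained[coh$retention$sex == "male"], 4)
  expect_equal(coh$retention$n_retained[coh$retention$sex == "female"], 5)
  expect_length(coh$models, 9)
  # identical expression columns give identical kept sets
  expr2 <- sim$expr
  expr2[, "F002"] <- expr2[, "F001"]
  coh2 <- build_cohort(m, expr2, sim$labels, sample_fluxes = FALSE)
  expect_setequal(coh2$models[["F001"]]$kept_reactions,
                  coh2$models[["F002"]]$kept_reactions)
  # every retained model meets the 40% filter
  expect_true(all(vapply(coh$models, `[[`, logical(1), "feasible_at_040")))
})

test_that("averaging a group of identical samples equals the single-sample context", {
  m <- make_toy_model(1)
  truth <- synthetic_truth(8)
  sim <- simulate_expression(m, truth, n_male = 3, n_female = 3, seed = 8)
  expr <- sim$expr
  expr[, "F002"] <- expr[, "F001"]
  expr[, "F003"] <- expr[, "F001"]
  avg <- averaged_model(m, expr, sim$labels, "female", sample_fluxes = FALSE)
  one <- build_cohort(m, expr[, "F001", drop = FALSE],
                      c(F001 = "female"), sample_fluxes = FALSE)
  expect_setequal(avg$kept_reactions, one$models[["F001"]]$kept_reactions)
  # empty group is an error
  expect_error(averaged_model(m, expr, c(F001 = "female"), "male"),
               class = "hepaflux_config_error")
})

test_that("averaged sex models recover the planted ribose-disposal branch", {
  m <- make_toy_model(1)
  truth <- synthetic_truth(13)
  sim <- simulate_expression(m, truth, n_male = 6, n_female = 6, seed = 13)
  fm <- averaged_model(m, sim$expr, sim$labels, "female", sample_fluxes = FALSE)
  mm <- averaged_model(m, sim$expr, sim$labels, "male", sample_fluxes = FALSE)
  expect_true(all(c("RBTD", "RBTt") %in% fm$kept_reactions))
  expect_true("RIBt" %in% fm$pruned_reactions)
  expect_true("RIBt" %in% mm$kept_reactions)
  expect_true(all(c("RBTD", "RBTt") %in% mm$pruned_reactions))
})
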