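test_that("FBA finds the bottleneck optimum on a linear chain", {
  m <- chain_model(ub_in = 10)
  res <- fba(m)
  expect_equal(res$objective_value, 10, tolerance = 1e-8)
  expect_equal(unname(res$fluxes[c("R_in", "R_mid", "R_out")]), c(10, 10, 10),
               tolerance = 1e-8)
  # forced-zero objective
  m0 <- set_bounds(m, "R_out", lb = 0, ub = 0)
  expect_equal(fba(m0)$objective_value, 0, tolerance = 1e-10)
  # minimisation direction
  expect_equal(fba(m, direction = "min")$objective_value, 0, tolerance = 1e-10)
})

test_that("FBA flags infeasible models", {
  m <- chain_model()
  # require flux out of an emptied chain
  m$reactions[["R_in"]]$ub <- 0
  m$reactions[["R_out"]]$lb <- 5
  expect_error(fba(m), class = "hepaflux_infeasible_error")
})

test_that("weighted flux-sum minimisation routes through the cheap path", {
  m <- two_path_model()
  m$reactions[["R_out"]]$lb <- 10   # force throughput
  v <- minimize_weighted_flux(m, weights = c(P1 = 0.1, P2 = 0.9))
  expect_equal(unname(v["P1"]), 10, tolerance = 1e-8)
  expect_equal(unname(v["P2"]), 0, tolerance = 1e-8)
  # enumeration oracle: the two extreme routings
  cost_p1 <- 0.1 * 10 + 1 * 10 + 1 * 10  # P1 route + default-weight in/out
  cost_p2 <- 0.9 * 10 + 1 * 10 + 1 * 10
  expect_equal(attr(v, "objective"), min(cost_p1, cost_p2), tolerance = 1e-8)
  # swap the weights and the routing flips
  v2 <- minimize_weighted_flux(m, weights = c(P1 = 0.9, P2 = 0.1))
  expect_equal(unname(v2["P2"]), 10, tolerance = 1e-8)
})

test_that("uniform weights reproduce the parsimonious (pFBA) flux total", {
  m <- make_toy_model(1)
  v <- minimize_weighted_flux(m, weights = NULL, biomass_fraction = 0.4,
                              default_weight = 1)
  # oracle: identical LP solved by scipy/HiGGS on an independent encoding
  bm_min <- 0.4 * fba(m)$objective_value
  w <- rep(1, length(m$reactions))
  sol <- scipy_solve_lps(list(oracle_weighted_problem(m, w, bm_min)))[[1]]
  expect_equal(sol$status, 0L)
  expect_equal(attr(v, "objective"), sol$value, tolerance = 1e-6)
})

test_that("zero-demand models admit the zero flux vector at fraction 0", {
  m <- two_path_model()   # all lower bounds 0
  v <- minimize_weighted_flux(m, biomass_fraction = 0)
  expect_equal(max(abs(v)), 0, tolerance = 1e-10)
})

test_that("weighted flux-sum maximisation saturates bounds", {
  m <- metabolic_model(
    id = "single",
    metabolites = data.frame(id = "A", name = "A", compartment = "c"),
    reactions = list(
      reaction("R1", stoichiometry = c(A = 1), lb = 0, ub = 5),
      reaction("R2", stoichiometry = c(A = -1), lb = 0, ub = 5)
    ),
    objective = "R2"
  )
  mx <- maximize_weighted_flux(m, weights = c(R1 = 1, R2 = 0),
                               default_weight = 0)
  expect_equal(mx$objective_value, 5, tolerance = 1e-8)
  # all-zero weights give objective 0
  mx0 <- maximize_weighted_flux(m, weights = NULL, default_weight = 0)
  expect_equal(mx0$objective_value, 0, tolerance = 1e-10)
  # infinite bounds are refused with the offending reactions named
  m$reactions[["R1"]]$ub <- Inf
  err <- tryCatch(maximize_weighted_flux(m, default_weight = 1),
                  error = identity)
  expect_s3_class(err, "hepaflux_unbounded_error")
  expect_match(conditionMessage(err), "R1")
})

test_that("LP results match the scipy/HiGHS oracle across jittered fixtures", {
  # 20+ fixtures: toy model under random bound jitters and random
  # weights, checked for fba max and weighted min/max agreement.
  base <- make_toy_model(1)
  rids <- reaction_ids(base)
  set.seed(2024)
  problems <- list()
  mine <- numeric(0)
  kinds <- character(0)
  for (k in 1:7) {
    m <- base
    # jitter uptake capacities to vary the optimum
    m$reactions[["EX_glc"]]$lb <- -stats::runif(1, 4, 12)
    m$reactions[["EX_aa"]]$lb <- -stats::runif(1, 2, 8)
    m$reactions[["ATPM"]]$lb <- stats::runif(1, 0.2, 2)
    w <- stats::setNames(stats::runif(length(rids)), rids)

    f <- fba(m)
    problems[[length(problems) + 1]] <- oracle_fba_problem(m, m$objective)
    mine <- c(mine, f$objective_value); kinds <- c(kinds, "fba")

    bm_min <- 0.4 * f$objective_value
    v <- minimize_weighted_flux(m, w, biomass_fraction = 0.4)
    problems[[length(problems) + 1]] <-
      oracle_weighted_problem(m, unname(w[rids]), bm_min, maximize = FALSE)
    mine <- c(mine, attr(v, "objective")); kinds <- c(kinds, "min")

    mx <- maximize_weighted_flux(m, w, biomass_fraction = 0.4)
    problems[[length(problems) + 1]] <-
      oracle_weighted_problem(m, unname(w[rids]), bm_min, maximize = TRUE)
    mine <- c(mine, mx$objective_value); kinds <- c(kinds, "max")
  }
  sols <- scipy_solve_lps(problems)
  for (i in seq_along(sols)) {
    expect_equal(sols[[i]]$status, 0L, info = paste("fixture", i, kinds[i]))
    denom <- max(1, abs(sols[[i]]$value))
    expect_lt(abs(mine[i] - sols[[i]]$value) / denom, 1e-6)
  }
})

test_that("infeasible biomass floors raise errors carrying the fraction", {
  m <- make_toy_model(1)
  m2 <- set_bounds(m, "NUCSYN", lb = 0, ub = 0)  # no nucleotides, no growth
  err <- tryCatch(
    minimize_weighted_flux(m2, biomass_fraction = 0.4,
                           biomass_min = 0.4 * fba(m)$objective_value),
    error = identity
  )
  expect_s3_class(err, "hepaflux_infeasible_error")
  expect_equal(err$biomass_fraction, 0.4)
})
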