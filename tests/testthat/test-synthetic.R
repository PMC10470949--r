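test_that("the toy model is well-formed, growing, and branch-redundant", {
  m <- make_toy_model(1)
  expect_silent(validate_model(m))
  n <- length(m$reactions)
  expect_gte(n, 30); expect_lte(n, 60)
  # AND/OR GPRs on at least half the reactions
  with_gpr <- sum(vapply(m$reactions, function(r) !is.null(r$gpr), logical(1)))
  expect_gte(with_gpr / n, 0.5)
  # labelled subsystems incl. the focal ones
  subs <- unique(stats::na.omit(subsystems(m)))
  expect_true(all(c("Glycolysis / Gluconeogenesis", "Pentose phosphate pathway",
                    "Nucleotide metabolism", "Transport reactions") %in% subs))
  # growth, and growth through either disposal branch alone
  base <- fba(m)$objective_value
  expect_gt(base, 0)
  no_direct <- fba(set_bounds(m, "RIBt", lb = 0, ub = 0))$objective_value
  no_ribitol <- fba(set_bounds(m, c("RBTD", "RBTt"), lb = 0, ub = 0))$objective_value
  expect_gt(no_direct, 0.5 * base)
  expect_gt(no_ribitol, 0.5 * base)
  # closing both branches stops growth (ribose must be disposed of)
  none <- fba(set_bounds(m, c("RIBt", "RBTD"), lb = 0, ub = 0))$objective_value
  expect_lt(none, 1e-8)
  # determinism
  expect_true(hepaflux:::models_equal(make_toy_model(1), make_toy_model(1)))
})

test_that("subsystem count is configurable", {
  m5 <- make_toy_model(1, n_subsystems = 5)
  m10 <- make_toy_model(1, n_subsystems = 10)
  count_metabolic <- function(m) {
    subs <- unique(stats::na.omit(subsystems(m)))
    length(setdiff(subs, c("Transport reactions", "Exchange/demand reactions",
                           "Biomass and maintenance")))
  }
  expect_equal(count_metabolic(m5), 5)
  expect_equal(count_metabolic(m10), 10)
  expect_gt(fba(m5)$objective_value, 0)
  expect_gt(fba(m10)$objective_value, 0)
})

test_that("expression simulation is seeded, labelled and marker-separable", {
  m <- make_toy_model(1)
  truth <- synthetic_truth(2)
  a <- simulate_expression(m, truth, n_male = 10, n_female = 10, seed = 2)
  b <- simulate_expression(m, truth, n_male = 10, n_female = 10, seed = 2)
  expect_identical(a$expr, b$expr)
  c <- simulate_expression(m, truth, n_male = 10, n_female = 10, seed = 3)
  expect_false(identical(a$expr, c$expr))
  expect_equal(dim(a$expr), c(length(m$genes) + 21L, 20L))
  expect_true(all(a$expr >= 0))

  # the marker rule never mislabels; every assigned call matches truth
  sx <- infer_sex(a$expr, "G_sry")
  assigned <- sx != "unassigned"
  expect_gt(sum(assigned), 0)
  expect_true(all(sx[assigned] == a$labels[assigned]))
})

test_that("null simulations carry no planted signal", {
  m <- make_toy_model(1)
  null_truth <- synthetic_truth(
    7, biased_subsystems = data.frame(subsystem = character(0),
                                      direction = character(0),
                                      effect = numeric(0)),
    plant_branch = FALSE
  )
  sim <- simulate_expression(m, null_truth, n_male = 20, n_female = 20, seed = 7)
  degs <- differential_expression(sim$expr, sim$labels)
  degs <- degs[degs$gene_id != "G_sry", ]   # the marker is real signal
  expect_lt(sum(degs$fdr < 0.1), 5)
  # planted effect is recovered
  eff_truth <- synthetic_truth(7)
  sim2 <- simulate_expression(m, eff_truth, n_male = 20, n_female = 20, seed = 7)
  degs2 <- differential_expression(sim2$expr, sim2$labels)
  glyc_genes <- unique(unlist(lapply(
    m$reactions[names(subsystems(m))[subsystems(m) %in%
                                     "Glycolysis / Gluconeogenesis"]],
    function(r) gpr_genes(r$gpr)
  )))
  hit <- degs2[degs2$gene_id %in% glyc_genes, ]
  expect_true(all(hit$fdr < 0.1))
  expect_equal(mean(hit$log2fc), 2, tolerance = 0.25)
})

test_that("adverse-event simulation matches its generating rates", {
  sim <- simulate_aers(seed = 9)
  expect_equal(nrow(sim$quarterly), 142)   # 71 quarters x 2 sexes
  expect_identical(sim$quarterly$quarter[1], "2004Q1")
  expect_identical(sim$quarterly$quarter[71], "2021Q3")
  q <- quarterly_proportions(sim$quarterly)
  expect_equal(mean(q$proportion[q$sex == "male"]), 0.05, tolerance = 0.01)
  expect_equal(mean(q$proportion[q$sex == "female"]), 0.07, tolerance = 0.01)
  expect_identical(simulate_aers(seed = 9)$quarterly, sim$quarterly)
  # drug table exercises the volume filter in both directions
  expect_true(any(sim$drugs$female_reports + sim$drugs$male_reports <= 1e5))
  expect_true(any(sim$drugs$female_reports + sim$drugs$male_reports > 1e5))
})

test_that("simulate_all writes a coherent text bundle", {
  outdir <- withr::local_tempdir()
  paths <- simulate_all(outdir, seed = 4, n_male = 4, n_female = 4)
  expect_true(all(file.exists(paths)))
  m <- read_model(paths["model"])
  expect_silent(validate_model(m))
  expr <- read_expression_tsv(paths["expression"])
  lab <- utils::read.delim(paths["labels"])
  expect_equal(ncol(expr), nrow(lab))
  expect_true(all(c("G_sry", m$genes) %in% rownames(expr)))
  q <- utils::read.csv(paths["quarterly"])
  expect_silent(quarterly_proportions(q))
})
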