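## Synthetic inputs with known ground truth: a ~50-reaction liver-like
## toy GEM, expression cohorts with planted sex-biased subsystems and a
## sex-specific pentose-phosphate branch choice, and quarterly
## sex-stratified adverse-event tables.
##
## The toy network has a glycolysis backbone feeding pyruvate and ATP,
## an oxidative PPP producing ribose-5-phosphate, nucleotide synthesis
## that consumes r5p and releases free ribose (so any growth forces
## ribose disposal), and two disposal branches: direct ribose export
## (RIBt) versus reduction to ribitol with NAD+ regeneration followed
## by ribitol export (RBTD + RBTt).  Which branch a context model keeps
## is controlled by the planted expression of the branch genes.

#' Generate the toy liver-like metabolic model
#'
#' Deterministic construction (the seed is recorded for provenance):
#' glycolysis backbone, oxidative PPP, nucleotide synthesis releasing
#' free ribose, the two-branch ribose-disposal motif, lumped TCA /
#' oxidative phosphorylation / fatty-acid / amino-acid / xenobiotic
#' modules, exchanges, an ATP maintenance demand and a biomass
#' reaction.  Over half the reactions carry AND/OR GPRs.
#'
#' @param seed Integer, recorded in the model id.
#' @param n_subsystems Number of metabolic subsystems (5-12; default
#'   8).  Below 8 the xenobiotic, amino-acid and fatty-acid modules are
#'   dropped (in that order); above 8 generic auxiliary pathways are
#'   appended.
#' @return A validated `metabolic_model` with positive maximal biomass
#'   flux.
#' @export
make_toy_model <- function(seed = 1, n_subsystems = 8) {
  stopifnot(n_subsystems >= 5, n_subsystems <= 12)
  met <- function(id, name, comp) data.frame(id = id, name = name, compartment = comp,
                                             stringsAsFactors = FALSE)
  mets <- rbind(
    met("glc_e", "glucose", "e"),        met("glc_c", "glucose", "c"),
    met("g6p_c", "glucose-6-phosphate", "c"),
    met("f6p_c", "fructose-6-phosphate", "c"),
    met("fbp_c", "fructose-bisphosphate", "c"),
    met("g3p_c", "glyceraldehyde-3-phosphate", "c"),
    met("pep_c", "phosphoenolpyruvate", "c"),
    met("pyr_c", "pyruvate", "c"),
    met("lac_c", "lactate", "c"),        met("lac_e", "lactate", "e"),
    met("atp_c", "ATP", "c"),            met("adp_c", "ADP", "c"),
    met("nad_c", "NAD+", "c"),           met("nadh_c", "NADH", "c"),
    met("r5p_c", "ribose-5-phosphate", "c"),
    met("rib_c", "ribose", "c"),         met("rib_e", "ribose", "e"),
    met("rbt_c", "ribitol", "c"),        met("rbt_e", "ribitol", "e"),
    met("aa_e", "amino acids", "e"),     met("aa_c", "amino acids", "c"),
    met("nuc_c", "purine nucleotide", "c"),
    met("nuc2_c", "pyrimidine nucleotide", "c"),
    met("nucp_c", "purine nucleotide triphosphate", "c"),
    met("co2_c", "CO2", "c"),            met("co2_e", "CO2", "e"),
    met("accoa_c", "acetyl-CoA", "c")
  )
  sub <- list(
    glyc = "Glycolysis / Gluconeogenesis",
    ppp = "Pentose phosphate pathway",
    nuc = "Nucleotide metabolism",
    tca = "TCA and glyoxylate/dicarboxylate metabolism",
    oxp = "Oxidative phosphorylation",
    fa = "Fatty acid oxidation",
    aam = "Amino acid metabolism",
    xen = "Xenobiotics metabolism",
    tr = "Transport reactions",
    ex = "Exchange/demand reactions",
    bio = "Biomass and maintenance"
  )
  rx <- function(id, st, lb = 0, ub = 1000, gpr = NULL, subsystem) {
    reaction(id, stoichiometry = st, lb = lb, ub = ub, gpr = gpr,
             subsystem = subsystem)
  }
  rxns <- list(
    ## exchanges (negative flux = uptake)
    rx("EX_glc", c(glc_e = -1), lb = -10, ub = 0, subsystem = sub$ex),
    rx("EX_aa", c(aa_e = -1), lb = -5, ub = 0, subsystem = sub$ex),
    rx("EX_lac", c(lac_e = -1), subsystem = sub$ex),
    rx("EX_rib", c(rib_e = -1), subsystem = sub$ex),
    rx("EX_rbt", c(rbt_e = -1), subsystem = sub$ex),
    rx("EX_co2", c(co2_e = -1), subsystem = sub$ex),
    ## transport
    rx("GLCt", c(glc_e = -1, glc_c = 1), gpr = "G_slc2a1 or G_slc2a2",
       subsystem = sub$tr),
    rx("AAt", c(aa_e = -1, aa_c = 1), gpr = "G_slc7a1 and G_slc3a2", subsystem = sub$tr),
    rx("LACt", c(lac_c = -1, lac_e = 1), gpr = "G_slc16a1 and G_bsg", subsystem = sub$tr),
    ## ABC-type active export: the ATP cost balances the NADH the
    ## ribitol branch consumes, so transcript weights decide the branch
    rx("RIBt", c(rib_c = -1, atp_c = -2, rib_e = 1, adp_c = 2),
       gpr = "G_ribt", subsystem = sub$tr),
    rx("RBTt", c(rbt_c = -1, rbt_e = 1), gpr = "G_rbtt", subsystem = sub$tr),
    rx("CO2t", c(co2_c = -1, co2_e = 1), subsystem = sub$tr),
    ## glycolysis
    rx("HEX1", c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1),
       gpr = "G_hk1 or G_gck", subsystem = sub$glyc),
    rx("PGI", c(g6p_c = -1, f6p_c = 1), lb = -1000, gpr = "G_gpi",
       subsystem = sub$glyc),
    rx("PFK", c(f6p_c = -1, atp_c = -1, fbp_c = 1, adp_c = 1),
       gpr = "G_pfkl and G_pfkm", subsystem = sub$glyc),
    rx("FBA", c(fbp_c = -1, g3p_c = 2), gpr = "G_aldob",
       subsystem = sub$glyc),
    rx("GAPD", c(g3p_c = -1, nad_c = -1, adp_c = -1,
                 pep_c = 1, nadh_c = 1, atp_c = 1),
       gpr = "G_gapdh and G_pgk1", subsystem = sub$glyc),
    rx("PYK", c(pep_c = -1, adp_c = -1, pyr_c = 1, atp_c = 1),
       gpr = "G_pklr or G_pkm", subsystem = sub$glyc),
    rx("LDH", c(pyr_c = -1, nadh_c = -1, lac_c = 1, nad_c = 1), lb = -1000,
       gpr = "G_ldha or G_ldhb", subsystem = sub$glyc),
    ## pentose phosphate pathway and the two-branch ribose disposal
    rx("G6PDH", c(g6p_c = -1, nad_c = -2, r5p_c = 1, nadh_c = 2, co2_c = 1),
       gpr = "G_g6pd and G_pgls", subsystem = sub$ppp),
    rx("RPI", c(r5p_c = -1, rib_c = 1), gpr = "G_rpia or G_rpe", subsystem = sub$ppp),
    rx("RBTD", c(rib_c = -1, nadh_c = -1, rbt_c = 1, nad_c = 1),
       gpr = "G_rdh", subsystem = sub$ppp),
    ## nucleotide metabolism (releases free ribose: growth forces disposal)
    rx("NUCSYN", c(r5p_c = -2, atp_c = -2, aa_c = -1,
                   nuc_c = 1, adp_c = 2, rib_c = 1),
       gpr = "G_prps1 and (G_ppat or G_gart)", subsystem = sub$nuc),
    rx("NUCSYN2", c(r5p_c = -1, atp_c = -1, aa_c = -1, nuc2_c = 1, adp_c = 1),
       gpr = "G_umps", subsystem = sub$nuc),
    rx("NTK", c(nuc_c = -1, atp_c = -1, nucp_c = 1, adp_c = 1),
       gpr = "G_nme1 or G_nme2", subsystem = sub$nuc),
    ## TCA (lumped)
    rx("PDH", c(pyr_c = -1, nad_c = -1, accoa_c = 1, nadh_c = 1, co2_c = 1),
       gpr = "G_pdha1 and G_dlat", subsystem = sub$tca),
    rx("TCAOX", c(accoa_c = -1, nad_c = -3, nadh_c = 3, co2_c = 2),
       gpr = "G_cs", subsystem = sub$tca),
    rx("SUCOAS", c(accoa_c = -1, adp_c = -1, atp_c = 1, co2_c = 2),
       gpr = "G_suclg1 or G_suclg2", subsystem = sub$tca),
    ## oxidative phosphorylation (lumped; different P/O ratios)
    rx("OXPHOS", c(nadh_c = -1, adp_c = -2, nad_c = 1, atp_c = 2),
       gpr = "(G_ndufa1 and G_ndufb1) or G_cox4i1", subsystem = sub$oxp),
    rx("OXPHOS2", c(nadh_c = -1, adp_c = -1, nad_c = 1, atp_c = 1),
       gpr = "G_sdha and G_sdhb", subsystem = sub$oxp),
    rx("UNCPL", c(nadh_c = -1, nad_c = 1), gpr = "G_ucp2", subsystem = sub$oxp),
    ## biomass and maintenance
    rx("ATPM", c(atp_c = -1, adp_c = 1), lb = 1, subsystem = sub$bio),
    rx("BIOMASS", c(nucp_c = -0.5, nuc2_c = -0.5, pyr_c = -1, aa_c = -1,
                    atp_c = -3, adp_c = 3),
       subsystem = sub$bio)
  )
  if (n_subsystems >= 6) {
    mets <- rbind(mets, met("fa_e", "fatty acid", "e"),
                  met("fa_c", "fatty acid", "c"),
                  met("facoa_c", "fatty acyl-CoA", "c"),
                  met("facoam_c", "mitochondrial fatty acyl-CoA", "c"))
    rxns <- c(rxns, list(
      rx("EX_fa", c(fa_e = -1), lb = -3, ub = 0, subsystem = sub$ex),
      rx("FAt", c(fa_e = -1, fa_c = 1), gpr = "G_cd36", subsystem = sub$tr),
      rx("FACT", c(fa_c = -1, atp_c = -1, facoa_c = 1, adp_c = 1),
         gpr = "G_acsl1", subsystem = sub$fa),
      rx("CPTS", c(facoa_c = -1, facoam_c = 1), gpr = "G_cpt1a and G_cpt2",
         subsystem = sub$fa),
      rx("BOX", c(facoam_c = -1, nad_c = -3, accoa_c = 1, nadh_c = 3),
         gpr = "G_acadm or G_acadl", subsystem = sub$fa)
    ))
  }
  if (n_subsystems >= 7) {
    rxns <- c(rxns, list(
      rx("AADEG", c(aa_c = -1, nad_c = -1, pyr_c = 1, nadh_c = 1),
         gpr = "G_gpt", subsystem = sub$aam),
      rx("AADEG2", c(aa_c = -1, nad_c = -1, accoa_c = 1, nadh_c = 1),
         gpr = "G_bcat1 and G_bcat2", subsystem = sub$aam),
      rx("AASYN", c(pyr_c = -1, nadh_c = -1, aa_c = 1, nad_c = 1),
         gpr = "G_got1 or G_got2", subsystem = sub$aam)
    ))
  }
  if (n_subsystems >= 8) {
    mets <- rbind(mets, met("xen_e", "xenobiotic", "e"),
                  met("xen_c", "xenobiotic", "c"),
                  met("xeno_c", "oxidised xenobiotic", "c"),
                  met("xconj_c", "conjugated xenobiotic", "c"),
                  met("xconj_e", "conjugated xenobiotic", "e"))
    rxns <- c(rxns, list(
      rx("EX_xen", c(xen_e = -1), lb = -1, ub = 0, subsystem = sub$ex),
      rx("XENt", c(xen_e = -1, xen_c = 1), gpr = "G_slco1b1 or G_slco1b3", subsystem = sub$tr),
      rx("XENOX", c(xen_c = -1, nadh_c = -1, xeno_c = 1, nad_c = 1),
         gpr = "G_cyp3a4 or G_cyp1a2", subsystem = sub$xen),
      rx("XENCONJ", c(xeno_c = -1, aa_c = -1, xconj_c = 1),
         gpr = "G_ugt1a1 and G_sult1a1", subsystem = sub$xen),
      rx("XCJt", c(xconj_c = -1, xconj_e = 1), gpr = "G_abcc2",
         subsystem = sub$xen),
      rx("EX_xconj", c(xconj_e = -1), subsystem = sub$ex)
    ))
  }
  if (n_subsystems > 8) {
    for (k in seq_len(n_subsystems - 8)) {
      aux <- sprintf("aux%d", k)
      mets <- rbind(mets,
                    met(paste0(aux, "_e"), paste("auxiliary substrate", k), "e"),
                    met(paste0(aux, "_c"), paste("auxiliary substrate", k), "c"),
                    met(paste0(aux, "m_c"), paste("auxiliary intermediate", k), "c"),
                    met(paste0(aux, "n_c"), paste("auxiliary product", k), "c"),
                    met(paste0(aux, "n_e"), paste("auxiliary product", k), "e"))
      st1 <- stats::setNames(c(-1), paste0(aux, "_e"))
      st2 <- stats::setNames(c(-1, 1), c(paste0(aux, "_e"), paste0(aux, "_c")))
      st3 <- stats::setNames(c(-1, 1), c(paste0(aux, "_c"), paste0(aux, "m_c")))
      st4 <- stats::setNames(c(-1, -1, 1, 1),
                             c(paste0(aux, "m_c"), "nad_c", paste0(aux, "n_c"), "nadh_c"))
      st5 <- stats::setNames(c(-1, 1), c(paste0(aux, "n_c"), paste0(aux, "n_e")))
      st6 <- stats::setNames(c(-1), paste0(aux, "n_e"))
      sname <- sprintf("Auxiliary pathway %d", k)
      rxns <- c(rxns, list(
        rx(paste0("EX_", aux), st1, lb = -2, ub = 0, subsystem = sub$ex),
        rx(paste0("AUXt", k), st2, gpr = sprintf("G_aux%dt", k), subsystem = sub$tr),
        rx(paste0("AUXM", k), st3, gpr = sprintf("G_aux%da or G_aux%db", k, k),
           subsystem = sname),
        rx(paste0("AUXO", k), st4, gpr = sprintf("G_aux%dc and G_aux%dd", k, k),
           subsystem = sname),
        rx(paste0("AUXS", k), st5, gpr = sprintf("G_aux%de", k), subsystem = sname),
        rx(paste0("EX_", aux, "n"), st6, subsystem = sub$ex)
      ))
    }
  }
  metabolic_model(
    id = sprintf("toy_liver_s%d", as.integer(seed)),
    metabolites = mets, reactions = rxns, objective = "BIOMASS"
  )
}

#' Ground truth for a synthetic study
#'
#' Bundles the planted structure the generators imprint on their
#' outputs: sex-biased subsystems (direction and log2 effect size), the
#' sex-specific ribose-disposal branch genes, and the adverse-event sex
#' effect.
#'
#' @param seed Master seed.
#' @param biased_subsystems Data frame `subsystem`, `direction`
#'   (`"male"`/`"female"`), `effect` (log2 fold change).  Default: a
#'   male-biased glycolysis and a female-biased nucleotide metabolism
#'   at effect 2.  Use a 0-row frame for a global null.
#' @param plant_branch Plant the sex-specific branch expression
#'   (female: ribitol route `RBTD`+`RBTt`; male: direct export `RIBt`)?
#'   Default `TRUE`.
#' @param branch_effect Log2 shift applied to the favoured branch genes
#'   (default 4).
#' @param aers_sex_effect Additive shift of the female liver-report
#'   proportion (default 0.02).
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(seed = 1,
                            biased_subsystems = data.frame(
                              subsystem = c("Glycolysis / Gluconeogenesis",
                                            "Nucleotide metabolism"),
                              direction = c("male", "female"),
                              effect = c(2, 2),
                              stringsAsFactors = FALSE
                            ),
                            plant_branch = TRUE,
                            branch_effect = 4,
                            aers_sex_effect = 0.02) {
  structure(
    list(
      seed = as.integer(seed),
      biased_subsystems = biased_subsystems,
      plant_branch = plant_branch,
      branch_effect = branch_effect,
      planted_unique = list(
        female = c("RBTD", "RBTt"),
        male = c("RIBt")
      ),
      aers_sex_effect = aers_sex_effect
    ),
    class = "synthetic_truth"
  )
}

#' Simulate an expression cohort on the toy model
#'
#' Per-gene baselines are drawn on the log2 scale and shared across
#' samples; genes of planted sex-biased subsystems are shifted by the
#' effect size in the favoured sex; the branch genes are shifted by
#' `branch_effect` (female: `G_rdh`, `G_rbtt`; male: `G_ribt`); a
#' male-specific marker gene `G_sry` is high in males and near zero in
#' females; independent Normal noise of sd `noise_sd` is added per
#' sample; values are returned on the linear scale (`2^x`).  Background
#' genes not in the model are included so gene filtering is exercised.
#'
#' @param model The toy `metabolic_model`.
#' @param truth A `synthetic_truth`.
#' @param n_male,n_female Cohort sizes (default 20 each).
#' @param noise_sd Log2-scale noise standard deviation (default 0.3).
#' @param seed Seed (default: the truth's seed).
#' @param n_crippled Number of male samples whose essential nucleotide
#'   gene `G_prps1` is zeroed, making their context model infeasible at
#'   the biomass floor (default 0).
#' @param n_background Background (non-model) genes (default 20).
#' @return List with `expr` (linear-scale matrix), `labels` (named,
#'   generating truth), `crippled` (sample ids), `truth`.
#' @export
simulate_expression <- function(model, truth = synthetic_truth(),
                                n_male = 20, n_female = 20, noise_sd = 0.3,
                                seed = truth$seed, n_crippled = 0,
                                n_background = 20) {
  genes <- model$genes
  bg <- if (n_background > 0) sprintf("G_bg%02d", seq_len(n_background)) else character(0)
  all_genes <- c(genes, "G_sry", bg)
  samples <- c(sprintf("M%03d", seq_len(n_male)), sprintf("F%03d", seq_len(n_female)))
  sex <- c(rep("male", n_male), rep("female", n_female))
  names(sex) <- samples
  subs <- subsystems(model)
  with_seed(seed, {
    mu <- pmax(stats::rnorm(length(all_genes), mean = 8, sd = 1), 5)
    names(mu) <- all_genes
    mu["G_sry"] <- 0   # female baseline; male columns get the marker shift
    M <- matrix(mu, nrow = length(all_genes), ncol = length(samples),
                dimnames = list(all_genes, samples))
    M["G_sry", sex == "male"] <- 8
    if (nrow(truth$biased_subsystems) > 0) {
      for (i in seq_len(nrow(truth$biased_subsystems))) {
        sname <- truth$biased_subsystems$subsystem[i]
        dir_i <- truth$biased_subsystems$direction[i]
        eff <- truth$biased_subsystems$effect[i]
        member_rxns <- names(subs)[!is.na(subs) & subs == sname]
        sgenes <- unique(unlist(lapply(model$reactions[member_rxns],
                                       function(r) gpr_genes(r$gpr))))
        sgenes <- intersect(sgenes, all_genes)
        M[sgenes, sex == dir_i] <- M[sgenes, sex == dir_i] + eff
      }
    }
    if (isTRUE(truth$plant_branch)) {
      fg <- intersect(c("G_rdh", "G_rbtt"), all_genes)
      mg <- intersect("G_ribt", all_genes)
      M[fg, sex == "female"] <- M[fg, sex == "female"] + truth$branch_effect
      M[mg, sex == "male"] <- M[mg, sex == "male"] + truth$branch_effect
    }
    noise <- matrix(stats::rnorm(length(M), sd = noise_sd), nrow = nrow(M))
    expr <- 2^(M + noise)
    expr["G_sry", sex == "female"] <-
      expr["G_sry", sex == "female"] * stats::runif(sum(sex == "female"), 0.5, 1.5)
    crippled <- character(0)
    if (n_crippled > 0) {
      crippled <- samples[sex == "male"][seq_len(n_crippled)]
      expr["G_prps1", crippled] <- 0
    }
    list(expr = expr, labels = sex, crippled = crippled, truth = truth)
  })
}

#' Simulate quarterly sex-stratified adverse-event tables
#'
#' Quarterly totals are Poisson around `total_reports`; liver-related
#' counts are Binomial with rate `base_rate` for males and
#' `base_rate + sex_effect` for females.  A per-drug report table with
#' a spread of female fractions (and some drugs below the volume
#' filter) is generated alongside.
#'
#' @param n_quarters Number of quarters starting 2004Q1 (default 71,
#'   i.e. through 2021Q3).
#' @param base_rate Male liver-report proportion (default 0.05).
#' @param sex_effect Additive female excess (default 0.02).
#' @param total_reports Expected reports per quarter and sex
#'   (default 1e5).
#' @param seed Integer seed.
#' @return List with `quarterly` (columns `quarter`, `sex`,
#'   `liver_reports`, `total_reports`), `drugs` (columns `drug`,
#'   `female_reports`, `male_reports`), and `truth`.
#' @export
simulate_aers <- function(n_quarters = 71, base_rate = 0.05, sex_effect = 0.02,
                          total_reports = 1e5, seed = 1) {
  stopifnot(base_rate > 0, base_rate + sex_effect < 1, base_rate + sex_effect > 0)
  years <- 2004 + (seq_len(n_quarters) - 1) %/% 4
  qs <- (seq_len(n_quarters) - 1) %% 4 + 1
  quarters <- sprintf("%dQ%d", years, qs)
  with_seed(seed, {
    rows <- list()
    for (s in c("male", "female")) {
      rate <- base_rate + if (s == "female") sex_effect else 0
      tot <- stats::rpois(n_quarters, total_reports)
      liv <- stats::rbinom(n_quarters, tot, rate)
      rows[[s]] <- data.frame(quarter = quarters, sex = s,
                              liver_reports = liv, total_reports = tot,
                              stringsAsFactors = FALSE)
    }
    quarterly <- do.call(rbind, rows)
    rownames(quarterly) <- NULL
    drug_names <- sprintf("drug_%s", letters[1:12])
    totals <- c(5e5, 3e5, 2.5e5, 2e5, 1.8e5, 1.5e5, 1.2e5, 1.1e5,
                9e4, 8e4, 5e4, 4e4)
    ffrac <- seq(0.35, 0.75, length.out = 12)
    female <- stats::rbinom(12, totals, ffrac)
    drugs <- data.frame(drug = drug_names,
                        female_reports = female,
                        male_reports = totals - female,
                        stringsAsFactors = FALSE)
    list(quarterly = quarterly, drugs = drugs,
         truth = list(base_rate = base_rate, sex_effect = sex_effect,
                      total_reports = total_reports, seed = as.integer(seed)))
  })
}

#' Write all synthetic inputs to a directory
#'
#' Writes the toy model (JSON), expression matrix and labels (TSV),
#' adverse-event tables (CSV) and the ground truth (JSON).
#'
#' @param outdir Output directory (created if needed).
#' @param seed Master seed.
#' @param ... Passed to [simulate_expression()].
#' @return Named character vector of written paths, invisibly.
#' @export
simulate_all <- function(outdir, seed = 1, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  model <- make_toy_model(seed)
  truth <- synthetic_truth(seed)
  sim <- simulate_expression(model, truth, seed = seed, ...)
  aers <- simulate_aers(seed = seed)
  paths <- c(
    model = file.path(outdir, "model.json"),
    expression = file.path(outdir, "expression.tsv"),
    labels = file.path(outdir, "labels.tsv"),
    quarterly = file.path(outdir, "aers_quarterly.csv"),
    drugs = file.path(outdir, "aers_drugs.csv"),
    truth = file.path(outdir, "truth.json")
  )
  write_model(model, paths["model"])
  expr_df <- data.frame(gene_id = rownames(sim$expr), sim$expr,
                        check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(expr_df, paths["expression"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(sim$labels), sex = unname(sim$labels)),
    paths["labels"], sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.csv(aers$quarterly, paths["quarterly"], row.names = FALSE)
  utils::write.csv(aers$drugs, paths["drugs"], row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed,
         biased_subsystems = sim$truth$biased_subsystems,
         plant_branch = sim$truth$plant_branch,
         branch_effect = sim$truth$branch_effect,
         planted_unique = sim$truth$planted_unique,
         aers = aers$truth,
         crippled = sim$crippled),
    paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
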