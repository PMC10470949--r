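## End-to-end orchestration: expression -> subsystem scoring, expression
## -> context models -> cohort comparison, and adverse-event analysis,
## driven by one config, with a provenance manifest.

#' Default pipeline configuration
#'
#' @param model Path to a model file (JSON or SBML).
#' @param expression Path to a gene-by-sample TSV (optional if `degs`
#'   given).
#' @param labels Path to a sample-sex TSV (optional; inferred from the
#'   marker gene when absent).
#' @param degs Path to a precomputed DEG TSV (optional).
#' @param aers_quarterly,aers_drugs Paths to adverse-event CSVs
#'   (optional).
#' @param output_dir Output directory.
#' @param seed Master seed.
#' @param fdr_threshold,alpha,n_permutations,min_reactions TIDEs-stage
#'   thresholds.
#' @param biomass_fraction,n_flux_samples,objective_fraction,min_frac
#'   Context-model-stage thresholds.
#' @param marker_gene Marker used when labels must be inferred.
#' @return A `run_config` list.
#' @export
run_config <- function(model, expression = NULL, labels = NULL, degs = NULL,
                       aers_quarterly = NULL, aers_drugs = NULL,
                       output_dir = "hepaflux_out", seed = 1,
                       fdr_threshold = 0.1, alpha = 0.025,
                       n_permutations = 1000, min_reactions = 3,
                       biomass_fraction = 0.4, n_flux_samples = 110,
                       objective_fraction = 0.8, min_frac = 0.1,
                       marker_gene = "G_sry") {
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1,
            alpha > 0, alpha < 0.5,
            n_permutations >= 1, min_reactions >= 1,
            biomass_fraction >= 0, biomass_fraction <= 1,
            n_flux_samples >= 1,
            objective_fraction >= 0, objective_fraction <= 1,
            min_frac >= 0, min_frac <= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a YAML/JSON file whose fields match
#'   [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(run_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Stages (each skipped when its inputs are absent, failures collected
#' rather than fatal): sex labelling (given or marker-inferred),
#' differential expression (or precomputed DEGs), subsystem scoring
#' with its permutation test, per-sample context-model extraction and
#' cohort comparison, and adverse-event proportion analysis.  All
#' outputs are plain TSV/JSON under `config$output_dir`; a manifest
#' records seeds, input hashes, and per-stage status, so identical
#' configs reproduce identical outputs.
#'
#' @param config A `run_config`.
#' @return The manifest list, invisibly.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$expression) && is.null(config$degs)) {
    stop_hf("config needs 'expression' and/or 'degs' input",
            "hepaflux_config_error")
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- Filter(Negate(is.null), config[c(
    "model", "expression", "labels", "degs", "aers_quarterly", "aers_drugs"
  )])
  for (p in inputs) {
    if (!file.exists(p)) {
      stop_hf(sprintf("input file not found: %s", p), "hepaflux_config_error")
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("hepaflux")),
    seed = config$seed,
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    stages = list()
  )
  stage <- function(name, code) {
    res <- tryCatch({ force(code); list(status = "ok") },
                    error = function(e) list(status = "failed",
                                             error = conditionMessage(e)))
    manifest$stages[[name]] <<- res
    res$status == "ok"
  }
  out <- function(...) file.path(config$output_dir, ...)

  model <- NULL; expr <- NULL; labels <- NULL; degs <- NULL
  stage("load_model", { model <- read_model(config$model) })
  if (!is.null(config$expression)) {
    stage("load_expression", {
      expr <- read_expression_tsv(config$expression)
      labels <- if (!is.null(config$labels)) {
        lab <- utils::read.delim(config$labels, stringsAsFactors = FALSE)
        stats::setNames(lab$sex, lab$sample_id)
      } else {
        infer_sex(expr, config$marker_gene)
      }
      utils::write.table(
        data.frame(sample_id = names(labels), sex = unname(labels)),
        out("labels_used.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
      )
    })
  }
  if (!is.null(expr) && !is.null(model)) {
    stage("differential_expression", {
      degs <- differential_expression(expr, labels)
      utils::write.table(degs, out("degs.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    })
  } else if (!is.null(config$degs)) {
    stage("load_degs", { degs <- read_precomputed_degs(config$degs) })
  }
  if (!is.null(degs) && !is.null(model)) {
    stage("tides", {
      gw <- weights_from_degs(degs, config$fdr_threshold)
      tr <- run_tides(model, gw, n_permutations = config$n_permutations,
                      alpha = config$alpha,
                      min_reactions = config$min_reactions,
                      seed = config$seed)
      write_tides_tsv(tr, out("tides.tsv"))
    })
  }
  if (!is.null(expr) && !is.null(model)) {
    stage("context_models", {
      coh <- build_cohort(model, expr, labels,
                          biomass_fraction = config$biomass_fraction,
                          n_samples = config$n_flux_samples,
                          objective_fraction = config$objective_fraction,
                          seed = config$seed)
      utils::write.table(coh$retention, out("retention.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(coh$excluded, out("excluded_samples.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      sex <- vapply(coh$models, `[[`, character(1), "sex")
      if (any(sex == "male") && any(sex == "female")) {
        pt <- presence_table(coh$models[sex == "male"],
                             coh$models[sex == "female"])
        utils::write.table(as.data.frame(pt), out("presence.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        ur <- unique_reactions(pt, config$min_frac)
        utils::write.table(ur$subsystem_counts_A, out("unique_male_subsystems.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(ur$subsystem_counts_B, out("unique_female_subsystems.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    })
  }
  if (!is.null(config$aers_quarterly)) {
    stage("aers", {
      q <- quarterly_proportions(utils::read.csv(config$aers_quarterly,
                                                 stringsAsFactors = FALSE))
      cmp <- compare_sex_series(q$proportion[q$sex == "female"],
                                q$proportion[q$sex == "male"])
      res <- data.frame(U = cmp$U, p_two_sided = cmp$p_two_sided,
                        median_female = cmp$median_female,
                        median_male = cmp$median_male)
      utils::write.table(res, out("aers_sex_comparison.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      if (!is.null(config$aers_drugs)) {
        d <- drug_sex_fractions(utils::read.csv(config$aers_drugs,
                                                stringsAsFactors = FALSE))
        utils::write.table(d, out("drug_sex_fractions.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    })
  }
  manifest$outputs <- lapply(
    stats::setNames(nm = list.files(config$output_dir, pattern = "\\.tsv$")),
    function(f) unname(tools::md5sum(out(f)))
  )
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
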