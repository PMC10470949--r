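## In-memory representation of a (small) genome-scale metabolic model:
## metabolites, reactions with stoichiometry / bounds / GPR / subsystem,
## a gene list, and a biomass objective.  Deliberately plain lists and
## data frames, in the spirit of constraint-based modelling toolkits.

#' Construct a metabolic model
#'
#' @param id Model identifier.
#' @param metabolites Data frame with columns `id`, `name`,
#'   `compartment`.
#' @param reactions List of reactions as returned by [reaction()].
#' @param genes Character vector of gene ids; defaults to the union of
#'   genes referenced by the reactions' GPRs.
#' @param objective Reaction id of the biomass (objective) reaction.
#' @param validate Check model invariants (default `TRUE`).
#' @return Object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, genes = NULL,
                            objective, validate = TRUE) {
  stopifnot(is.data.frame(metabolites),
            all(c("id", "name", "compartment") %in% names(metabolites)))
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  if (is.null(genes)) {
    genes <- unique(unlist(lapply(reactions, function(r) gpr_genes(r$gpr))))
    if (is.null(genes)) genes <- character(0)
  }
  m <- structure(
    list(
      id = id,
      metabolites = metabolites,
      reactions = reactions,
      genes = genes,
      objective = objective
    ),
    class = "metabolic_model"
  )
  if (validate) validate_model(m)
  m
}

#' Construct a reaction
#'
#' @param id,name Identifiers.
#' @param stoichiometry Named numeric vector, metabolite id to signed
#'   coefficient (negative = consumed).
#' @param lb,ub Flux bounds (arbitrary units); `lb <= ub`.
#' @param gpr GPR rule string (parsed with [parse_gpr()]), a `gpr`
#'   object, or `NULL`.
#' @param subsystem Subsystem label or `NA`.
#' @return A list of class `model_reaction`.
#' @export
reaction <- function(id, name = id, stoichiometry, lb = 0, ub = 1000,
                     gpr = NULL, subsystem = NA_character_) {
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  structure(
    list(
      id = id, name = name,
      stoichiometry = stoichiometry,
      lb = as.numeric(lb), ub = as.numeric(ub),
      gpr = gpr,
      subsystem = subsystem
    ),
    class = "model_reaction"
  )
}

#' Validate model invariants
#'
#' Checks id uniqueness, bound ordering, resolvable metabolite and gene
#' references, and a resolvable objective.  Errors (class
#' `hepaflux_consistency_error`) on the first violation.
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  if (anyDuplicated(mets$id)) {
    stop_hf("duplicate metabolite ids", "hepaflux_consistency_error")
  }
  if (any(!nzchar(mets$compartment) | is.na(mets$compartment))) {
    stop_hf("metabolite with empty compartment", "hepaflux_consistency_error")
  }
  rids <- vapply(model$reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids)) {
    stop_hf("duplicate reaction ids", "hepaflux_consistency_error")
  }
  for (r in model$reactions) {
    if (r$lb > r$ub) {
      stop_hf(sprintf("reaction %s: lower bound exceeds upper bound", r$id),
              "hepaflux_consistency_error")
    }
    if (length(r$stoichiometry) == 0) {
      stop_hf(sprintf("reaction %s: empty stoichiometry", r$id),
              "hepaflux_consistency_error")
    }
    bad <- setdiff(names(r$stoichiometry), mets$id)
    if (length(bad)) {
      stop_hf(sprintf("reaction %s: unknown metabolite(s) %s",
                      r$id, paste(bad, collapse = ", ")),
              "hepaflux_consistency_error")
    }
    gg <- gpr_genes(r$gpr)
    missing_genes <- setdiff(gg, model$genes)
    if (length(missing_genes)) {
      stop_hf(sprintf("reaction %s: GPR references unknown gene(s) %s",
                      r$id, paste(missing_genes, collapse = ", ")),
              "hepaflux_consistency_error")
    }
  }
  if (!model$objective %in% rids) {
    stop_hf(sprintf("objective reaction '%s' not in model", model$objective),
            "hepaflux_consistency_error")
  }
  invisible(model)
}

#' Reaction ids of a model
#' @param model A `metabolic_model`.
#' @return Character vector.
#' @export
reaction_ids <- function(model) {
  vapply(model$reactions, `[[`, character(1), "id")
}

#' Subsystem labels of a model's reactions
#' @param model A `metabolic_model`.
#' @return Named character vector (reaction id -> subsystem, `NA` when
#'   unlabelled).
#' @export
subsystems <- function(model) {
  out <- vapply(model$reactions, function(r) {
    s <- r$subsystem
    if (is.null(s) || length(s) == 0) NA_character_ else as.character(s)
  }, character(1))
  names(out) <- reaction_ids(model)
  out
}

#' Stoichiometric matrix of a model
#'
#' @param model A `metabolic_model`.
#' @return Dense numeric matrix, one row per metabolite, one column per
#'   reaction, with dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  mids <- model$metabolites$id
  rids <- reaction_ids(model)
  S <- matrix(0, nrow = length(mids), ncol = length(rids),
              dimnames = list(mids, rids))
  for (r in model$reactions) {
    S[names(r$stoichiometry), r$id] <- r$stoichiometry
  }
  S
}

#' Flux bounds of a model
#' @param model A `metabolic_model`.
#' @return List with numeric vectors `lb` and `ub`, named by reaction id.
#' @export
flux_bounds <- function(model) {
  rids <- reaction_ids(model)
  lb <- vapply(model$reactions, `[[`, numeric(1), "lb")
  ub <- vapply(model$reactions, `[[`, numeric(1), "ub")
  names(lb) <- names(ub) <- rids
  list(lb = lb, ub = ub)
}

#' Restrict a model to a subset of reactions
#'
#' Drops all other reactions, then removes orphaned metabolites and
#' genes.  The objective is retained if present in `keep`.
#'
#' @param model A `metabolic_model`.
#' @param keep Character vector of reaction ids to keep.
#' @return A `metabolic_model`.
#' @export
subset_model <- function(model, keep) {
  keep <- intersect(reaction_ids(model), keep)
  rxns <- model$reactions[keep]
  used_mets <- unique(unlist(lapply(rxns, function(r) names(r$stoichiometry))))
  mets <- model$metabolites[model$metabolites$id %in% used_mets, , drop = FALSE]
  used_genes <- unique(unlist(lapply(rxns, function(r) gpr_genes(r$gpr))))
  if (is.null(used_genes)) used_genes <- character(0)
  obj <- if (model$objective %in% keep) model$objective else keep[[1]]
  metabolic_model(
    id = paste0(model$id, "_sub"),
    metabolites = mets, reactions = rxns,
    genes = used_genes, objective = obj, validate = FALSE
  )
}

#' Set flux bounds on selected reactions
#'
#' Convenience for knockouts and media changes; returns the modified
#' model (models are plain values, never mutated in place).
#'
#' @param model A `metabolic_model`.
#' @param rids Reaction ids to change.
#' @param lb,ub New bounds (either may be `NULL` to leave unchanged).
#' @return The modified `metabolic_model`.
#' @export
set_bounds <- function(model, rids, lb = NULL, ub = NULL) {
  for (rid in rids) {
    if (!is.null(lb)) model$reactions[[rid]]$lb <- lb
    if (!is.null(ub)) model$reactions[[rid]]$ub <- ub
  }
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  subs <- subsystems(x)
  cat(sprintf(
    "<metabolic_model> %s: %d metabolites, %d reactions, %d genes, %d subsystems (objective: %s)\n",
    x$id, nrow(x$metabolites), length(x$reactions), length(x$genes),
    length(unique(subs[!is.na(subs)])), x$objective
  ))
  invisible(x)
}

## Structural equality of two models (used by round-trip tests):
## identical reaction sets, bounds, stoichiometries, GPR trees and
## subsystem labels.
models_equal <- function(a, b, tol = 1e-9) {
  ra <- sort(reaction_ids(a)); rb <- sort(reaction_ids(b))
  if (!identical(ra, rb)) return(FALSE)
  if (!setequal(a$metabolites$id, b$metabolites$id)) return(FALSE)
  if (!setequal(a$genes, b$genes)) return(FALSE)
  if (!identical(a$objective, b$objective)) return(FALSE)
  for (rid in ra) {
    x <- a$reactions[[rid]]; y <- b$reactions[[rid]]
    if (abs(x$lb - y$lb) > tol || abs(x$ub - y$ub) > tol) return(FALSE)
    sx <- x$stoichiometry[order(names(x$stoichiometry))]
    sy <- y$stoichiometry[order(names(y$stoichiometry))]
    if (!identical(names(sx), names(sy)) || any(abs(sx - sy) > tol)) return(FALSE)
    if (!identical(gpr_to_string(x$gpr), gpr_to_string(y$gpr))) return(FALSE)
    sub_x <- if (is.null(x$subsystem)) NA_character_ else x$subsystem
    sub_y <- if (is.null(y$subsystem)) NA_character_ else y$subsystem
    if (!identical(is.na(sub_x), is.na(sub_y))) return(FALSE)
    if (!is.na(sub_x) && !identical(sub_x, sub_y)) return(FALSE)
  }
  TRUE
}
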