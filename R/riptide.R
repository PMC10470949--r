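## Transcript-guided context-specific model extraction (RIPTiDe-style):
## linear abundance-to-weight mapping, weighted flux-sum minimisation
## with a biomass floor, pruning of zero-flux reactions, inverse-weight
## maximisation, and constrained flux sampling of the kept model.

#' Linear transcript weights for a model's reactions
#'
#' Resolves each reaction's abundance through its GPR (OR = max,
#' AND = min over gene abundances, genes absent from the data skipped)
#' and maps abundances linearly to weights in `[0, 1]`: the
#' highest-abundance reaction gets weight 0, the lowest weight 1.
#' Reactions without a resolvable abundance (no GPR or no matched
#' genes) get `default_weight`.
#'
#' @param model A `metabolic_model`.
#' @param abundances Named nonnegative numeric vector (gene id ->
#'   transcript abundance, linear scale).
#' @param default_weight Weight for unresolvable reactions (default
#'   0.5, neutral).
#' @return Named numeric vector over all reactions with attribute
#'   `resolved` (logical vector: abundance resolvable).
#' @export
transcript_weights <- function(model, abundances, default_weight = 0.5) {
  rids <- reaction_ids(model)
  if (!any(names(abundances) %in% model$genes)) {
    stop_hf("no model gene found in the abundance vector", "hepaflux_config_error")
  }
  ab <- vapply(model$reactions, function(r) {
    if (is.null(r$gpr)) NA_real_ else evaluate_gpr(r$gpr, abundances, missing = "skip")
  }, numeric(1))
  names(ab) <- rids
  resolved <- !is.na(ab)
  w <- rep(default_weight, length(rids))
  names(w) <- rids
  if (any(resolved)) {
    rng <- range(ab[resolved])
    if (rng[2] - rng[1] <= 0) {
      warning("all resolvable reaction abundances are equal; assigning weight 0.5")
      w[resolved] <- 0.5
    } else {
      w[resolved] <- 1 - (ab[resolved] - rng[1]) / (rng[2] - rng[1])
    }
  }
  attr(w, "resolved") <- resolved
  attr(w, "abundance") <- ab
  w
}

#' Prune a model to its transcript-consistent parsimonious core
#'
#' Minimises the transcript-weighted flux sum subject to biomass at
#' least `biomass_fraction` of the base model's maximum, then removes
#' every reaction whose optimal flux magnitude is at most `flux_tol`
#' (orphaned metabolites and genes are dropped with them).  The kept
#' submodel is re-verified to reach the same biomass floor.
#'
#' @param model A `metabolic_model`.
#' @param weights Named weights from [transcript_weights()].
#' @param biomass_fraction Biomass floor as a fraction of the base
#'   maximum (default 0.4).
#' @param flux_tol Pruning tolerance (default 1e-6).
#' @param base_max Optional maximal biomass of the reference base
#'   model; defaults to this model's own maximum.  Supplying the
#'   unmodified base model's maximum makes the floor meaningful for
#'   models whose zero-abundance reactions were closed beforehand.
#' @return A `context_model`: list with `base_model_id`, `model` (the
#'   kept submodel), `kept_reactions`, `pruned_reactions`,
#'   `pruning_fluxes` (the minimising flux vector), `weights`,
#'   `biomass_fraction_used`, `base_max_biomass`, `feasible_at_040`,
#'   `subsystems` (reaction -> subsystem map of the kept model), and
#'   `flux_samples` (`NULL` until [contextual_sample()] is run).
#' @export
prune <- function(model, weights, biomass_fraction = 0.4, flux_tol = 1e-6,
                  base_max = NULL) {
  base_max <- base_max %||% fba(model)$objective_value
  v <- tryCatch(
    minimize_weighted_flux(model, weights, biomass_fraction,
                           default_weight = 0.5,
                           biomass_min = biomass_fraction * base_max),
    hepaflux_infeasible_error = function(e) {
      stop_hf(
        sprintf("pruning LP infeasible at biomass fraction %.3f", biomass_fraction),
        "hepaflux_infeasible_error", biomass_fraction = biomass_fraction
      )
    }
  )
  kept <- names(v)[abs(v) > flux_tol]
  pruned <- setdiff(names(v), kept)
  sub <- subset_model(model, kept)
  kept_max <- fba(sub)$objective_value
  if (kept_max < biomass_fraction * base_max - 1e-6) {
    stop_hf("pruned model lost the biomass floor (numerical inconsistency)",
            "hepaflux_lp_error")
  }
  structure(
    list(
      base_model_id = model$id,
      model = sub,
      kept_reactions = kept,
      pruned_reactions = pruned,
      pruning_fluxes = v[kept],
      weights = weights[kept],
      biomass_fraction_used = biomass_fraction,
      base_max_biomass = base_max,
      kept_max_biomass = kept_max,
      feasible_at_040 = kept_max >= 0.4 * base_max - 1e-6,
      subsystems = subsystems(sub),
      flux_samples = NULL
    ),
    class = "context_model"
  )
}

#' @export
print.context_model <- function(x, ...) {
  cat(sprintf(
    "<context_model> base %s: kept %d / pruned %d reactions, biomass floor %.2f x max (40%% filter: %s)\n",
    x$base_model_id, length(x$kept_reactions), length(x$pruned_reactions),
    x$biomass_fraction_used, if (x$feasible_at_040) "pass" else "FAIL"
  ))
  invisible(x)
}

#' Constrained flux sampling of a context model
#'
#' Re-weights the kept reactions inversely (`w' = 1 - w`, so the
#' highest-abundance reaction now has the largest weight), maximises
#' the weighted flux sum within the flux-direction orthant of the
#' pruning solution, constrains the sampled polytope to retain at least
#' `objective_fraction` of that maximum (plus the biomass floor), and
#' draws `n` hit-and-run samples.  Fixing the orthant keeps
#' `sum w'|v|` linear, so every sample verifiably satisfies the
#' weighted-flux constraint on its net fluxes.
#'
#' @param context A `context_model` from [prune()].
#' @param n Number of samples (default 110).
#' @param objective_fraction Fraction of the maximal weighted flux sum
#'   retained during sampling (default 0.8).
#' @param seed Integer seed.
#' @return The `context_model` with `flux_samples` set to a
#'   `flux_sample_set` (also attached attribute `weighted_flux_max`).
#' @export
contextual_sample <- function(context, n = 110, objective_fraction = 0.8,
                              seed = 1) {
  stopifnot(inherits(context, "context_model"),
            objective_fraction >= 0, objective_fraction <= 1)
  sub <- context$model
  rids <- reaction_ids(sub)
  w_inv <- 1 - pmin(pmax(context$weights[rids], 0), 1)
  names(w_inv) <- rids
  orthant <- ifelse(context$pruning_fluxes[rids] >= 0, 1, -1)
  names(orthant) <- rids
  bm_min <- context$biomass_fraction_used * context$base_max_biomass
  ## orthant-restricted bounds (biomass floor is a fraction of the BASE max)
  bb <- flux_bounds(sub)
  lb <- ifelse(orthant > 0, pmax(bb$lb, 0), bb$lb)
  ub <- ifelse(orthant > 0, bb$ub, pmin(bb$ub, 0))
  names(lb) <- names(ub) <- rids
  constraints <- list(
    flux_constraint(stats::setNames(1, sub$objective), ">=", bm_min)
  )
  mx <- orthant_lp(sub, obj_w = w_inv, orthant = orthant, biomass_min = bm_min,
                   maximize = TRUE)
  z_star <- mx$value
  if (z_star > 1e-9) {
    constraints <- c(constraints, list(
      flux_constraint(w_inv * orthant, ">=", objective_fraction * z_star)
    ))
  }
  fs <- flux_sample(sub, constraints = constraints, n = n, seed = seed,
                    lb = lb, ub = ub)
  attr(fs, "weighted_flux_max") <- z_star
  attr(fs, "objective_fraction") <- objective_fraction
  context$flux_samples <- fs
  context
}

## GPR-resolved reaction abundances equal to zero close the reaction
## (absent-transcript call) -- the mechanism by which a sample can fail
## the biomass floor.
close_zero_abundance <- function(model, abundances) {
  for (r in model$reactions) {
    if (is.null(r$gpr)) next
    a <- evaluate_gpr(r$gpr, abundances, missing = "skip")
    if (!is.na(a) && a <= 0) {
      model <- set_bounds(model, r$id, lb = 0, ub = 0)
    }
  }
  model
}

#' Build a cohort of per-sample context models
#'
#' For every labelled sample, maps its expression column to gene
#' abundances, optionally closes reactions whose GPR-resolved abundance
#' is exactly zero (`close_zero`), computes transcript weights, prunes
#' at the biomass floor, and (optionally) draws constrained flux
#' samples.  Samples whose pruning problem is infeasible at the floor
#' are excluded and reported, mirroring the retention filter that keeps
#' only models reaching at least 40% of the original maximum biomass
#' flux.
#'
#' @param model Base `metabolic_model`.
#' @param expr Gene-by-sample abundance matrix (linear scale).
#' @param labels Named sex labels (`"male"` / `"female"` retained).
#' @param biomass_fraction Biomass floor (default 0.4).
#' @param n_samples Flux samples per context model (default 110).
#' @param objective_fraction Sampling-stage weighted-flux fraction
#'   (default 0.8).
#' @param seed Master seed; per-sample seeds are derived from it.
#' @param sample_fluxes Draw flux samples per model (default `TRUE`).
#' @param close_zero Close zero-abundance reactions before pruning
#'   (default `TRUE`).
#' @return List with `models` (named list of `context_model`),
#'   `excluded` (data frame `sample_id`, `sex`, `reason`), and
#'   `retention` (data frame `sex`, `n_input`, `n_retained`).
#' @export
build_cohort <- function(model, expr, labels, biomass_fraction = 0.4,
                         n_samples = 110, objective_fraction = 0.8, seed = 1,
                         sample_fluxes = TRUE, close_zero = TRUE) {
  labels <- labels[intersect(names(labels), colnames(expr))]
  use <- names(labels)[labels %in% c("male", "female")]
  base_max <- fba(model)$objective_value
  models <- list()
  excluded <- data.frame(sample_id = character(0), sex = character(0),
                         reason = character(0), stringsAsFactors = FALSE)
  for (i in seq_along(use)) {
    sid <- use[i]
    ab <- expr[, sid]
    names(ab) <- rownames(expr)
    m_i <- if (close_zero) close_zero_abundance(model, ab) else model
    ctx <- tryCatch({
      w <- transcript_weights(m_i, ab)
      ctx <- prune(m_i, w, biomass_fraction, base_max = base_max)
      if (sample_fluxes) {
        ctx <- contextual_sample(ctx, n = n_samples,
                                 objective_fraction = objective_fraction,
                                 seed = derive_seed(seed, i))
      }
      ctx
    }, hepaflux_infeasible_error = function(e) {
      conditionMessage(e)
    })
    if (is.character(ctx)) {
      excluded <- rbind(excluded, data.frame(
        sample_id = sid, sex = unname(labels[sid]), reason = ctx,
        stringsAsFactors = FALSE
      ))
    } else {
      ctx$sample_id <- sid
      ctx$sex <- unname(labels[sid])
      models[[sid]] <- ctx
    }
  }
  retained_sex <- vapply(models, `[[`, character(1), "sex")
  retention <- do.call(rbind, lapply(c("male", "female"), function(s) {
    data.frame(sex = s,
               n_input = sum(labels[use] == s),
               n_retained = sum(retained_sex == s),
               stringsAsFactors = FALSE)
  }))
  list(models = models, excluded = excluded, retention = retention)
}

#' Group-averaged context model
#'
#' Averages gene abundances (arithmetic mean on the linear scale)
#' across a sex group's samples, then runs the transcript-weighting,
#' pruning and constrained-sampling pipeline once on the averaged
#' profile.
#'
#' @inheritParams build_cohort
#' @param group `"male"` or `"female"`.
#' @param sample_fluxes Draw flux samples (default `TRUE`).
#' @return A `context_model` (with `group` field set).
#' @export
averaged_model <- function(model, expr, labels, group = c("male", "female"),
                           biomass_fraction = 0.4, n_samples = 110,
                           objective_fraction = 0.8, seed = 1,
                           sample_fluxes = TRUE, close_zero = TRUE) {
  group <- match.arg(group)
  labels <- labels[intersect(names(labels), colnames(expr))]
  ids <- names(labels)[labels == group]
  if (length(ids) == 0) {
    stop_hf(sprintf("no samples labelled '%s'", group), "hepaflux_config_error")
  }
  ab <- rowMeans(expr[, ids, drop = FALSE])
  names(ab) <- rownames(expr)
  base_max <- fba(model)$objective_value
  m_g <- if (close_zero) close_zero_abundance(model, ab) else model
  w <- transcript_weights(m_g, ab)
  ctx <- prune(m_g, w, biomass_fraction, base_max = base_max)
  if (sample_fluxes) {
    ctx <- contextual_sample(ctx, n = n_samples,
                             objective_fraction = objective_fraction,
                             seed = seed)
  }
  ctx$group <- group
  ctx
}

#' Write a context-model manifest as JSON
#'
#' @param context A `context_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_context_manifest <- function(context, path) {
  obj <- list(
    base_model_id = context$base_model_id,
    kept_reactions = context$kept_reactions,
    pruned_reactions = context$pruned_reactions,
    biomass_fraction_used = context$biomass_fraction_used,
    base_max_biomass = context$base_max_biomass,
    kept_max_biomass = context$kept_max_biomass,
    feasible_at_040 = context$feasible_at_040
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
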