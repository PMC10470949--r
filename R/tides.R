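## Subsystem scoring from differential expression (TIDEs-style):
## gene weights are projected onto reactions through the GPR rules
## (OR = max, AND = min), averaged per subsystem, and tested against an
## empirical null built from out-of-subsystem reaction weights.

#' Project gene weights onto reactions through GPR rules
#'
#' Each reaction with a GPR is assigned the GPR-resolved value of its
#' genes' weights: isozymes (OR) contribute their highest fold
#' difference, complexes (AND) their lowest.  Reactions without a GPR,
#' or none of whose genes appear in `gene_weights`, are omitted.
#'
#' @param model A `metabolic_model`.
#' @param gene_weights Named numeric vector (gene id -> log2 fold
#'   change, 0 for non-significant genes).
#' @return Named numeric vector over the resolvable reactions.
#' @export
reaction_weights <- function(model, gene_weights) {
  out <- numeric(0)
  for (r in model$reactions) {
    if (is.null(r$gpr)) next
    v <- evaluate_gpr(r$gpr, gene_weights, missing = "skip")
    if (!is.na(v)) out[r$id] <- v
  }
  out
}

#' Mean reaction weight of a subsystem
#'
#' @param rxn_weights Named numeric vector from [reaction_weights()].
#' @param member_reactions Character vector of the subsystem's reaction
#'   ids.
#' @param min_reactions Minimum number of weighted members required
#'   (default 3); fewer raises a skip condition
#'   (`hepaflux_skip_subsystem`).
#' @return Numeric scalar: the subsystem score.
#' @export
subsystem_score <- function(rxn_weights, member_reactions, min_reactions = 3) {
  members <- intersect(member_reactions, names(rxn_weights))
  if (length(members) < min_reactions) {
    stop_hf(
      sprintf("subsystem has %d weighted reaction(s), need >= %d",
              length(members), min_reactions),
      "hepaflux_skip_subsystem", n_weighted = length(members)
    )
  }
  mean(rxn_weights[members])
}

#' Permutation null for a subsystem score
#'
#' Draws `n_permutations` null scores, each the mean of `k` reaction
#' weights sampled uniformly with replacement from reactions outside
#' the subsystem, where `k` is the subsystem's weighted-member count.
#'
#' @inheritParams subsystem_score
#' @param n_permutations Number of null draws (default 1000).
#' @param seed Integer seed.
#' @return Numeric vector of length `n_permutations`.
#' @export
permutation_null <- function(rxn_weights, member_reactions,
                             n_permutations = 1000, seed = 1) {
  members <- intersect(member_reactions, names(rxn_weights))
  k <- length(members)
  pool <- rxn_weights[setdiff(names(rxn_weights), member_reactions)]
  if (length(pool) == 0) {
    stop_hf("no out-of-subsystem reaction weights to draw the null from",
            "hepaflux_degenerate_null_error")
  }
  with_seed(seed, {
    draws <- matrix(sample(pool, k * n_permutations, replace = TRUE),
                    nrow = k, ncol = n_permutations)
    colMeans(draws)
  })
}

#' Two-sided empirical test of a subsystem score
#'
#' One-tail empirical p-values use the add-one correction
#' `(1 + #{null >= score}) / (n + 1)` (ties count toward the extreme
#' tail); the two-sided p is `min(1, 2 * min(tails))`.  The direction
#' is the sign of the extreme tail when that tail's p is below `alpha`,
#' else `"none"`.
#'
#' @param score Observed subsystem score.
#' @param null_scores Numeric vector of permutation scores.
#' @param alpha Per-tail significance level (default 0.025, i.e. 0.05
#'   two-sided).
#' @return List with `p_two_sided`, `direction` (`"positive"`,
#'   `"negative"` or `"none"`; positive = biased toward group A of the
#'   contrast), and the one-tail p-values `p_pos`, `p_neg`.
#' @export
tides_test <- function(score, null_scores, alpha = 0.025) {
  stopifnot(length(null_scores) >= 1)
  n <- length(null_scores)
  p_pos <- (1 + sum(null_scores >= score)) / (n + 1)
  p_neg <- (1 + sum(null_scores <= score)) / (n + 1)
  p_two <- min(1, 2 * min(p_pos, p_neg))
  direction <- if (min(p_pos, p_neg) < alpha) {
    if (p_pos <= p_neg) "positive" else "negative"
  } else "none"
  list(p_two_sided = p_two, direction = direction, p_pos = p_pos, p_neg = p_neg)
}

#' Score every subsystem of a model against a permutation null
#'
#' Runs [reaction_weights()], then for each subsystem with at least
#' `min_reactions` weighted members computes the score, its permutation
#' null, and the two-sided empirical test.  Subsystems with fewer
#' weighted members are reported with `skipped = TRUE` rather than
#' silently dropped.
#'
#' @param model A `metabolic_model` with subsystem labels.
#' @param gene_weights Named numeric vector of gene weights.
#' @param n_permutations Null draws per subsystem (default 1000).
#' @param alpha Per-tail significance level (default 0.025).
#' @param min_reactions Minimum weighted members (default 3).
#' @param seed Master seed; per-subsystem seeds are derived from it.
#' @param adjust `"none"` (default; raw empirical p as in the
#'   two-sided 0.025 rule) or `"BH"` to add a `fdr` column across
#'   subsystems.
#' @return Data frame (`tides_result`) with one row per subsystem:
#'   `subsystem`, `n_reactions` (weighted members), `score`,
#'   `p_two_sided`, `direction`, `skipped`, `n_permutations`, `seed`,
#'   plus `fdr` when `adjust = "BH"`.  The per-subsystem null draws are
#'   attached as the `null_scores` attribute (a named list).
#' @export
run_tides <- function(model, gene_weights, n_permutations = 1000,
                      alpha = 0.025, min_reactions = 3, seed = 1,
                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  subs <- subsystems(model)
  if (all(is.na(subs))) {
    stop_hf("model has no subsystem labels", "hepaflux_config_error")
  }
  rw <- reaction_weights(model, gene_weights)
  sub_names <- sort(unique(subs[!is.na(subs)]))
  rows <- list()
  nulls <- list()
  for (i in seq_along(sub_names)) {
    sname <- sub_names[i]
    members <- names(subs)[!is.na(subs) & subs == sname]
    k <- length(intersect(members, names(rw)))
    sub_seed <- derive_seed(seed, i)
    if (k < min_reactions) {
      rows[[i]] <- data.frame(
        subsystem = sname, n_reactions = k, score = NA_real_,
        p_two_sided = NA_real_, direction = NA_character_, skipped = TRUE,
        n_permutations = n_permutations, seed = sub_seed,
        stringsAsFactors = FALSE
      )
      next
    }
    score <- subsystem_score(rw, members, min_reactions)
    ns <- permutation_null(rw, members, n_permutations, seed = sub_seed)
    tt <- tides_test(score, ns, alpha)
    nulls[[sname]] <- ns
    rows[[i]] <- data.frame(
      subsystem = sname, n_reactions = k, score = score,
      p_two_sided = tt$p_two_sided, direction = tt$direction, skipped = FALSE,
      n_permutations = n_permutations, seed = sub_seed,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust == "BH") {
    out$fdr <- NA_real_
    ok <- !out$skipped
    out$fdr[ok] <- stats::p.adjust(out$p_two_sided[ok], method = "BH")
  }
  attr(out, "null_scores") <- nulls
  class(out) <- c("tides_result", "data.frame")
  out
}

#' Write a TIDEs result table as TSV
#'
#' @param result A `tides_result` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tides_tsv <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
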