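## Cohort comparison of context models: per-group reaction-presence
## fractions, presence histograms, strict uniqueness calls with
## subsystem tallies, and per-reaction flux contrasts.

#' Reaction-presence fractions across two cohorts of context models
#'
#' For every reaction kept by at least one model, computes the fraction
#' of each group's models containing it (number of models with the
#' reaction divided by the group size).
#'
#' @param models_A,models_B Lists of `context_model` objects.
#' @return Data frame (`presence_table`) with columns `reaction_id`,
#'   `subsystem`, `frac_A`, `frac_B`; attributes `n_A`, `n_B`.
#' @export
presence_table <- function(models_A, models_B) {
  if (length(models_A) == 0 || length(models_B) == 0) {
    stop_hf("both cohorts must be non-empty", "hepaflux_config_error")
  }
  kept_A <- lapply(models_A, `[[`, "kept_reactions")
  kept_B <- lapply(models_B, `[[`, "kept_reactions")
  all_rxns <- sort(unique(c(unlist(kept_A), unlist(kept_B))))
  count_in <- function(kept_list) {
    tab <- table(unlist(kept_list))
    out <- stats::setNames(rep(0, length(all_rxns)), all_rxns)
    out[names(tab)] <- as.numeric(tab)
    out
  }
  frac_A <- count_in(kept_A) / length(models_A)
  frac_B <- count_in(kept_B) / length(models_B)
  subs <- character(0)
  for (m in c(models_A, models_B)) subs[names(m$subsystems)] <- m$subsystems
  out <- data.frame(
    reaction_id = all_rxns,
    subsystem = unname(subs[all_rxns]),
    frac_A = unname(frac_A),
    frac_B = unname(frac_B),
    stringsAsFactors = FALSE
  )
  attr(out, "n_A") <- length(models_A)
  attr(out, "n_B") <- length(models_B)
  class(out) <- c("presence_table", "data.frame")
  out
}

#' Histogram of presence fractions within one group
#'
#' Bins the nonzero presence fractions of one group into `bins` equal
#' intervals of `(0, 1]`; with the default 10 bins the edges are
#' `[0, 0.1), ..., [0.9, 1.0]` and a fraction of exactly 1 falls in the
#' top bin.  Reactions absent from the group (fraction 0) are excluded.
#'
#' @param table A `presence_table`.
#' @param group `"A"` or `"B"`.
#' @param bins Number of bins (default 10).
#' @return Named integer vector of bin counts.
#' @export
presence_histogram <- function(table, group = c("A", "B"), bins = 10) {
  group <- match.arg(group)
  f <- table[[paste0("frac_", group)]]
  f <- f[f > 0]
  ## left-closed bins; computed directly to keep boundary fractions
  ## (k/n landing exactly on an edge) in their upper bin
  idx <- pmin(floor(f * bins) + 1L, bins)
  counts <- tabulate(idx, nbins = bins)
  edges <- seq_len(bins + 1) - 1
  names(counts) <- sprintf("[%.1f,%.1f%s", edges[-(bins + 1)] / bins,
                           edges[-1] / bins,
                           c(rep(")", bins - 1), "]"))
  counts
}

#' Sex-unique reactions and their subsystem tallies
#'
#' A reaction is unique to a group when its presence fraction is at
#' least `min_frac` there and exactly 0 in the other group (strict
#' absence).  Subsystem tallies count each group's unique reactions per
#' subsystem, sorted descending.
#'
#' @param table A `presence_table`.
#' @param min_frac Minimum in-group presence (default 0.1).
#' @return List with `unique_A`, `unique_B` (character vectors),
#'   `subsystem_counts_A`, `subsystem_counts_B` (data frames
#'   `subsystem`, `count`, sorted descending), and `min_frac`.
#' @export
unique_reactions <- function(table, min_frac = 0.1) {
  uA <- table$reaction_id[table$frac_A >= min_frac & table$frac_B == 0]
  uB <- table$reaction_id[table$frac_B >= min_frac & table$frac_A == 0]
  tally <- function(rids) {
    if (length(rids) == 0) {
      return(data.frame(subsystem = character(0), count = integer(0),
                        stringsAsFactors = FALSE))
    }
    subs <- table$subsystem[match(rids, table$reaction_id)]
    subs[is.na(subs)] <- "(unlabelled)"
    tab <- sort(table(subs), decreasing = TRUE)
    data.frame(subsystem = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
  }
  list(
    unique_A = uA, unique_B = uB,
    subsystem_counts_A = tally(uA), subsystem_counts_B = tally(uB),
    min_frac = min_frac
  )
}

#' Mann-Whitney U test (two-sided)
#'
#' Wraps [stats::wilcox.test()]: exact null when both samples are
#' untied and the smaller has at most 20 observations, tie-corrected
#' normal approximation otherwise.  Degenerate input (all values
#' identical) returns `p = 1`.
#'
#' @param x,y Numeric vectors.
#' @return List with `U` (the U statistic of `x`), `p_two_sided`, and
#'   `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (max(c(x, y)) - min(c(x, y)) == 0) {
    return(list(U = length(x) * length(y) / 2, p_two_sided = 1,
                method = "degenerate"))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && min(length(x), length(y)) <= 20
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = !exact)
  )
  list(U = unname(wt$statistic), p_two_sided = wt$p.value,
       method = if (exact) "exact" else "normal")
}

#' Per-reaction flux contrast between two sample sets
#'
#' Compares one reaction's flux distribution between two
#' `flux_sample_set`s with a two-sided Mann-Whitney U test.  A reaction
#' present in only one set is reported as structurally different (no
#' test); absent from both raises an error.
#'
#' @param samples_A,samples_B `flux_sample_set` objects.
#' @param reaction_id Reaction to contrast.
#' @return List with `reaction_id`, `structural` (logical), `U`,
#'   `p_two_sided`, `median_A`, `median_B` (medians `NA` where the
#'   reaction is absent).
#' @export
flux_contrast <- function(samples_A, samples_B, reaction_id) {
  in_A <- reaction_id %in% samples_A$reaction_ids
  in_B <- reaction_id %in% samples_B$reaction_ids
  if (!in_A && !in_B) {
    stop_hf(sprintf("reaction '%s' absent from both sample sets", reaction_id),
            "hepaflux_missing_reaction_error")
  }
  if (!in_A || !in_B) {
    return(list(
      reaction_id = reaction_id, structural = TRUE, U = NA_real_,
      p_two_sided = NA_real_,
      median_A = if (in_A) stats::median(samples_A$samples[, reaction_id]) else NA_real_,
      median_B = if (in_B) stats::median(samples_B$samples[, reaction_id]) else NA_real_
    ))
  }
  a <- samples_A$samples[, reaction_id]
  b <- samples_B$samples[, reaction_id]
  mw <- mann_whitney_u(a, b)
  list(
    reaction_id = reaction_id, structural = FALSE, U = mw$U,
    p_two_sided = mw$p_two_sided,
    median_A = stats::median(a), median_B = stats::median(b)
  )
}
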