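## Sex-stratified adverse-event report analysis: quarterly liver-report
## proportions, between-sex Mann-Whitney comparison of the quarterly
## series, and per-drug female report fractions for high-volume drugs.

#' Quarterly liver-report proportions by sex
#'
#' @param data Data frame with columns `quarter` (e.g. `"2004Q1"`),
#'   `sex` (`"male"` / `"female"`), `liver_reports`, `total_reports`
#'   (one row per quarter-sex pair).
#' @return The input with an added `proportion` column
#'   (`liver_reports / total_reports`).
#' @export
quarterly_proportions <- function(data) {
  required <- c("quarter", "sex", "liver_reports", "total_reports")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop_hf(sprintf("quarterly table missing column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "hepaflux_format_error")
  }
  if (anyDuplicated(data[, c("quarter", "sex")])) {
    stop_hf("duplicate (quarter, sex) rows", "hepaflux_format_error")
  }
  bad <- which(data$total_reports <= 0)
  if (length(bad)) {
    stop_hf(sprintf("total_reports must be positive (row %d)", bad[1]),
            "hepaflux_format_error")
  }
  if (any(data$liver_reports < 0 | data$liver_reports > data$total_reports)) {
    stop_hf("liver_reports must lie in [0, total_reports]", "hepaflux_format_error")
  }
  data$proportion <- data$liver_reports / data$total_reports
  data
}

#' Compare two quarterly proportion series between the sexes
#'
#' Treats the per-quarter proportions of each sex as two samples and
#' applies a two-sided Mann-Whitney U test ([mann_whitney_u()]).
#'
#' @param props_female,props_male Numeric vectors of per-quarter
#'   proportions (length at least 2 each).
#' @return List with `U`, `p_two_sided`, `median_female`,
#'   `median_male`, `method`.
#' @export
compare_sex_series <- function(props_female, props_male) {
  if (length(props_female) < 2 || length(props_male) < 2) {
    stop_hf("both series need length >= 2", "hepaflux_format_error")
  }
  mw <- mann_whitney_u(props_female, props_male)
  list(
    U = mw$U, p_two_sided = mw$p_two_sided,
    median_female = stats::median(props_female),
    median_male = stats::median(props_male),
    method = mw$method
  )
}

#' Female report fractions for high-volume drugs
#'
#' Keeps drugs whose combined report count is strictly greater than
#' `min_total` (robustness filter against small-sample artefacts) and
#' computes each drug's female report fraction, sorted ascending by
#' fraction.
#'
#' @param data Data frame with columns `drug`, `female_reports`,
#'   `male_reports`.
#' @param min_total Minimum combined reports, strict (default 100000).
#' @return Data frame `drug`, `total`, `female_fraction`, sorted by
#'   fraction.
#' @export
drug_sex_fractions <- function(data, min_total = 100000) {
  required <- c("drug", "female_reports", "male_reports")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop_hf(sprintf("drug table missing column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "hepaflux_format_error")
  }
  if (any(data$female_reports < 0 | data$male_reports < 0)) {
    stop_hf("report counts must be nonnegative", "hepaflux_format_error")
  }
  total <- data$female_reports + data$male_reports
  keep <- total > min_total
  out <- data.frame(
    drug = data$drug[keep],
    total = total[keep],
    female_fraction = data$female_reports[keep] / total[keep],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$female_fraction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Liver-related adverse-event term list
#'
#' The report labels treated as liver-related when preprocessing raw
#' adverse-event dumps into quarterly counts.
#'
#' @return Character vector of terms.
#' @export
liver_event_terms <- function() {
  c(
    "drug-induced liver injury",
    "hepatotoxicity",
    "hepatic enzyme increased",
    "hepatic and hepatobiliary disorders nec",
    "liver function analyses",
    "hepatic and hepatobiliary disorders",
    "hepatic failure and associated disorders",
    "hepatic enzymes and function abnormalities"
  )
}

#' Parse and validate quarter labels
#'
#' @param quarters Character vector like `"2004Q1"`.
#' @param validate_range Require quarters within 2004Q1-2021Q3
#'   (default `FALSE`).
#' @return Data frame `quarter`, `year`, `q` (integer quarter index).
#' @export
parse_quarters <- function(quarters, validate_range = FALSE) {
  m <- regmatches(quarters, regexec("^([0-9]{4})Q([1-4])$", quarters))
  bad <- which(vapply(m, length, integer(1)) != 3)
  if (length(bad)) {
    stop_hf(sprintf("malformed quarter label '%s' (expected YYYYQn)",
                    quarters[bad[1]]),
            "hepaflux_format_error")
  }
  year <- as.integer(vapply(m, `[`, character(1), 2))
  q <- as.integer(vapply(m, `[`, character(1), 3))
  if (validate_range) {
    idx <- year * 4 + q
    if (any(idx < 2004 * 4 + 1 | idx > 2021 * 4 + 3)) {
      stop_hf("quarter outside 2004Q1-2021Q3", "hepaflux_format_error")
    }
  }
  data.frame(quarter = quarters, year = year, q = q, stringsAsFactors = FALSE)
}
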