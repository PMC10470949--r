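## Expression handling: marker-based sex inference, Welch-t differential
## expression with Benjamini-Hochberg correction, and the thresholded
## gene weight map consumed by the subsystem scoring stage.

#' Infer sample sex from a male-specific marker gene
#'
#' Samples whose marker abundance is at or above the `1 - quantile`
#' empirical quantile are called male; at or below the `quantile`
#' quantile, female; the remainder unassigned.  Quantiles use linear
#' interpolation (type 7).  With the default `quantile = 0.16` the two
#' cutoffs approximate one standard deviation above and below the mean
#' for roughly normal marker distributions.  A zero-spread marker
#' leaves every sample unassigned, and a sample meeting both cutoffs
#' simultaneously (possible under heavy ties) stays unassigned so the
#' male and female sets are always disjoint.
#'
#' @param expr Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param marker_gene Row name of the marker (e.g. an SRY probe).
#' @param quantile Tail fraction assigned to each sex (default 0.16).
#' @param method `"quantile"` (default) or `"sd"` (cutoffs at mean
#'   plus/minus one standard deviation).
#' @return Named character vector over samples with values `"male"`,
#'   `"female"`, `"unassigned"`.
#' @export
infer_sex <- function(expr, marker_gene, quantile = 0.16,
                      method = c("quantile", "sd")) {
  method <- match.arg(method)
  if (!marker_gene %in% rownames(expr)) {
    stop_hf(sprintf("marker gene '%s' absent from expression matrix", marker_gene),
            "hepaflux_missing_marker_error")
  }
  x <- expr[marker_gene, ]
  out <- rep("unassigned", length(x))
  names(out) <- colnames(expr)
  if (max(x) - min(x) <= 0) return(out)
  if (method == "quantile") {
    lo <- stats::quantile(x, quantile, type = 7, names = FALSE)
    hi <- stats::quantile(x, 1 - quantile, type = 7, names = FALSE)
  } else {
    lo <- mean(x) - stats::sd(x)
    hi <- mean(x) + stats::sd(x)
  }
  is_m <- x >= hi
  is_f <- x <= lo
  both <- is_m & is_f
  out[is_m & !both] <- "male"
  out[is_f & !both] <- "female"
  out
}

#' Differential expression between two sample groups
#'
#' Log2-transforms abundances with a +1 offset, then tests each gene
#' with a Welch two-sample t-test and adjusts p-values by
#' Benjamini-Hochberg.  The contrast orientation is fixed: positive
#' `log2fc` means higher in group A (`"male"` for the default sex
#' contrast).
#'
#' @param expr Numeric gene-by-sample matrix (nonnegative abundances,
#'   linear scale).
#' @param labels Named character vector over samples; samples labelled
#'   `group_a` / `group_b` enter the contrast, others are dropped.
#' @param group_a,group_b Labels defining the contrast (defaults
#'   `"male"` vs `"female"`).
#' @return Data frame (`deg_table`) with columns `gene_id`, `log2fc`,
#'   `p`, `fdr`, one row per gene; attribute `contrast` records the
#'   orientation.
#' @export
differential_expression <- function(expr, labels,
                                    group_a = "male", group_b = "female") {
  labels <- labels[intersect(names(labels), colnames(expr))]
  a_ids <- names(labels)[labels == group_a]
  b_ids <- names(labels)[labels == group_b]
  if (length(a_ids) < 2 || length(b_ids) < 2) {
    stop_hf(
      sprintf("need >= 2 samples per group (got %d '%s', %d '%s')",
              length(a_ids), group_a, length(b_ids), group_b),
      "hepaflux_replication_error"
    )
  }
  la <- log2(expr[, a_ids, drop = FALSE] + 1)
  lb <- log2(expr[, b_ids, drop = FALSE] + 1)
  genes <- rownames(expr)
  log2fc <- rowMeans(la) - rowMeans(lb)
  p <- vapply(seq_along(genes), function(i) {
    xa <- la[i, ]; xb <- lb[i, ]
    if (stats::var(xa) == 0 && stats::var(xb) == 0) {
      return(if (mean(xa) == mean(xb)) 1 else 0)
    }
    stats::t.test(xa, xb, var.equal = FALSE)$p.value
  }, numeric(1))
  out <- data.frame(
    gene_id = genes,
    log2fc = unname(log2fc),
    p = p,
    fdr = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE
  )
  attr(out, "contrast") <- c(A = group_a, B = group_b)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Gene weights from a differential-expression table
#'
#' Significant genes (FDR below `fdr_threshold`) keep their log2 fold
#' change as weight; every other tested gene gets exactly 0.
#'
#' @param degs A `deg_table` (columns `gene_id`, `log2fc`, `fdr`).
#' @param fdr_threshold Significance cutoff (default 0.1).
#' @return Named numeric vector over all tested genes.
#' @export
weights_from_degs <- function(degs, fdr_threshold = 0.1) {
  stopifnot(all(c("gene_id", "log2fc", "fdr") %in% names(degs)))
  w <- ifelse(degs$fdr < fdr_threshold, degs$log2fc, 0)
  names(w) <- degs$gene_id
  w
}

#' Read a precomputed differential-expression table
#'
#' Tab-separated input with columns `gene_id`, `log2fc`, `p` and
#' optionally `fdr`; a missing `fdr` column is filled by
#' Benjamini-Hochberg on `p`.  Lets treated-vs-untreated contrasts
#' (e.g. hepatotoxicant exposure panels) enter the pipeline without raw
#' expression data.
#'
#' @param path Path to the TSV file.
#' @return A `deg_table` data frame.
#' @export
read_precomputed_degs <- function(path) {
  if (!file.exists(path)) {
    stop_hf(sprintf("DEG file not found: %s", path), "hepaflux_io_error")
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_id", "log2fc", "p")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_hf(sprintf("DEG table missing column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "hepaflux_format_error")
  }
  if (anyDuplicated(df$gene_id)) {
    dups <- unique(df$gene_id[duplicated(df$gene_id)])
    stop_hf(sprintf("duplicated gene_id(s) in DEG table: %s",
                    paste(utils::head(dups, 5), collapse = ", ")),
            "hepaflux_format_error")
  }
  if (!"fdr" %in% names(df)) df$fdr <- stats::p.adjust(df$p, method = "BH")
  out <- df[, c("gene_id", "log2fc", "p", "fdr")]
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Read a gene-by-sample expression TSV
#'
#' First column is the gene id, remaining columns one sample each.
#' Duplicate gene ids keep the first occurrence with a warning.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- df[[1]]
  if (anyDuplicated(genes)) {
    warning("duplicate gene ids in expression table; keeping first occurrence")
    keep <- !duplicated(genes)
    df <- df[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- genes
  storage.mode(m) <- "double"
  m
}
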