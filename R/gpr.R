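## Gene-protein-reaction (GPR) rules: parsing, printing, evaluation.
##
## A GPR is a boolean expression over gene identifiers with `and` / `or`
## (case-insensitive) and parentheses.  AND encodes an enzyme complex
## (all subunits required), OR encodes isozymes (any suffices).  When a
## rule is evaluated against per-gene scores, OR takes the maximum of its
## children and AND the minimum, so an isozyme set inherits its strongest
## member and a complex its weakest.

#' Parse a gene-protein-reaction rule
#'
#' Parses a boolean gene association string such as
#' `"(G1 and G2) or G3"` into an expression tree.  `and` binds tighter
#' than `or`; both keywords are case-insensitive.  Consecutive
#' applications of the same operator are flattened, so
#' `"A and B and C"` yields a single AND node with three children.
#'
#' @param rule Character scalar; the rule.  An empty or all-whitespace
#'   string returns `NULL` (no gene association).
#' @return An object of class `gpr`: a list with `kind` (`"gene"`,
#'   `"and"` or `"or"`), and either `gene` (for leaves) or `children`
#'   (a list of at least two `gpr` nodes), or `NULL` for an empty rule.
#' @examples
#' parse_gpr("G1 and G2 or G3")   # OR(AND(G1, G2), G3)
#' parse_gpr("(G1 or G2) and G3") # AND(OR(G1, G2), G3)
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0 || is.na(rule)) return(NULL)
  stopifnot(is.character(rule), length(rule) == 1)
  tokens <- gpr_tokenize(rule)
  if (length(tokens$type) == 0) return(NULL)
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$pos <- 1L
  expr <- gpr_parse_or(state)
  if (state$pos <= length(state$tokens$type)) {
    stop_hf(
      sprintf(
        "GPR parse error at position %d: unexpected '%s'",
        state$tokens$at[state$pos], state$tokens$text[state$pos]
      ),
      "hepaflux_parse_error"
    )
  }
  expr
}

gpr_tokenize <- function(rule) {
  type <- character(0); text <- character(0); at <- integer(0)
  chars <- strsplit(rule, "", fixed = TRUE)[[1]]
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
    } else if (ch == "(" || ch == ")") {
      type <- c(type, ch); text <- c(text, ch); at <- c(at, i)
      i <- i + 1L
    } else {
      j <- i
      while (j <= n && !grepl("^[\\s()]$", chars[j], perl = TRUE)) j <- j + 1L
      word <- paste(chars[i:(j - 1L)], collapse = "")
      lw <- tolower(word)
      if (lw == "and" || lw == "or") {
        type <- c(type, lw)
      } else {
        type <- c(type, "gene")
      }
      text <- c(text, word); at <- c(at, i)
      i <- j
    }
  }
  list(type = type, text = text, at = at)
}

gpr_peek <- function(state) {
  if (state$pos > length(state$tokens$type)) NA_character_ else state$tokens$type[state$pos]
}

gpr_parse_or <- function(state) {
  children <- list(gpr_parse_and(state))
  while (identical(gpr_peek(state), "or")) {
    state$pos <- state$pos + 1L
    children <- c(children, list(gpr_parse_and(state)))
  }
  if (length(children) == 1) children[[1]] else gpr_node("or", children)
}

gpr_parse_and <- function(state) {
  children <- list(gpr_parse_factor(state))
  while (identical(gpr_peek(state), "and")) {
    state$pos <- state$pos + 1L
    children <- c(children, list(gpr_parse_factor(state)))
  }
  if (length(children) == 1) children[[1]] else gpr_node("and", children)
}

gpr_parse_factor <- function(state) {
  tk <- gpr_peek(state)
  if (is.na(tk)) {
    stop_hf("GPR parse error: unexpected end of rule (dangling operator?)",
            "hepaflux_parse_error")
  }
  if (tk == "(") {
    open_at <- state$tokens$at[state$pos]
    state$pos <- state$pos + 1L
    expr <- gpr_parse_or(state)
    if (!identical(gpr_peek(state), ")")) {
      stop_hf(sprintf("GPR parse error: unbalanced '(' at position %d", open_at),
              "hepaflux_parse_error")
    }
    state$pos <- state$pos + 1L
    return(expr)
  }
  if (tk == "gene") {
    g <- state$tokens$text[state$pos]
    state$pos <- state$pos + 1L
    return(gpr_gene(g))
  }
  stop_hf(
    sprintf(
      "GPR parse error at position %d: unexpected '%s'",
      state$tokens$at[state$pos], state$tokens$text[state$pos]
    ),
    "hepaflux_parse_error"
  )
}

gpr_gene <- function(gene) {
  structure(list(kind = "gene", gene = gene), class = "gpr")
}

## Build an AND/OR node, flattening children of the same kind.
gpr_node <- function(kind, children) {
  flat <- list()
  for (ch in children) {
    if (!inherits(ch, "gpr")) stop_hf("GPR children must be gpr nodes", "hepaflux_parse_error")
    if (identical(ch$kind, kind)) flat <- c(flat, ch$children) else flat <- c(flat, list(ch))
  }
  structure(list(kind = kind, children = flat), class = "gpr")
}

#' Genes referenced by a GPR tree
#'
#' @param expr A `gpr` object or `NULL`.
#' @return Character vector of unique gene identifiers (empty for `NULL`).
#' @export
gpr_genes <- function(expr) {
  if (is.null(expr)) return(character(0))
  if (expr$kind == "gene") return(expr$gene)
  unique(unlist(lapply(expr$children, gpr_genes)))
}

#' Serialize a GPR tree back to a rule string
#'
#' Produces a fully parenthesised, round-trippable representation:
#' `parse_gpr(gpr_to_string(x))` reconstructs a structurally identical
#' tree.
#'
#' @param expr A `gpr` object or `NULL`.
#' @return Character scalar (`""` for `NULL`).
#' @export
gpr_to_string <- function(expr) {
  if (is.null(expr)) return("")
  if (expr$kind == "gene") return(expr$gene)
  sep <- if (expr$kind == "and") " and " else " or "
  parts <- vapply(expr$children, function(ch) {
    s <- gpr_to_string(ch)
    if (ch$kind != "gene") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = sep)
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", gpr_to_string(x), "\n", sep = "")
  invisible(x)
}

#' Evaluate a GPR tree against per-gene scores
#'
#' OR nodes return the maximum of their children's values and AND nodes
#' the minimum, so for log2 fold changes an isozyme set takes the
#' highest fold difference and an enzyme complex the lowest.  Genes
#' absent from `gene_values` are treated according to `missing`:
#' `"skip"` drops the leaf from its parent (a node with no surviving
#' children is itself dropped), `"zero"` scores it 0.
#'
#' @param expr A `gpr` object, or `NULL`.
#' @param gene_values Named numeric vector of per-gene scores.
#' @param missing Missing-gene policy, `"skip"` (default) or `"zero"`.
#' @return Numeric scalar, or `NA_real_` when the rule is `NULL` or no
#'   leaf could be resolved under the `"skip"` policy.
#' @examples
#' e <- parse_gpr("G1 or G2")
#' evaluate_gpr(e, c(G1 = 2, G2 = -1))  # 2
#' e2 <- parse_gpr("G1 and G2")
#' evaluate_gpr(e2, c(G1 = 2, G2 = -1)) # -1
#' @export
evaluate_gpr <- function(expr, gene_values, missing = c("skip", "zero")) {
  missing <- match.arg(missing)
  if (is.null(expr)) return(NA_real_)
  v <- gpr_eval_rec(expr, gene_values, missing)
  if (is.null(v)) NA_real_ else v
}

gpr_eval_rec <- function(expr, gene_values, missing) {
  if (expr$kind == "gene") {
    if (expr$gene %in% names(gene_values)) {
      return(unname(gene_values[[expr$gene]]))
    }
    return(if (missing == "zero") 0 else NULL)
  }
  vals <- unlist(lapply(expr$children, gpr_eval_rec,
                        gene_values = gene_values, missing = missing))
  if (is.null(vals) || length(vals) == 0) return(NULL)
  if (expr$kind == "or") max(vals) else min(vals)
}
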