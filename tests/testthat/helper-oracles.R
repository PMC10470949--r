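# Independent oracles, written before (and kept independent of) the
# implementations they check.

# --- GPR -------------------------------------------------------------

# Independent recursive GPR evaluator: returns a list of resolved leaf
# values per subtree and folds with min/max at the top, so it shares no
# code path with evaluate_gpr().
oracle_gpr_values <- function(node, vals) {
  if (node$kind == "gene") {
    if (node$gene %in% names(vals)) return(unname(vals[[node$gene]]))
    return(numeric(0))
  }
  resolved <- lapply(node$children, oracle_gpr_values, vals = vals)
  folded <- numeric(0)
  for (r in resolved) {
    if (length(r) == 1) folded <- c(folded, r)
  }
  if (length(folded) == 0) return(numeric(0))
  if (node$kind == "or") max(folded) else min(folded)
}

oracle_eval_gpr <- function(node, vals) {
  out <- oracle_gpr_values(node, vals)
  if (length(out) == 0) NA_real_ else out
}

# Random GPR tree generator (depth-limited), plus a random value map.
random_gpr <- function(depth = 3, genes = paste0("G", 1:8)) {
  if (depth == 0 || stats::runif(1) < 0.35) {
    return(structure(list(kind = "gene", gene = sample(genes, 1)),
                     class = "gpr"))
  }
  kind <- sample(c("and", "or"), 1)
  k <- sample(2:3, 1)
  kids <- lapply(seq_len(k), function(i) random_gpr(depth - 1, genes))
  # flatten same-kind children the way the parser canonicalises
  flat <- list()
  for (ch in kids) {
    if (identical(ch$kind, kind)) flat <- c(flat, ch$children)
    else flat <- c(flat, list(ch))
  }
  structure(list(kind = kind, children = flat), class = "gpr")
}

# --- LP (scipy / HiGHS through the python binary) --------------------

# Batch-solve standard-form LPs:
#   each problem: list(obj, A_ub, b_ub, A_eq, b_eq, lb, ub, maximize)
# Returns a list of list(status, value, x).
scipy_solve_lps <- function(problems) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(problems, infile, digits = NA, auto_unbox = FALSE,
                       null = "null")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    "probs = json.load(open(sys.argv[1]))",
    "out = []",
    "for p in probs:",
    "    c = np.asarray(p['obj'], float)",
    "    sign = -1.0 if p['maximize'][0] else 1.0",
    "    A_ub = np.asarray(p['A_ub'], float) if p.get('A_ub') else None",
    "    b_ub = np.asarray(p['b_ub'], float) if p.get('A_ub') else None",
    "    A_eq = np.asarray(p['A_eq'], float) if p.get('A_eq') else None",
    "    b_eq = np.asarray(p['b_eq'], float) if p.get('A_eq') else None",
    "    bounds = list(zip(p['lb'], p['ub']))",
    "    r = linprog(sign * c, A_ub=A_ub, b_ub=b_ub, A_eq=A_eq, b_eq=b_eq,",
    "                bounds=bounds, method='highs')",
    "    ok = (r.status == 0)",
    "    out.append({'status': int(r.status),",
    "                'value': float(sign * r.fun) if ok else None,",
    "                'x': [float(v) for v in r.x] if ok else None})",
    "json.dump(out, open(sys.argv[2], 'w'))"
  ), script)
  status <- system2("python", c(script, infile, outfile),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("scipy LP oracle failed to run")
  jsonlite::read_json(outfile, simplifyVector = FALSE)
}

# FBA oracle problem in the net-flux formulation (no split variables):
# an independent encoding of max/min v_j s.t. S v = 0, lb <= v <= ub.
oracle_fba_problem <- function(model, objective, maximize = TRUE) {
  S <- stoichiometric_matrix(model)
  bb <- flux_bounds(model)
  obj <- rep(0, ncol(S))
  obj[match(objective, colnames(S))] <- 1
  list(obj = obj, A_ub = NULL, b_ub = NULL,
       A_eq = unname(S), b_eq = rep(0, nrow(S)),
       lb = unname(bb$lb), ub = unname(bb$ub), maximize = maximize)
}

# Weighted flux-sum problem in the split encoding, assembled
# independently of the package's split_lp builder.
oracle_weighted_problem <- function(model, w, biomass_min = 0,
                                    maximize = FALSE) {
  S <- stoichiometric_matrix(model)
  bb <- flux_bounds(model)
  n <- ncol(S)
  obj <- c(w, w)
  A_eq <- cbind(S, -S)
  b_eq <- rep(0, nrow(S))
  lb <- rep(0, 2 * n)
  ub <- c(pmax(bb$ub, 0), pmax(-bb$lb, 0))
  A_ub <- NULL; b_ub <- NULL
  net_row <- function(j) { r <- rep(0, 2 * n); r[j] <- 1; r[n + j] <- -1; r }
  for (j in which(bb$lb > 0)) {
    A_ub <- rbind(A_ub, -net_row(j)); b_ub <- c(b_ub, -bb$lb[j])
  }
  for (j in which(bb$ub < 0)) {
    A_ub <- rbind(A_ub, net_row(j)); b_ub <- c(b_ub, bb$ub[j])
  }
  if (biomass_min > 0) {
    j <- match(model$objective, colnames(S))
    A_ub <- rbind(A_ub, -net_row(j)); b_ub <- c(b_ub, -biomass_min)
  }
  list(obj = obj, A_ub = if (is.null(A_ub)) NULL else unname(A_ub),
       b_ub = b_ub, A_eq = unname(A_eq), b_eq = b_eq,
       lb = lb, ub = ub, maximize = maximize)
}

# --- Mann-Whitney ----------------------------------------------------

# Exact two-sided p by exhaustive enumeration of all group-A position
# subsets (requires untied values).
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  stopifnot(!anyDuplicated(pool))
  rk <- rank(pool)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  subsets <- utils::combn(n1 + n2, n1)
  us <- apply(subsets, 2, function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# --- cohort counting -------------------------------------------------

# Brute-force presence fractions / uniqueness over raw keep-sets.
oracle_presence <- function(keeps_A, keeps_B, min_frac = 0.1) {
  rxns <- sort(unique(c(unlist(keeps_A), unlist(keeps_B))))
  fA <- vapply(rxns, function(r) {
    mean(vapply(keeps_A, function(k) r %in% k, logical(1)))
  }, numeric(1))
  fB <- vapply(rxns, function(r) {
    mean(vapply(keeps_B, function(k) r %in% k, logical(1)))
  }, numeric(1))
  list(
    reaction_id = rxns, frac_A = unname(fA), frac_B = unname(fB),
    unique_A = rxns[fA >= min_frac & fB == 0],
    unique_B = rxns[fB >= min_frac & fA == 0]
  )
}

# Direct binning of nonzero fractions into bins-of-0.1 with the top bin
# closed.
oracle_histogram <- function(fracs, bins = 10) {
  fracs <- fracs[fracs > 0]
  counts <- integer(bins)
  for (f in fracs) {
    b <- min(floor(f * bins) + 1, bins)
    counts[b] <- counts[b] + 1L
  }
  counts
}

# Wrap a plain keep-set in the minimal structure presence_table() needs.
fake_context <- function(kept, subsystem_map = NULL) {
  structure(
    list(kept_reactions = kept,
         subsystems = if (is.null(subsystem_map)) {
           stats::setNames(rep(NA_character_, length(kept)), kept)
         } else subsystem_map[kept]),
    class = "context_model"
  )
}
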