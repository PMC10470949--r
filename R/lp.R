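## Linear-programming layer.  All constraint-based computations (FBA,
## weighted flux-sum minimisation / maximisation, polytope vertex
## probes for the sampler) reduce to one standard form
##     opt  c'x   s.t.  A_le x <= b_le,  A_ge x >= b_ge,  A_eq x = b_eq,
##     x >= 0,
## solved with the two-phase simplex in boot::simplex.  Rows are
## sign-normalised first (boot::simplex assumes nonnegative right-hand
## sides and silently misbehaves otherwise).
##
## Absolute-value objectives sum w_i |v_i| are linearised by the
## standard split v = v+ - v- with v+, v- >= 0 (the pFBA construction).

LP_TOL <- 1e-6

## Solve the standard form above (see R/simplex.R for the engine).
## Returns list(x, value, status) with status one of "optimal",
## "infeasible", "unbounded", "maxiter".
solve_lp <- function(obj, A_le = NULL, b_le = NULL, A_ge = NULL, b_ge = NULL,
                     A_eq = NULL, b_eq = NULL, maximize = FALSE) {
  lp_simplex(obj, A_le, b_le, A_ge, b_ge, A_eq, b_eq, maximize = maximize)
}

## Build the split-variable LP skeleton for a model:
## variables x = (v_plus, v_minus), caps from bounds, equalities
## S v_plus - S v_minus = 0, plus rows enforcing strictly positive lb /
## strictly negative ub, plus an optional biomass floor.
split_lp_parts <- function(model, biomass_min = NULL) {
  S <- stoichiometric_matrix(model)
  bb <- flux_bounds(model)
  n <- ncol(S)
  cap_p <- pmax(bb$ub, 0)
  cap_m <- pmax(-bb$lb, 0)
  if (any(is.infinite(cap_p)) || any(is.infinite(cap_m))) {
    bad <- reaction_ids(model)[is.infinite(cap_p) | is.infinite(cap_m)]
    stop_hf(
      sprintf("infinite bounds would make the flux-sum objective unbounded: %s",
              paste(bad, collapse = ", ")),
      "hepaflux_unbounded_error", reactions = bad
    )
  }
  A_le <- cbind(diag(n), matrix(0, n, n))      # v+ <= cap_p
  A_le <- rbind(A_le, cbind(matrix(0, n, n), diag(n)))  # v- <= cap_m
  b_le <- c(cap_p, cap_m)
  A_ge <- NULL; b_ge <- NULL
  pos_lb <- which(bb$lb > 0)
  if (length(pos_lb)) {                         # v+ - v- >= lb  (lb > 0)
    rows <- matrix(0, length(pos_lb), 2 * n)
    for (k in seq_along(pos_lb)) {
      j <- pos_lb[k]; rows[k, j] <- 1; rows[k, n + j] <- -1
    }
    A_ge <- rbind(A_ge, rows); b_ge <- c(b_ge, bb$lb[pos_lb])
  }
  neg_ub <- which(bb$ub < 0)
  if (length(neg_ub)) {                         # v+ - v- <= ub  (ub < 0)
    rows <- matrix(0, length(neg_ub), 2 * n)
    for (k in seq_along(neg_ub)) {
      j <- neg_ub[k]; rows[k, j] <- 1; rows[k, n + j] <- -1
    }
    A_le <- rbind(A_le, rows); b_le <- c(b_le, bb$ub[neg_ub])
  }
  if (!is.null(biomass_min) && biomass_min > 0) {
    j <- match(model$objective, reaction_ids(model))
    row <- rep(0, 2 * n); row[j] <- 1; row[n + j] <- -1
    A_ge <- rbind(A_ge, matrix(row, 1)); b_ge <- c(b_ge, biomass_min)
  }
  A_eq <- cbind(S, -S)
  b_eq <- rep(0, nrow(S))
  list(A_le = A_le, b_le = b_le, A_ge = A_ge, b_ge = b_ge,
       A_eq = A_eq, b_eq = b_eq, n = n)
}

net_flux <- function(x, model) {
  n <- length(model$reactions)
  v <- x[seq_len(n)] - x[n + seq_len(n)]
  names(v) <- reaction_ids(model)
  v
}

#' Flux balance analysis
#'
#' Optimises the flux of one reaction subject to steady-state mass
#' balance `S v = 0` and the model's flux bounds.
#'
#' @param model A `metabolic_model`.
#' @param objective Reaction id to optimise; defaults to the model's
#'   biomass objective.
#' @param direction `"max"` (default) or `"min"`.
#' @return List with `fluxes` (named numeric vector) and
#'   `objective_value`.
#' @export
fba <- function(model, objective = model$objective, direction = c("max", "min")) {
  direction <- match.arg(direction)
  rids <- reaction_ids(model)
  j <- match(objective, rids)
  if (is.na(j)) {
    stop_hf(sprintf("objective reaction '%s' not in model", objective),
            "hepaflux_consistency_error")
  }
  parts <- split_lp_parts(model)
  obj <- rep(0, 2 * parts$n); obj[j] <- 1; obj[parts$n + j] <- -1
  res <- solve_lp(obj, parts$A_le, parts$b_le, parts$A_ge, parts$b_ge,
                  parts$A_eq, parts$b_eq, maximize = (direction == "max"))
  if (res$status == "infeasible") {
    stop_hf(sprintf("model '%s' is infeasible", model$id), "hepaflux_infeasible_error")
  }
  if (res$status != "optimal") {
    stop_hf("LP failed to converge (iteration limit)", "hepaflux_lp_error")
  }
  list(fluxes = net_flux(res$x, model), objective_value = res$value)
}

resolve_biomass_min <- function(model, biomass_fraction) {
  stopifnot(biomass_fraction >= 0, biomass_fraction <= 1)
  if (biomass_fraction == 0) return(0)
  biomass_fraction * fba(model)$objective_value
}

#' Minimise a weighted flux sum at a biomass floor
#'
#' Finds `argmin sum_i w_i |v_i|` subject to `S v = 0`, the model's
#' bounds, and biomass flux at least `biomass_fraction` of the model's
#' maximum.  Absolute values are linearised by splitting each reaction
#' into nonnegative forward/backward components; the net flux is
#' returned.  With uniform weights this is the parsimonious-FBA flux
#' distribution.
#'
#' @param model A `metabolic_model`.
#' @param weights Named nonnegative numeric vector (reaction id ->
#'   weight).  Unlisted reactions get `default_weight`.
#' @param biomass_fraction Biomass floor as a fraction of the maximum
#'   (in `[0, 1]`).
#' @param default_weight Weight for reactions absent from `weights`.
#' @param biomass_min Optional absolute biomass floor overriding
#'   `biomass_fraction` (used when the floor refers to a different
#'   base model's maximum).
#' @return Named numeric flux vector with attributes `objective`
#'   (the attained weighted flux sum) and `biomass_min`.
#' @export
minimize_weighted_flux <- function(model, weights = NULL, biomass_fraction = 0,
                                   default_weight = 1, biomass_min = NULL) {
  rids <- reaction_ids(model)
  w <- rep(default_weight, length(rids)); names(w) <- rids
  if (!is.null(weights)) w[names(weights)[names(weights) %in% rids]] <-
      weights[names(weights) %in% rids]
  if (any(w < 0)) stop_hf("flux-sum weights must be nonnegative", "hepaflux_lp_error")
  bm_min <- biomass_min %||% resolve_biomass_min(model, biomass_fraction)
  parts <- split_lp_parts(model, biomass_min = bm_min)
  obj <- c(w, w)
  res <- solve_lp(obj, parts$A_le, parts$b_le, parts$A_ge, parts$b_ge,
                  parts$A_eq, parts$b_eq, maximize = FALSE)
  if (res$status == "infeasible") {
    stop_hf(
      sprintf("infeasible at biomass fraction %.3f", biomass_fraction),
      "hepaflux_infeasible_error", biomass_fraction = biomass_fraction
    )
  }
  if (res$status != "optimal") {
    stop_hf("LP failed to converge (iteration limit)", "hepaflux_lp_error")
  }
  v <- net_flux(res$x, model)
  attr(v, "objective") <- res$value
  attr(v, "biomass_min") <- bm_min
  v
}

#' Maximise a weighted flux sum at a biomass floor
#'
#' Maximises `sum_i w_i (v_i^+ + v_i^-)` over the split-variable
#' polytope (the irreversible expansion of the network) subject to mass
#' balance, bounds, and the biomass floor.  When `orthant` is supplied
#' (a named sign vector, one of -1/+1 per reaction), the problem is
#' instead solved in the fixed flux-direction orthant, where the
#' objective equals `sum_i w_i |v_i|` exactly; this is the form used
#' ahead of constrained flux sampling.
#'
#' @inheritParams minimize_weighted_flux
#' @param orthant Optional named sign vector fixing each reaction's flux
#'   direction.
#' @return List with `fluxes` (net, named), `objective_value`, and
#'   `biomass_min`.
#' @export
maximize_weighted_flux <- function(model, weights = NULL, biomass_fraction = 0,
                                   default_weight = 1, orthant = NULL) {
  rids <- reaction_ids(model)
  w <- rep(default_weight, length(rids)); names(w) <- rids
  if (!is.null(weights)) w[names(weights)[names(weights) %in% rids]] <-
      weights[names(weights) %in% rids]
  if (any(w < 0)) stop_hf("flux-sum weights must be nonnegative", "hepaflux_lp_error")
  bm_min <- resolve_biomass_min(model, biomass_fraction)
  if (is.null(orthant)) {
    parts <- split_lp_parts(model, biomass_min = bm_min)
    obj <- c(w, w)
    res <- solve_lp(obj, parts$A_le, parts$b_le, parts$A_ge, parts$b_ge,
                    parts$A_eq, parts$b_eq, maximize = TRUE)
    if (res$status == "infeasible") {
      stop_hf(sprintf("infeasible at biomass fraction %.3f", biomass_fraction),
              "hepaflux_infeasible_error", biomass_fraction = biomass_fraction)
    }
    if (res$status != "optimal") {
      stop_hf("LP failed to converge (iteration limit)", "hepaflux_lp_error")
    }
    return(list(fluxes = net_flux(res$x, model), objective_value = res$value,
                biomass_min = bm_min))
  }
  res <- orthant_lp(model, obj_w = w, orthant = orthant, biomass_min = bm_min,
                    maximize = TRUE)
  list(fluxes = res$fluxes, objective_value = res$value, biomass_min = bm_min)
}

## LP over a fixed flux-direction orthant.  Substituting u_r = s_r v_r
## (u >= 0) makes sum w |v| = sum w u linear.  Bounds become
## u in [max(0, s lb or -ub), ...]; columns of S are sign-scaled.
orthant_lp <- function(model, obj_w, orthant, biomass_min = 0,
                       extra_ge = NULL, maximize = TRUE) {
  rids <- reaction_ids(model)
  s <- orthant[rids]
  stopifnot(all(s %in% c(-1, 1)))
  bb <- flux_bounds(model)
  lo <- ifelse(s > 0, pmax(bb$lb, 0), pmax(-bb$ub, 0))
  hi <- ifelse(s > 0, bb$ub, -bb$lb)
  if (any(hi < lo - 1e-12)) {
    stop_hf("orthant incompatible with bounds", "hepaflux_infeasible_error")
  }
  S <- stoichiometric_matrix(model)
  Ssc <- sweep(S, 2, s, `*`)
  n <- length(rids)
  A_le <- diag(n); b_le <- hi
  A_ge <- NULL; b_ge <- NULL
  pos <- which(lo > 0)
  if (length(pos)) {
    A_ge <- diag(n)[pos, , drop = FALSE]; b_ge <- lo[pos]
  }
  if (biomass_min > 0) {
    j <- match(model$objective, rids)
    if (s[j] < 0) stop_hf("biomass orthant must be positive", "hepaflux_lp_error")
    row <- rep(0, n); row[j] <- 1
    A_ge <- rbind(A_ge, row); b_ge <- c(b_ge, biomass_min)
  }
  if (!is.null(extra_ge)) {
    A_ge <- rbind(A_ge, extra_ge$A); b_ge <- c(b_ge, extra_ge$b)
  }
  res <- solve_lp(obj_w[rids], A_le, b_le, A_ge, b_ge, Ssc, rep(0, nrow(Ssc)),
                  maximize = maximize)
  if (res$status == "infeasible") {
    stop_hf("orthant LP infeasible", "hepaflux_infeasible_error")
  }
  if (res$status != "optimal") {
    stop_hf("LP failed to converge (iteration limit)", "hepaflux_lp_error")
  }
  v <- res$x * s
  names(v) <- rids
  list(fluxes = v, value = res$value)
}

## LP over the general net-flux polytope
##   S v = 0 (+ extra equalities), lb <= v <= ub, extra <=/>= rows,
## via the shift u = v - lb >= 0.  Used by the sampler's vertex probes.
## `constraints` is a list of list(coef = named numeric, dir, rhs).
polytope_lp <- function(model, obj, constraints = list(), maximize = TRUE,
                        lb = NULL, ub = NULL) {
  rids <- reaction_ids(model)
  bb <- flux_bounds(model)
  if (!is.null(lb)) bb$lb <- lb
  if (!is.null(ub)) bb$ub <- ub
  n <- length(rids)
  S <- stoichiometric_matrix(model)
  A_eq <- S; b_eq <- as.numeric(-S %*% bb$lb)
  A_le <- diag(n); b_le <- bb$ub - bb$lb
  A_ge <- NULL; b_ge <- NULL
  for (cn in constraints) {
    row <- rep(0, n); names(row) <- rids
    row[names(cn$coef)] <- cn$coef
    shift <- sum(row * bb$lb)
    if (cn$dir == "<=") {
      A_le <- rbind(A_le, unname(row)); b_le <- c(b_le, cn$rhs - shift)
    } else if (cn$dir == ">=") {
      A_ge <- rbind(A_ge, unname(row)); b_ge <- c(b_ge, cn$rhs - shift)
    } else {
      A_eq <- rbind(A_eq, unname(row)); b_eq <- c(b_eq, cn$rhs - shift)
    }
  }
  res <- solve_lp(obj[rids], A_le, b_le, A_ge, b_ge, A_eq, b_eq,
                  maximize = maximize)
  if (res$status == "infeasible") {
    stop_hf("polytope is empty", "hepaflux_infeasible_error")
  }
  if (res$status != "optimal") {
    stop_hf("LP failed to converge (iteration limit)", "hepaflux_lp_error")
  }
  v <- res$x + bb$lb
  names(v) <- rids
  list(fluxes = v, value = sum(obj[rids] * v))
}
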