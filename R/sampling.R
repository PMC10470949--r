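## Flux sampling by a seeded hit-and-run walk (ACHR-style) over the
## steady-state flux polytope
##   { v : S v = 0, lb <= v <= ub, extra linear constraints },
## run in the null space of the equality system so every iterate is
## mass-balanced by construction.

#' Linear flux constraint helper
#'
#' @param coef Named numeric vector of reaction coefficients.
#' @param dir One of `"<="`, `">="`, `"=="`.
#' @param rhs Right-hand side.
#' @return A `flux_constraint` list usable by [flux_sample()] and the
#'   LP layer.
#' @export
flux_constraint <- function(coef, dir = c("<=", ">=", "=="), rhs) {
  dir <- match.arg(dir)
  stopifnot(!is.null(names(coef)), is.numeric(rhs), length(rhs) == 1)
  structure(list(coef = coef, dir = dir, rhs = rhs), class = "flux_constraint")
}

#' Sample flux distributions from a model's feasible polytope
#'
#' Runs a seeded hit-and-run walk over `{v : S v = 0, lb <= v <= ub}`
#' intersected with any extra linear constraints.  The chain starts
#' from the average of boundary probe points (LP optima of random
#' coordinate directions), discards `warmup` steps, then records every
#' `thinning`-th step.  Identical seeds give identical sample matrices.
#'
#' @param model A `metabolic_model`.
#' @param constraints List of [flux_constraint()] objects.
#' @param n Number of samples to return.
#' @param seed Integer seed.
#' @param warmup Discarded initial steps (default 100).
#' @param thinning Record every `thinning`-th step (default 10).
#' @param lb,ub Optional named bound overrides (e.g. an orthant
#'   restriction); defaults to the model's bounds.
#' @param n_probes Max number of reactions probed (min and max) to
#'   build the interior starting point.
#' @return A `flux_sample_set`: list with `samples` (`n` x n_reactions
#'   matrix, columns named by reaction id), `reaction_ids`, `seed`.
#' @export
flux_sample <- function(model, constraints = list(), n = 110, seed = 1,
                        warmup = 100, thinning = 10, lb = NULL, ub = NULL,
                        n_probes = 24) {
  stopifnot(n >= 1)
  rids <- reaction_ids(model)
  n_rxn <- length(rids)
  bb <- flux_bounds(model)
  if (!is.null(lb)) bb$lb <- lb[rids]
  if (!is.null(ub)) bb$ub <- ub[rids]
  S <- stoichiometric_matrix(model)

  ## equality system (mass balance + any "==" constraints)
  E <- S; f <- rep(0, nrow(S))
  ineqs <- Filter(function(cn) cn$dir != "==", constraints)
  for (cn in constraints) {
    if (cn$dir == "==") {
      row <- rep(0, n_rxn); names(row) <- rids
      row[names(cn$coef)] <- cn$coef
      E <- rbind(E, unname(row)); f <- c(f, cn$rhs)
    }
  }

  ## inequality system G v <= h (bounds + extra rows)
  G <- rbind(diag(n_rxn), -diag(n_rxn))
  h <- c(bb$ub, -bb$lb)
  for (cn in ineqs) {
    row <- rep(0, n_rxn); names(row) <- rids
    row[names(cn$coef)] <- cn$coef
    if (cn$dir == "<=") {
      G <- rbind(G, unname(row)); h <- c(h, cn$rhs)
    } else {
      G <- rbind(G, -unname(row)); h <- c(h, -cn$rhs)
    }
  }

  ## interior-ish starting point: average of boundary probes
  with_seed(seed, {
    probe_rxns <- if (n_rxn <= n_probes) seq_len(n_rxn) else
      sort(sample.int(n_rxn, n_probes))
    probes <- list()
    for (j in probe_rxns) {
      obj <- rep(0, n_rxn); names(obj) <- rids; obj[j] <- 1
      for (maxi in c(TRUE, FALSE)) {
        sol <- polytope_lp(model, obj, constraints = constraints,
                           maximize = maxi, lb = bb$lb, ub = bb$ub)
        probes[[length(probes) + 1]] <- sol$fluxes
      }
    }
    v0 <- Reduce(`+`, probes) / length(probes)

    ## null-space basis of the equality system
    N <- MASS::Null(t(E))
    dim_t <- if (is.null(dim(N))) 0L else ncol(N)

    samples <- matrix(0, nrow = n, ncol = n_rxn,
                      dimnames = list(NULL, rids))
    if (dim_t == 0L) {
      for (i in seq_len(n)) samples[i, ] <- v0
    } else {
      GN <- G %*% N
      v_cur <- v0
      g_cur <- as.numeric(G %*% v_cur)
      step <- 0L
      collected <- 0L
      tol <- 1e-10
      while (collected < n) {
        step <- step + 1L
        d <- stats::rnorm(dim_t)
        d <- d / sqrt(sum(d^2))
        a <- as.numeric(GN %*% d)
        slack <- h - g_cur
        slack[slack < 0] <- 0          # numerical guard
        up <- a > tol
        dn <- a < -tol
        amax <- if (any(up)) min(slack[up] / a[up]) else 0
        amin <- if (any(dn)) max(slack[dn] / a[dn]) else 0
        if (amax - amin > tol) {
          alpha <- stats::runif(1, amin, amax)
          v_cur <- v_cur + alpha * as.numeric(N %*% d)
          g_cur <- g_cur + alpha * a
          if (step %% 50L == 0L) g_cur <- as.numeric(G %*% v_cur)  # drift control
        }
        if (step > warmup && (step - warmup) %% thinning == 0L) {
          collected <- collected + 1L
          samples[collected, ] <- v_cur
        }
      }
    }
    structure(
      list(samples = samples, reaction_ids = rids, seed = as.integer(seed),
           constraints = constraints, lb = bb$lb, ub = bb$ub),
      class = "flux_sample_set"
    )
  })
}

#' @export
print.flux_sample_set <- function(x, ...) {
  cat(sprintf("<flux_sample_set> %d samples x %d reactions (seed %d)\n",
              nrow(x$samples), length(x$reaction_ids), x$seed))
  invisible(x)
}

#' Check a flux sample set against its polytope
#'
#' Recomputes mass-balance residuals, bound violations, and extra
#' constraint violations for every sample.
#'
#' @param model The sampled `metabolic_model`.
#' @param fs A `flux_sample_set`.
#' @return List of componentwise maxima: `max_balance`, `max_bound`,
#'   `max_constraint` (0 when no extra constraints).
#' @export
check_flux_samples <- function(model, fs) {
  S <- stoichiometric_matrix(model)
  V <- fs$samples[, colnames(S), drop = FALSE]
  bal <- max(abs(S %*% t(V)))
  lbv <- max(0, max(sweep(-V, 2, fs$lb[colnames(S)], `+`)))  # lb - v
  ubv <- max(0, max(sweep(V, 2, fs$ub[colnames(S)], `-`)))   # v - ub
  cons <- 0
  for (cn in fs$constraints) {
    lhs <- as.numeric(V[, names(cn$coef), drop = FALSE] %*% cn$coef)
    viol <- switch(cn$dir,
      "<=" = lhs - cn$rhs,
      ">=" = cn$rhs - lhs,
      "==" = abs(lhs - cn$rhs)
    )
    cons <- max(cons, max(viol))
  }
  list(max_balance = bal, max_bound = max(lbv, ubv), max_constraint = max(0, cons))
}
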