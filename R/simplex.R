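## Dense two-phase primal simplex with Dantzig pivoting and a Bland's-
## rule fallback for anti-cycling.  Written for the heavily degenerate
## LPs of constraint-based metabolic modelling (all mass-balance
## right-hand sides zero, many zero-capacity rows), which off-the-shelf
## textbook simplex implementations available to this package do not
## survive.  Problem sizes here are small (hundreds of variables), so a
## dense tableau is appropriate.

## Solve min/max c'x  s.t.  A_le x <= b_le, A_ge x >= b_ge,
## A_eq x = b_eq, x >= 0.
## Returns list(x, value, status) with status in
## "optimal" / "infeasible" / "unbounded" / "maxiter".
lp_simplex <- function(obj, A_le = NULL, b_le = NULL, A_ge = NULL, b_ge = NULL,
                       A_eq = NULL, b_eq = NULL, maximize = FALSE,
                       tol = 1e-9, max_iter = 20000L) {
  n <- length(obj)
  cost <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  rows <- list(); rhs <- numeric(0); type <- character(0)
  add_rows <- function(A, b, tp) {
    if (is.null(A) || length(b) == 0) return()
    A <- matrix(A, ncol = n)
    for (i in seq_len(nrow(A))) {
      r <- A[i, ]; bi <- b[i]; ti <- tp
      if (bi < 0) {           # normalize to nonnegative rhs
        r <- -r; bi <- -bi
        ti <- switch(tp, "le" = "ge", "ge" = "le", "eq" = "eq")
      }
      rows[[length(rows) + 1L]] <<- r
      rhs[length(rhs) + 1L] <<- bi
      type[length(type) + 1L] <<- ti
    }
  }
  add_rows(A_le, b_le, "le")
  add_rows(A_ge, b_ge, "ge")
  add_rows(A_eq, b_eq, "eq")
  m <- length(rows)
  if (m == 0L) {
    ## only x >= 0: bounded iff all costs nonnegative (min form)
    if (all(cost >= -tol)) {
      return(list(x = rep(0, n), value = 0, status = "optimal"))
    }
    return(list(x = rep(0, n), value = NA_real_, status = "unbounded"))
  }
  A <- do.call(rbind, rows)

  n_slack <- sum(type == "le")
  n_surp <- sum(type == "ge")
  n_art <- sum(type != "le")
  N <- n + n_slack + n_surp + n_art
  Tab <- matrix(0, m, N)
  Tab[, seq_len(n)] <- A
  basis <- integer(m)
  s_i <- 0L; g_i <- 0L; a_i <- 0L
  for (i in seq_len(m)) {
    if (type[i] == "le") {
      s_i <- s_i + 1L
      Tab[i, n + s_i] <- 1
      basis[i] <- n + s_i
    } else if (type[i] == "ge") {
      g_i <- g_i + 1L; a_i <- a_i + 1L
      Tab[i, n + n_slack + g_i] <- -1
      Tab[i, n + n_slack + n_surp + a_i] <- 1
      basis[i] <- n + n_slack + n_surp + a_i
    } else {
      a_i <- a_i + 1L
      Tab[i, n + n_slack + n_surp + a_i] <- 1
      basis[i] <- n + n_slack + n_surp + a_i
    }
  }
  b <- rhs
  art_cols <- if (n_art > 0) (n + n_slack + n_surp) + seq_len(n_art) else integer(0)

  run_phase <- function(Tab, b, basis, cvec, allowed, tol, max_iter) {
    m <- nrow(Tab)
    ## canonical reduced-cost row: r = cvec - sum_i cvec[basis_i] * Tab[i, ]
    r <- cvec - as.numeric(t(Tab) %*% cvec[basis])
    bland_after <- 3L * (m + ncol(Tab))
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(status = "maxiter", Tab = Tab, b = b,
                                     basis = basis))
      cand <- which(allowed & r < -tol)
      if (length(cand) == 0L) {
        return(list(status = "optimal", Tab = Tab, b = b, basis = basis))
      }
      j <- if (it > bland_after) cand[1L] else cand[which.min(r[cand])]
      col <- Tab[, j]
      pos <- which(col > tol)
      if (length(pos) == 0L) {
        return(list(status = "unbounded", Tab = Tab, b = b, basis = basis))
      }
      ratio <- b[pos] / col[pos]
      best <- min(ratio)
      ties <- pos[ratio <= best + tol]
      i <- if (length(ties) > 1L) ties[which.min(basis[ties])] else ties[1L]
      ## pivot on (i, j)
      piv <- Tab[i, j]
      Tab[i, ] <- Tab[i, ] / piv
      b[i] <- b[i] / piv
      others <- setdiff(seq_len(m), i)
      f <- Tab[others, j]
      nz <- which(abs(f) > 0)
      if (length(nz)) {
        oi <- others[nz]
        Tab[oi, ] <- Tab[oi, , drop = FALSE] - outer(f[nz], Tab[i, ])
        b[oi] <- b[oi] - f[nz] * b[i]
      }
      r <- r - r[j] * Tab[i, ]
      basis[i] <- j
      b[b < 0 & b > -tol] <- 0       # clamp tiny negatives from roundoff
    }
  }

  allowed <- rep(TRUE, N)
  if (n_art > 0) {
    c1 <- rep(0, N); c1[art_cols] <- 1
    ph1 <- run_phase(Tab, b, basis, c1, allowed, tol, max_iter)
    if (ph1$status == "maxiter") {
      return(list(x = rep(NA_real_, n), value = NA_real_, status = "maxiter"))
    }
    infeas <- sum(ph1$b[ph1$basis %in% art_cols])
    if (ph1$status != "optimal" || infeas > 1e-7) {
      return(list(x = rep(NA_real_, n), value = NA_real_, status = "infeasible"))
    }
    Tab <- ph1$Tab; b <- ph1$b; basis <- ph1$basis
    ## drive basic artificials (at zero) out, or drop redundant rows
    drop_rows <- integer(0)
    for (i in which(basis %in% art_cols)) {
      row <- Tab[i, ]
      cand <- which(!(seq_len(N) %in% art_cols) & abs(row) > tol)
      if (length(cand) == 0L) {
        drop_rows <- c(drop_rows, i)
      } else {
        j <- cand[1L]
        piv <- Tab[i, j]
        Tab[i, ] <- Tab[i, ] / piv
        b[i] <- b[i] / piv
        others <- setdiff(seq_len(nrow(Tab)), i)
        f <- Tab[others, j]
        nz <- which(abs(f) > 0)
        if (length(nz)) {
          oi <- others[nz]
          Tab[oi, ] <- Tab[oi, , drop = FALSE] - outer(f[nz], Tab[i, ])
          b[oi] <- b[oi] - f[nz] * b[i]
        }
        basis[i] <- j
      }
    }
    if (length(drop_rows)) {
      keep <- setdiff(seq_len(nrow(Tab)), drop_rows)
      Tab <- Tab[keep, , drop = FALSE]
      b <- b[keep]
      basis <- basis[keep]
    }
    allowed[art_cols] <- FALSE
  }

  c2 <- c(cost, rep(0, N - n))
  ph2 <- run_phase(Tab, b, basis, c2, allowed, tol, max_iter)
  if (ph2$status == "maxiter") {
    return(list(x = rep(NA_real_, n), value = NA_real_, status = "maxiter"))
  }
  if (ph2$status == "unbounded") {
    return(list(x = rep(NA_real_, n), value = NA_real_, status = "unbounded"))
  }
  x <- rep(0, N)
  x[ph2$basis] <- ph2$b
  xx <- x[seq_len(n)]
  value <- sum(obj * xx)
  list(x = xx, value = value, status = "optimal")
}
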