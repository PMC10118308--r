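# Dense two-phase simplex solver for the small linear programs arising in
# flux variability analysis. No LP backend is assumed: problems here have a
# handful of variables, so a textbook tableau method with Bland's rule is
# adequate and exactly reproducible.

# Solve: maximize c'x subject to A x = b, x >= 0 (b may have any sign on
# entry; rows are normalised to b >= 0). Returns list(status, x, objective).
.simplex_solve <- function(c_obj, A, b, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  # phase 1: artificial variables
  Tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  obj1 <- c(rep(0, n), rep(1, m))
  run <- function(Tab, basis, obj, n_total) {
    repeat {
      cb <- obj[basis]
      z <- as.vector(cb %*% Tab[, seq_len(n_total), drop = FALSE])
      red <- obj[seq_len(n_total)] - z
      enter <- which(red < -tol)
      if (length(enter) == 0L) return(list(Tab = Tab, basis = basis))
      e <- min(enter)                      # Bland's rule
      col <- Tab[, e]
      pos <- which(col > tol)
      if (length(pos) == 0L) return(list(Tab = Tab, basis = basis,
                                         unbounded = TRUE, enter = e))
      ratio <- Tab[pos, n_total + 1L] / col[pos]
      leave <- pos[which(ratio <= min(ratio) + tol)]
      leave <- leave[which.min(basis[leave])] # Bland on leaving too
      piv <- Tab[leave, e]
      Tab[leave, ] <- Tab[leave, ] / piv
      for (r in seq_len(nrow(Tab))) {
        if (r != leave && abs(Tab[r, e]) > 0) {
          Tab[r, ] <- Tab[r, ] - Tab[r, e] * Tab[leave, ]
        }
      }
      basis[leave] <- e
    }
  }
  ph1 <- run(Tab, basis, obj1, n + m)
  if (isTRUE(ph1$unbounded)) return(list(status = "infeasible"))
  Tab <- ph1$Tab; basis <- ph1$basis
  phase1_obj <- sum(obj1[basis] * Tab[, n + m + 1L])
  if (phase1_obj > 1e-7) return(list(status = "infeasible"))
  # drive any residual artificials out of the basis where possible
  art <- which(basis > n)
  for (ai in art) {
    row <- Tab[ai, seq_len(n)]
    piv <- which(abs(row) > tol)
    if (length(piv) > 0L) {
      e <- piv[1L]
      Tab[ai, ] <- Tab[ai, ] / Tab[ai, e]
      for (r in seq_len(nrow(Tab))) {
        if (r != ai && abs(Tab[r, e]) > 0) {
          Tab[r, ] <- Tab[r, ] - Tab[r, e] * Tab[ai, ]
        }
      }
      basis[ai] <- e
    }
  }
  # phase 2 on original columns only
  keep <- c(seq_len(n), n + m + 1L)
  Tab2 <- Tab[, keep, drop = FALSE]
  ok <- basis <= n
  if (!all(ok)) {
    # redundant rows with artificial basics at zero level: drop them
    Tab2 <- Tab2[ok, , drop = FALSE]
    basis <- basis[ok]
  }
  obj2 <- -c_obj  # run() minimises reduced costs for a max problem via -c
  ph2 <- run(Tab2, basis, obj2, n)
  if (isTRUE(ph2$unbounded)) return(list(status = "unbounded"))
  Tab2 <- ph2$Tab; basis <- ph2$basis
  x <- numeric(n)
  x[basis] <- Tab2[, n + 1L]
  list(status = "optimal", x = x, objective = sum(c_obj * x))
}

# Maximize (or minimize) c'v subject to S v = 0 and lb <= v <= ub.
# Shifts v = lb + x (x >= 0), adds slack rows for the upper bounds, and
# calls the two-phase simplex.
.solve_bounded_lp <- function(c_obj, S, lb, ub, maximize = TRUE) {
  n <- length(lb)
  m <- if (is.null(dim(S)) || nrow(S) == 0L) 0L else nrow(S)
  span <- ub - lb
  Aeq <- if (m > 0L) cbind(S, matrix(0, m, n)) else NULL
  beq <- if (m > 0L) as.vector(-S %*% lb) else NULL
  Aub <- cbind(diag(n), diag(n))
  bub <- span
  A <- rbind(Aeq, Aub)
  b <- c(beq, bub)
  cc <- c(if (maximize) c_obj else -c_obj, rep(0, n))
  sol <- .simplex_solve(cc, A, b)
  if (sol$status != "optimal") return(sol)
  v <- lb + sol$x[seq_len(n)]
  list(status = "optimal", v = v,
       objective = if (maximize) sum(c_obj * v) else sum(c_obj * v))
}
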