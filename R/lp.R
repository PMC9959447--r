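## Small dense two-phase tableau simplex.
##
## The SBM efficiency programs reduce (via the Charnes-Cooper substitution) to
## linear programs with at most a couple of dozen rows, which a dense tableau
## handles comfortably. Phase 1 drives artificial variables out; phase 2 uses
## Dantzig pricing with a Bland's-rule fallback so degenerate DEA instances
## (frequent: duplicated units, ties on the frontier) cannot cycle.

#' Solve a small linear program
#'
#' Minimises `c'v` subject to `Aeq v = beq`, `Age v >= bge`, `Ale v <= ble`
#' and `v >= 0`.
#'
#' @param cvec objective coefficients.
#' @param Aeq,beq equality constraints (matrix/vector or NULL).
#' @param Age,bge greater-or-equal constraints.
#' @param Ale,ble less-or-equal constraints.
#' @param tol pivot tolerance.
#' @param maxit iteration cap per phase.
#' @return list with `status` ("optimal", "infeasible", "unbounded"),
#'   solution vector `x` and objective `value`.
#' @keywords internal
#' @noRd
lp_solve <- function(cvec, Aeq = NULL, beq = NULL, Age = NULL, bge = NULL,
                     Ale = NULL, ble = NULL, tol = 1e-9, maxit = 20000L) {
  nv <- length(cvec)
  A <- matrix(numeric(0), 0, nv); b <- numeric(0); sgn <- integer(0)
  add <- function(Ax, bx, s) {
    if (!is.null(Ax) && nrow(Ax) > 0) {
      A <<- rbind(A, Ax); b <<- c(b, bx); sgn <<- c(sgn, rep(s, nrow(Ax)))
    }
  }
  add(Aeq, beq, 0L); add(Age, bge, -1L); add(Ale, ble, 1L)
  m <- nrow(A)
  assert_that(m > 0L, "linear program has no constraints")
  ns <- sum(sgn != 0L)
  S <- matrix(0, m, ns)
  j <- 0L
  for (i in seq_len(m)) if (sgn[i] != 0L) { j <- j + 1L; S[i, j] <- sgn[i] }
  Afull <- cbind(A, S)
  neg <- b < 0
  Afull[neg, ] <- -Afull[neg, , drop = FALSE]; b[neg] <- -b[neg]
  ntot <- ncol(Afull)

  Tab <- cbind(Afull, diag(m), b)
  basis <- ntot + seq_len(m)
  ncols <- ntot + m

  pivot_loop <- function(Tab, basis, cost) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > maxit) return(list(Tab = Tab, basis = basis, status = "maxit"))
      cb <- cost[basis]
      red <- cost[seq_len(ncols)] -
        as.vector(crossprod(cb, Tab[, seq_len(ncols), drop = FALSE]))
      red[basis] <- 0
      enter <- which(red < -tol)
      if (!length(enter))
        return(list(Tab = Tab, basis = basis, status = "optimal"))
      # Dantzig rule; after a long stall switch to Bland's rule (anti-cycling)
      e <- if (it > 5L * ncols) enter[1L] else enter[which.min(red[enter])]
      col <- Tab[, e]; rhs <- Tab[, ncols + 1L]
      pos <- which(col > tol)
      if (!length(pos))
        return(list(Tab = Tab, basis = basis, status = "unbounded"))
      ratio <- rhs[pos] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      leave <- cand[which.min(basis[cand])]
      piv <- Tab[leave, e]
      Tab[leave, ] <- Tab[leave, ] / piv
      upd <- which(abs(Tab[, e]) > 0)
      upd <- upd[upd != leave]
      if (length(upd))
        Tab[upd, ] <- Tab[upd, ] - outer(Tab[upd, e], Tab[leave, ])
      basis[leave] <- e
    }
  }

  cost1 <- c(rep(0, ntot), rep(1, m))
  r1 <- pivot_loop(Tab, basis, cost1)
  if (r1$status != "optimal") return(list(status = "infeasible"))
  if (sum(cost1[r1$basis] * r1$Tab[, ncols + 1L]) > 1e-7)
    return(list(status = "infeasible"))
  Tab <- r1$Tab; basis <- r1$basis

  # pivot leftover artificials out of the basis; rows where that is impossible
  # are redundant and keep a zero-valued artificial
  for (i in seq_len(m)) {
    if (basis[i] > ntot) {
      piv <- which(abs(Tab[i, seq_len(ntot)]) > tol)
      if (length(piv)) {
        e <- piv[1L]
        Tab[i, ] <- Tab[i, ] / Tab[i, e]
        upd <- which(abs(Tab[, e]) > 0); upd <- upd[upd != i]
        if (length(upd))
          Tab[upd, ] <- Tab[upd, ] - outer(Tab[upd, e], Tab[i, ])
        basis[i] <- e
      }
    }
  }
  Tab[, ntot + seq_len(m)] <- 0  # bar artificials from re-entering

  cost2 <- c(cvec, rep(0, ns), rep(0, m))
  r2 <- pivot_loop(Tab, basis, cost2)
  if (r2$status == "unbounded") return(list(status = "unbounded"))
  rhs <- r2$Tab[, ncols + 1L]
  x <- numeric(ntot)
  keep <- r2$basis <= ntot
  x[r2$basis[keep]] <- rhs[keep]
  list(status = if (r2$status == "optimal") "optimal" else r2$status,
       x = x[seq_len(nv)],
       value = sum(cvec * x[seq_len(nv)]))
}
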