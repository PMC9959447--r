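# shared fixtures and independent oracles, built in code at test time

ctrl_cols <- c("AED", "PS", "ADR", "RHC", "FSA")

# closed-form CRS SBM oracle for single-input / single-output instances:
# score_k = ratio_k / best ratio among the other units
ratio_oracle <- function(x, y) {
  r <- y / x
  vapply(seq_along(r), function(k) r[k] / max(r[-k]), numeric(1))
}

random_ratio_dmus <- function(n) {
  dmu_set(data.frame(id = seq_len(n),
                     x = runif(n, 0.5, 5),
                     y = runif(n, 0.5, 5)),
          inputs = "x", good_outputs = "y")
}

# brute-force SBM oracle for tiny instances: with the slacks eliminated, the
# standard SBM objective is linear-fractional in the reference weights, so
# its minimum over the feasible polytope
#   { lambda >= 0 : X lambda <= x_k, Yd lambda >= yd_k, Yu lambda <= yu_k }
# is attained at a vertex. Enumerate every vertex (all n-subsets of the
# constraint rows), keep the feasible ones, and take the best objective —
# exact and independent of any LP code.
sbm_brute_force <- function(k, d) {
  X <- d$X; Yd <- d$Yd; Yu <- d$Yu
  n <- ncol(X); m <- nrow(X); r1 <- nrow(Yd); r2 <- nrow(Yu); rr <- r1 + r2
  A <- rbind(X, -Yd, if (r2) Yu, -diag(n))
  b <- c(X[, k], -Yd[, k], if (r2) Yu[, k], rep(0, n))
  obj <- function(lam) {
    sm <- X[, k] - X %*% lam
    sd <- Yd %*% lam - Yd[, k]
    su <- if (r2) Yu[, k] - Yu %*% lam else numeric(0)
    (1 - mean(sm / X[, k])) /
      (1 + (sum(sd / Yd[, k]) + if (r2) sum(su / Yu[, k]) else 0) / rr)
  }
  best <- Inf
  for (rows in utils::combn(nrow(A), n, simplify = FALSE)) {
    Asub <- A[rows, , drop = FALSE]
    if (abs(det(Asub)) < 1e-12) next
    lam <- solve(Asub, b[rows])
    if (all(A %*% lam <= b + 1e-9)) best <- min(best, obj(lam))
  }
  best
}

# panel whose yearly cross-sections are identical, with a duplicated frontier
# pair so super-efficiency of frontier units is pinned at 1 in every grouping
replicated_panel_dmus <- function(n_years = 3) {
  base <- data.frame(unit = c("A", "A2", "B", "C"),
                     x = c(1, 1, 2, 3),
                     yd = c(2, 2, 1.5, 1),
                     yu = c(1, 1, 2, 3))
  pan <- do.call(rbind, lapply(seq_len(n_years), function(yr)
    transform(base, year = yr, id = paste(unit, yr, sep = "_"))))
  dmu_set(pan, inputs = "x", good_outputs = "yd", bad_outputs = "yu",
          id = "id", year = "year")
}
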