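## Composite digital-infrastructure index construction: direction-aware
## min-max normalisation, entropy weighting, the two-system coupled
## coordination degree, and the fixed expert-weighted aggregate.

#' Construct an indicator matrix
#'
#' @param values numeric matrix or data.frame, units in rows, indicators in
#'   columns.
#' @param directions character vector, one per column, `"positive"` (more is
#'   better) or `"negative"`; recycled if length 1.
#' @return object of class `indicator_matrix`.
#' @export
indicator_matrix <- function(values, directions = "positive") {
  M <- as.matrix(values)
  assert_that(is.numeric(M) && all(is.finite(M)),
              "indicator values must be finite numerics")
  assert_that(nrow(M) >= 2L, "at least 2 units are required")
  assert_that(ncol(M) >= 1L, "at least 1 indicator is required")
  if (length(directions) == 1L) directions <- rep(directions, ncol(M))
  assert_that(length(directions) == ncol(M),
              "one direction flag per indicator column is required")
  assert_that(all(directions %in% c("positive", "negative")),
              "directions must be 'positive' or 'negative'")
  structure(list(values = M, directions = directions,
                 degenerate = rep(FALSE, ncol(M))),
            class = "indicator_matrix")
}

#' @export
print.indicator_matrix <- function(x, ...) {
  cat("<indicator_matrix> ", nrow(x$values), " units x ", ncol(x$values),
      " indicators (", sum(x$directions == "negative"), " negative)\n", sep = "")
  invisible(x)
}

#' Direction-aware min-max normalisation
#'
#' Positive columns map to `(x - min) / (max - min)`, negative columns to
#' `(max - x) / (max - min)`; every value is then shifted to
#' `(v + eps) / (1 + eps)` so that exact zeros never reach the entropy logs.
#' Constant columns cannot be scaled: they are flagged degenerate (and later
#' receive zero entropy weight) rather than raising an error.
#'
#' @param M an [indicator_matrix()].
#' @param eps positive shift applied after scaling (default `1e-4`).
#' @return an `indicator_matrix` with values in `(0, 1]` and a `degenerate`
#'   logical flag per column.
#' @export
minmax_normalize <- function(M, eps = 1e-4) {
  assert_that(inherits(M, "indicator_matrix"), "M must be an indicator_matrix")
  assert_that(is_number(eps) && eps >= 0, "eps must be a nonnegative number")
  V <- M$values
  deg <- rep(FALSE, ncol(V))
  for (j in seq_len(ncol(V))) {
    rng <- range(V[, j])
    if (rng[1] == rng[2]) {
      deg[j] <- TRUE
      V[, j] <- 1  # harmless placeholder; weight forced to 0 downstream
      next
    }
    v0 <- if (M$directions[j] == "positive")
      (V[, j] - rng[1]) / (rng[2] - rng[1])
    else
      (rng[2] - V[, j]) / (rng[2] - rng[1])
    V[, j] <- (v0 + eps) / (1 + eps)
  }
  out <- M
  out$values <- V
  out$degenerate <- deg
  out
}

#' Entropy weights of an indicator matrix
#'
#' Information-entropy weighting: with column shares
#' `p_ij = v_ij / sum_i v_ij`, column entropy
#' `e_j = -(1/ln n) sum_i p_ij ln p_ij`, and weights
#' `w_j = (1 - e_j) / sum_j (1 - e_j)`. More cross-unit dispersion means lower
#' entropy and more weight. Degenerate (constant) columns get weight 0.
#'
#' @param M a normalised [indicator_matrix()] with strictly positive values
#'   (see [minmax_normalize()]).
#' @return numeric weight vector summing to 1.
#' @export
entropy_weights <- function(M) {
  assert_that(inherits(M, "indicator_matrix"), "M must be an indicator_matrix")
  V <- M$values
  assert_that(nrow(V) >= 2L, "entropy weighting needs at least 2 units")
  assert_that(all(V > 0), "normalised values must be strictly positive")
  n <- nrow(V)
  e <- vapply(seq_len(ncol(V)), function(j) {
    p <- V[, j] / sum(V[, j])
    -sum(p * log(p)) / log(n)
  }, numeric(1))
  d <- 1 - e
  d[M$degenerate] <- 0
  d[d < 0] <- 0  # guard against tiny negative rounding
  assert_that(sum(d) > 0, "all indicator columns are degenerate")
  w <- d / sum(d)
  names(w) <- colnames(V)
  w
}

#' Entropy-weighted composite score
#'
#' Convenience chain: min-max normalise, entropy-weight, and return the
#' per-unit weighted sum (a score in `(0, 1]`).
#'
#' @param M an [indicator_matrix()] of raw values.
#' @param eps normalisation shift, see [minmax_normalize()].
#' @return list with `scores` (one per unit) and `weights`.
#' @export
entropy_index <- function(M, eps = 1e-4) {
  N <- minmax_normalize(M, eps = eps)
  w <- entropy_weights(N)
  list(scores = as.vector(N$values %*% w), weights = w)
}

#' Coupled coordination degree of two subsystems
#'
#' The canonical two-system form: coupling
#' `C = 2 sqrt(u1 u2) / (u1 + u2)` (1 when the subsystems are equal, 0 when
#' either is 0), composite level `T = alpha u1 + beta u2`, coordination
#' `D = sqrt(C T)`.
#'
#' @param u1,u2 subsystem scores in `[0, 1]` (vectorised).
#' @param alpha,beta nonnegative weights with `alpha + beta = 1`
#'   (default 0.5 / 0.5).
#' @return object of class `coupling_result`: list of vectors `coupling_C`,
#'   `composite_T`, `coordination_D`.
#' @export
#' @examples
#' coupling_coordination(0.5, 0.5)$coordination_D  # sqrt(0.5)
coupling_coordination <- function(u1, u2, alpha = 0.5, beta = 0.5) {
  assert_that(all(u1 >= 0 & u1 <= 1) && all(u2 >= 0 & u2 <= 1),
              "subsystem scores must lie in [0, 1]")
  assert_that(alpha >= 0 && beta >= 0 && abs(alpha + beta - 1) < 1e-12,
              "alpha and beta must be nonnegative and sum to 1")
  s <- u1 + u2
  C <- ifelse(s == 0, 0, 2 * sqrt(u1 * u2) / s)
  T_ <- alpha * u1 + beta * u2
  D <- sqrt(C * T_)
  structure(list(coupling_C = C, composite_T = T_, coordination_D = D),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat("<coupling_result> n =", length(x$coupling_C),
      "| mean C =", round(mean(x$coupling_C), 4),
      "T =", round(mean(x$composite_T), 4),
      "D =", round(mean(x$coordination_D), 4), "\n")
  invisible(x)
}

#' Composite digital-infrastructure index
#'
#' Expert-weighted aggregate of the information (INFI), convergence (CI) and
#' innovation (INNI) sub-indices; the shipped default weights are
#' `(0.4, 0.3, 0.3)`.
#'
#' @param infi,ci,inni sub-indices in `[0, 1]` (vectorised).
#' @param weights length-3 nonnegative vector summing to 1 for
#'   (information, convergence, innovation).
#' @return data.frame with columns `infi`, `ci`, `inni`, `ndi`.
#' @export
#' @examples
#' composite_ndi(1, 0, 0)$ndi  # 0.4
composite_ndi <- function(infi, ci, inni, weights = c(0.4, 0.3, 0.3)) {
  assert_that(length(weights) == 3L && all(weights >= 0),
              "weights must be 3 nonnegative numbers")
  assert_that(abs(sum(weights) - 1) < 1e-12, "weights must sum to 1")
  assert_that(all(infi >= 0 & infi <= 1) && all(ci >= 0 & ci <= 1) &&
                all(inni >= 0 & inni <= 1),
              "sub-indices must lie in [0, 1]")
  data.frame(infi = infi, ci = ci, inni = inni,
             ndi = weights[1] * infi + weights[2] * ci + weights[3] * inni)
}

#' Build the composite index from a raw indicator panel
#'
#' Assembles the three sub-dimensions from indicator blocks: entropy-weighted
#' scores for the information and innovation blocks; for convergence, entropy
#' scores of the traditional-infrastructure and informatisation blocks are
#' combined through the coupled coordination degree. Weighting is pooled
#' across the whole panel so index levels stay comparable over time.
#'
#' @param indicators data.frame with identifier columns (e.g. unit, year)
#'   plus raw indicator columns.
#' @param blocks named list with character vectors `information`,
#'   `traditional`, `informatization`, `innovation` naming the indicator
#'   columns of each block.
#' @param weights expert weights passed to [composite_ndi()].
#' @param eps normalisation shift.
#' @param alpha,beta coupling weights for the convergence sub-index.
#' @return data.frame: identifier columns plus `infi`, `ci`, `inni`, `ndi`.
#' @export
build_ndi <- function(indicators, blocks, weights = c(0.4, 0.3, 0.3),
                      eps = 1e-4, alpha = 0.5, beta = 0.5) {
  need <- c("information", "traditional", "informatization", "innovation")
  assert_that(all(need %in% names(blocks)),
              paste("blocks must name:", paste(need, collapse = ", ")))
  all_cols <- unlist(blocks[need], use.names = FALSE)
  missing_cols <- setdiff(all_cols, names(indicators))
  assert_that(length(missing_cols) == 0L,
              paste("indicator columns not found:",
                    paste(missing_cols, collapse = ", ")))
  blk_score <- function(cols) {
    entropy_index(indicator_matrix(indicators[cols]), eps = eps)$scores
  }
  infi <- blk_score(blocks$information)
  trad <- blk_score(blocks$traditional)
  info_deg <- blk_score(blocks$informatization)
  ci <- coupling_coordination(trad, info_deg, alpha, beta)$coordination_D
  inni <- blk_score(blocks$innovation)
  idcols <- setdiff(names(indicators), all_cols)
  cbind(indicators[idcols], composite_ndi(infi, ci, inni, weights))
}
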