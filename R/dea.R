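## Super-efficiency SBM-DEA with undesirable outputs.
##
## Each decision-making unit (DMU, here a province-year) is scored with the
## slacks-based measure: the standard SBM program first, and -- for units on
## the frontier -- the super-efficiency program that rebuilds the frontier
## without the evaluated unit, so efficient units can score above 1. Both
## fractional programs are linearised with the Charnes-Cooper substitution
## and solved with the package's dense simplex.

#' Construct a DMU set for DEA scoring
#'
#' @param data data.frame, one row per decision-making unit; all role columns
#'   must be strictly positive (SBM slack ratios are undefined at zero).
#' @param inputs,good_outputs,bad_outputs character vectors naming the input,
#'   desired-output and undesired-output columns; `bad_outputs` may be empty.
#' @param id name of the identifier column (default `"id"`); created from row
#'   numbers when absent.
#' @param year optional name of a year column used by
#'   [score_panel()]'s by-year frontier.
#' @return object of class `dmu_set`.
#' @export
#' @examples
#' d <- data.frame(id = c("A", "B"), x = c(1, 1), y = c(2, 1))
#' dmu_set(d, inputs = "x", good_outputs = "y")
dmu_set <- function(data, inputs, good_outputs, bad_outputs = character(0),
                    id = "id", year = NULL) {
  assert_that(is.data.frame(data) && nrow(data) >= 1L, "data must be a data.frame")
  assert_that(length(inputs) >= 1L, "at least one input is required")
  assert_that(length(good_outputs) >= 1L, "at least one desired output is required")
  cols <- c(inputs, good_outputs, bad_outputs)
  missing_cols <- setdiff(cols, names(data))
  assert_that(length(missing_cols) == 0L,
              paste("columns not found:", paste(missing_cols, collapse = ", ")))
  vals <- as.matrix(data[cols])
  assert_that(is.numeric(vals) && all(is.finite(vals)),
              "all DEA columns must be finite numerics")
  assert_that(all(vals > 0),
              "all inputs and outputs must be strictly positive for the SBM")
  ids <- if (id %in% names(data)) as.character(data[[id]]) else
    as.character(seq_len(nrow(data)))
  assert_that(!anyDuplicated(ids), "DMU ids must be unique")
  yr <- if (!is.null(year)) data[[year]] else NULL
  structure(list(
    id = ids,
    X = t(as.matrix(data[inputs])),          # m x n
    Yd = t(as.matrix(data[good_outputs])),   # r1 x n
    Yu = if (length(bad_outputs)) t(as.matrix(data[bad_outputs]))
         else matrix(numeric(0), 0, nrow(data)),
    year = yr,
    inputs = inputs, good_outputs = good_outputs, bad_outputs = bad_outputs
  ), class = "dmu_set")
}

#' @export
print.dmu_set <- function(x, ...) {
  cat("<dmu_set> ", ncol(x$X), " DMUs: ", nrow(x$X), " input(s), ",
      nrow(x$Yd), " desired, ", nrow(x$Yu), " undesired output(s)\n", sep = "")
  invisible(x)
}

n_dmus <- function(d) ncol(d$X)

subset_dmus <- function(d, keep) {
  d$id <- d$id[keep]
  d$X <- d$X[, keep, drop = FALSE]
  d$Yd <- d$Yd[, keep, drop = FALSE]
  d$Yu <- d$Yu[, keep, drop = FALSE]
  if (!is.null(d$year)) d$year <- d$year[keep]
  d
}

## standard SBM program (Charnes-Cooper form); reference set may or may not
## contain the evaluated unit. Variables: t, Lambda(n_ref), S-(m), Sd(r1), Su(r2).
sbm_standard_lp <- function(k, d, rts = c("crs", "vrs"), exclude = FALSE) {
  rts <- match.arg(rts)
  m <- nrow(d$X); r1 <- nrow(d$Yd); r2 <- nrow(d$Yu); rr <- r1 + r2
  xk <- d$X[, k]; ydk <- d$Yd[, k]
  yuk <- if (r2) d$Yu[, k] else numeric(0)
  ref <- if (exclude) setdiff(seq_len(n_dmus(d)), k) else seq_len(n_dmus(d))
  Xr <- d$X[, ref, drop = FALSE]
  Ydr <- d$Yd[, ref, drop = FALSE]
  Yur <- d$Yu[, ref, drop = FALSE]
  n <- length(ref)
  nv <- 1L + n + m + r1 + r2
  cvec <- c(1, rep(0, n), -1 / (m * xk), rep(0, r1 + r2))
  rows <- 1L + m + r1 + r2 + (rts == "vrs")
  Aeq <- matrix(0, rows, nv); beq <- numeric(rows)
  Aeq[1L, ] <- c(1, rep(0, n + m), 1 / (rr * ydk), if (r2) 1 / (rr * yuk))
  beq[1L] <- 1
  r <- 1L
  for (i in seq_len(m)) {
    r <- r + 1L
    Aeq[r, 1L] <- xk[i]; Aeq[r, 1L + seq_len(n)] <- -Xr[i, ]
    Aeq[r, 1L + n + i] <- -1
  }
  for (s in seq_len(r1)) {
    r <- r + 1L
    Aeq[r, 1L] <- ydk[s]; Aeq[r, 1L + seq_len(n)] <- -Ydr[s, ]
    Aeq[r, 1L + n + m + s] <- 1
  }
  if (r2) for (q in seq_len(r2)) {
    r <- r + 1L
    Aeq[r, 1L] <- yuk[q]; Aeq[r, 1L + seq_len(n)] <- -Yur[q, ]
    Aeq[r, 1L + n + m + r1 + q] <- -1
  }
  if (rts == "vrs") {
    r <- r + 1L
    Aeq[r, 1L] <- -1; Aeq[r, 1L + seq_len(n)] <- 1
  }
  sol <- lp_solve(cvec, Aeq = Aeq, beq = beq)
  if (sol$status != "optimal") return(list(status = sol$status))
  tt <- sol$x[1L]
  lambda <- numeric(n_dmus(d))
  lambda[ref] <- sol$x[1L + seq_len(n)] / tt
  sm <- sol$x[1L + n + seq_len(m)] / tt
  sd <- sol$x[1L + n + m + seq_len(r1)] / tt
  su <- if (r2) sol$x[1L + n + m + r1 + seq_len(r2)] / tt else numeric(0)
  list(status = "optimal", rho = sol$value, lambda = lambda,
       projection = list(inputs = xk - sm, good_outputs = ydk + sd,
                         bad_outputs = if (r2) yuk - su else numeric(0)))
}

## super-efficiency SBM program (evaluated unit excluded; projection point is
## weakly worse than the unit). Variables: t, Lambda(n-1), xt(m), ydt(r1), yut(r2).
sbm_super_lp <- function(k, d, rts = c("crs", "vrs")) {
  rts <- match.arg(rts)
  m <- nrow(d$X); r1 <- nrow(d$Yd); r2 <- nrow(d$Yu); rr <- r1 + r2
  xk <- d$X[, k]; ydk <- d$Yd[, k]
  yuk <- if (r2) d$Yu[, k] else numeric(0)
  ref <- setdiff(seq_len(n_dmus(d)), k)
  Xr <- d$X[, ref, drop = FALSE]
  Ydr <- d$Yd[, ref, drop = FALSE]
  Yur <- d$Yu[, ref, drop = FALSE]
  n <- length(ref)
  nv <- 1L + n + m + r1 + r2
  ix <- function(i) 1L + n + i            # xt columns
  iyd <- function(s) 1L + n + m + s       # ydt columns
  iyu <- function(q) 1L + n + m + r1 + q  # yut columns
  cvec <- numeric(nv); cvec[ix(seq_len(m))] <- 1 / (m * xk)
  # normalisation
  e1 <- numeric(nv)
  e1[iyd(seq_len(r1))] <- 1 / (rr * ydk)
  if (r2) e1[iyu(seq_len(r2))] <- 1 / (rr * yuk)
  Aeq <- rbind(e1); beq <- 1
  if (rts == "vrs") {
    row <- numeric(nv); row[1L] <- -1; row[1L + seq_len(n)] <- 1
    Aeq <- rbind(Aeq, row); beq <- c(beq, 0)
  }
  Age <- NULL; bge <- NULL; Ale <- NULL; ble <- NULL
  for (i in seq_len(m)) {
    row <- numeric(nv); row[ix(i)] <- 1; row[1L + seq_len(n)] <- -Xr[i, ]
    Age <- rbind(Age, row)                         # xt >= X lambda
    row <- numeric(nv); row[ix(i)] <- 1; row[1L] <- -xk[i]
    Age <- rbind(Age, row)                         # xt >= t xk
  }
  bge <- rep(0, 2L * m)
  for (s in seq_len(r1)) {
    row <- numeric(nv); row[iyd(s)] <- 1; row[1L + seq_len(n)] <- -Ydr[s, ]
    Ale <- rbind(Ale, row)                         # ydt <= Yd lambda
    row <- numeric(nv); row[iyd(s)] <- 1; row[1L] <- -ydk[s]
    Ale <- rbind(Ale, row)                         # ydt <= t ydk
  }
  if (r2) for (q in seq_len(r2)) {
    row <- numeric(nv); row[iyu(q)] <- 1; row[1L + seq_len(n)] <- -Yur[q, ]
    Age <- rbind(Age, row); bge <- c(bge, 0)       # yut >= Yu lambda
    row <- numeric(nv); row[iyu(q)] <- 1; row[1L] <- -yuk[q]
    Ale <- rbind(Ale, row)                         # yut <= t yuk
  }
  ble <- rep(0, nrow(Ale))
  sol <- lp_solve(cvec, Aeq = Aeq, beq = beq, Age = Age, bge = bge,
                  Ale = Ale, ble = ble)
  if (sol$status != "optimal") return(list(status = "infeasible_super"))
  tt <- sol$x[1L]
  lambda <- numeric(n_dmus(d))
  lambda[ref] <- sol$x[1L + seq_len(n)] / tt
  list(status = "optimal", rho = sol$value, lambda = lambda,
       projection = list(inputs = sol$x[ix(seq_len(m))] / tt,
                         good_outputs = sol$x[iyd(seq_len(r1))] / tt,
                         bad_outputs = if (r2) sol$x[iyu(seq_len(r2))] / tt
                                       else numeric(0)))
}

#' Super-efficiency SBM score of one DMU
#'
#' Solves the standard slacks-based measure with undesirable outputs for unit
#' `k`. Units below the frontier keep their standard score (for them the
#' evaluated unit never enters its own optimal reference basis, so exclusion
#' changes nothing); frontier units are re-scored against the reference set
#' with themselves excluded, which allows scores above 1.
#'
#' @param k index (or id) of the evaluated unit within `dmus`.
#' @param dmus a [dmu_set()].
#' @param rts returns-to-scale assumption, `"crs"` or `"vrs"`.
#' @param tol numerical tolerance used to call a unit efficient.
#' @return object of class `efficiency_result`: list with `id`, `score`,
#'   `rts`, `lambdas`, `status` (`"optimal"`, `"infeasible_super"`) and
#'   `projection`. Under VRS the super-efficiency program can be infeasible;
#'   then `score` is `NA` and `status = "infeasible_super"`.
#' @export
#' @examples
#' d <- dmu_set(data.frame(id = c("A", "B"), x = c(1, 1), y = c(2, 1)),
#'              inputs = "x", good_outputs = "y")
#' sbm_super_efficiency("B", d)$score  # 0.5
sbm_super_efficiency <- function(k, dmus, rts = c("crs", "vrs"), tol = 1e-7) {
  rts <- match.arg(rts)
  assert_that(inherits(dmus, "dmu_set"), "dmus must be a dmu_set")
  if (is.character(k)) {
    k <- match(k, dmus$id)
    assert_that(!is.na(k), "unknown DMU id")
  }
  assert_that(n_dmus(dmus) >= 3L,
              "super-efficiency needs at least 2 reference units besides the evaluated one")
  std <- sbm_standard_lp(k, dmus, rts = rts, exclude = FALSE)
  assert_that(std$status == "optimal",
              paste("standard SBM did not solve:", std$status),
              class = "agrecoeff_solver_error")
  res <- list(id = dmus$id[k], rts = rts)
  if (std$rho < 1 - tol) {
    res$score <- std$rho
    res$lambdas <- std$lambda
    res$status <- "optimal"
    res$projection <- std$projection
  } else {
    sup <- sbm_super_lp(k, dmus, rts = rts)
    if (sup$status == "optimal") {
      res$score <- sup$rho
      res$lambdas <- sup$lambda
      res$status <- "optimal"
      res$projection <- sup$projection
    } else {
      res$score <- NA_real_
      res$lambdas <- std$lambda
      res$status <- "infeasible_super"
      res$projection <- std$projection
    }
  }
  res$standard_score <- std$rho
  class(res) <- "efficiency_result"
  res
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat("<efficiency_result> DMU ", x$id, " [", toupper(x$rts), "]: score = ",
      ifelse(is.na(x$score), "NA", format(round(x$score, 4), nsmall = 4)),
      " (", x$status, ")\n", sep = "")
  invisible(x)
}

#' Score every DMU of a panel
#'
#' @param dmus a [dmu_set()]; needs a `year` column for `frontier = "by_year"`.
#' @param rts `"crs"` or `"vrs"`.
#' @param frontier `"pooled"` (all units share one frontier; default, so score
#'   levels are comparable across years) or `"by_year"` (each year scored
#'   against its own cross-section).
#' @param super_infeasible what to do when the VRS super-efficiency program is
#'   infeasible for a frontier unit: `"standard"` (default) substitutes the
#'   standard inclusive score of 1 with a warning, `"na"` leaves `NA`.
#' @return data.frame with one row per DMU: `id`, `year` (if present),
#'   `score` (full precision), `rts`, `status`.
#' @export
score_panel <- function(dmus, rts = c("crs", "vrs"),
                        frontier = c("pooled", "by_year"),
                        super_infeasible = c("standard", "na")) {
  rts <- match.arg(rts)
  frontier <- match.arg(frontier)
  super_infeasible <- match.arg(super_infeasible)
  assert_that(inherits(dmus, "dmu_set"), "dmus must be a dmu_set")
  groups <- if (frontier == "by_year") {
    assert_that(!is.null(dmus$year), "by-year frontier needs a year column")
    split(seq_len(n_dmus(dmus)), dmus$year)
  } else list(pooled = seq_len(n_dmus(dmus)))
  small <- names(groups)[vapply(groups, length, 1L) < 3L]
  assert_that(length(small) == 0L,
              paste("frontier group(s) with fewer than 3 DMUs:",
                    paste(small, collapse = ", ")))
  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    sub <- subset_dmus(dmus, idx)
    rows <- lapply(seq_along(idx), function(j) {
      r <- sbm_super_efficiency(j, sub, rts = rts)
      score <- r$score
      status <- r$status
      if (is.na(score) && super_infeasible == "standard") {
        warning("VRS super-efficiency infeasible for DMU ", r$id,
                "; substituting the standard SBM score", call. = FALSE)
        score <- r$standard_score
      }
      data.frame(id = r$id, score = score, status = status,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    if (!is.null(dmus$year)) res$year <- dmus$year[idx]
    out[[g]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$rts <- rts
  res[match(dmus$id, res$id), , drop = FALSE]
}
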