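## Panel regressions: pooled OLS baseline, Hansen-style threshold model with
## residual-bootstrap existence tests, interaction moderation with time fixed
## effects, one-period-lag robustness, censored Tobit, 2SLS instrumental
## variables and subsample splits. All fits return a common `aee_fit` record
## whose t-values are coefficient/SE by construction.

controls_default <- c("AED", "PS", "ADR", "RHC", "FSA")

#' Two-sided winsorization
#'
#' Values below the `frac` quantile are set to that quantile, values above the
#' `1 - frac` quantile to that quantile (the "1% tailing" convention at
#' `frac = 0.01`). Idempotent: winsorizing twice equals winsorizing once.
#'
#' @param x numeric vector.
#' @param frac fraction clipped from each tail, in `[0, 0.5)`.
#' @return winsorized vector.
#' @export
winsorize <- function(x, frac = 0.01) {
  assert_that(is_number(frac) && frac >= 0 && frac < 0.5,
              "frac must lie in [0, 0.5)")
  if (frac == 0) return(x)
  q <- stats::quantile(x, c(frac, 1 - frac), na.rm = TRUE, type = 1)
  pmin(pmax(x, q[1]), q[2])
}

outcome_col <- function(outcome) {
  switch(match.arg(outcome, c("vrs", "crs")), vrs = "aee_vrs", crs = "aee_crs")
}

## winsorize the continuous model variables, pooled across the panel
winsorize_panel <- function(panel, cols, frac) {
  if (frac > 0) for (cl in cols) panel[[cl]] <- winsorize(panel[[cl]], frac)
  panel
}

check_full_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop_agrecoeff(paste("design matrix is rank deficient; collinear column(s):",
                         paste(bad, collapse = ", ")),
                   "agrecoeff_singularity_error")
  }
  invisible(TRUE)
}

new_aee_fit <- function(coef, se, n_obs, model, extra = list()) {
  stopifnot(length(coef) == length(se))
  out <- c(list(coefficients = coef, se = se, t = coef / se,
                n_obs = n_obs, model = model), extra)
  class(out) <- "aee_fit"
  out
}

#' @export
print.aee_fit <- function(x, ...) {
  cat("<aee_fit> model:", x$model, " N =", x$n_obs, "\n")
  p <- 2 * stats::pnorm(-abs(x$t))
  tab <- data.frame(coef = round(x$coefficients, 4),
                    se = round(x$se, 4),
                    t = round(x$t, 2),
                    sig = stars(p))
  print(tab)
  invisible(x)
}

## internal least-squares engine returning an aee_fit
ols_engine <- function(y, X, model, robust = FALSE, lm_fit = NULL) {
  check_full_rank(X)
  fit <- stats::lm.fit(X, y)
  n <- length(y); k <- ncol(X)
  res <- fit$residuals
  XtXinv <- chol2inv(chol(crossprod(X)))
  if (robust) {
    # HC1 heteroskedasticity-robust covariance
    meat <- crossprod(X * res)
    V <- XtXinv %*% meat %*% XtXinv * n / (n - k)
  } else {
    V <- XtXinv * sum(res^2) / (n - k)
  }
  se <- sqrt(diag(V))
  names(se) <- colnames(X)
  coefs <- fit$coefficients
  new_aee_fit(coefs, se, n, model,
              extra = list(residuals = res, fitted = fit$fitted.values,
                           sigma = sqrt(sum(res^2) / (n - k)), vcov = V,
                           robust = robust))
}

#' Pooled OLS baseline regression
#'
#' Regresses eco-efficiency on one index regressor plus the standard control
#' set, after pooled two-sided winsorization of the continuous variables.
#' Conventional or HC1 heteroskedasticity-robust standard errors.
#'
#' @param panel data.frame with the panel columns (see
#'   [generate_regression_panel()]).
#' @param outcome `"vrs"` or `"crs"` eco-efficiency score.
#' @param regressor `"ndi"`, `"infi"`, `"ci"` or `"inni"`.
#' @param winsor winsorization fraction in `[0, 0.05]` (default 0.01).
#' @param robust use HC1 robust standard errors.
#' @param controls control column names.
#' @return an `aee_fit`.
#' @export
pooled_ols <- function(panel, outcome = c("vrs", "crs"),
                       regressor = c("ndi", "infi", "ci", "inni"),
                       winsor = 0.01, robust = FALSE,
                       controls = controls_default) {
  ycol <- outcome_col(outcome)
  regressor <- match.arg(regressor)
  assert_that(nrow(panel) >= 30L, "pooled OLS needs at least 30 rows")
  assert_that(is_number(winsor) && winsor >= 0 && winsor <= 0.05,
              "winsor must lie in [0, 0.05]")
  panel <- winsorize_panel(panel, c(ycol, regressor, controls), winsor)
  X <- cbind("(Intercept)" = 1,
             as.matrix(panel[c(regressor, controls)]))
  ols_engine(panel[[ycol]], X, model = paste0("pooled_ols[", regressor, "->",
                                              ycol, "]"), robust = robust)
}

## two-regime design columns for a threshold candidate
regime_design <- function(panel, thr_var, theta, controls) {
  v <- panel[[thr_var]]
  cbind("(Intercept)" = 1,
        reg_low = v * (v <= theta),
        reg_high = v * (v > theta),
        as.matrix(panel[controls]))
}

## Fast SSR machinery for the threshold grid search.
##
## By Frisch-Waugh, after residualising y, the threshold variable v and the
## candidate regime columns v*1(v <= theta_j) against [1, controls], the SSR
## of every candidate two-regime (or, given a first threshold, three-regime)
## fit reduces to a 2x2 / 3x3 normal-equation solve with Gram entries that can
## be precomputed once. This turns each bootstrap replicate into one O(n * G)
## crossproduct instead of G full regressions.
threshold_engine <- function(v, W, grid) {
  qrW <- qr(W)
  rv <- qr.resid(qrW, v)
  VL <- vapply(grid, function(th) v * (v <= th), numeric(length(v)))
  RVL <- qr.resid(qrW, VL)
  G11 <- sum(rv^2)
  Gj <- as.vector(crossprod(RVL, rv))
  D <- crossprod(RVL)
  list(qrW = qrW, rv = rv, RVL = RVL, G11 = G11, Gj = Gj, D = D, grid = grid)
}

## SSR of the no-threshold model and of every single-threshold candidate
engine_ssr1 <- function(eng, y) {
  ry <- qr.resid(eng$qrW, y)
  ryy <- sum(ry^2)
  a <- sum(eng$rv * ry)
  cv <- as.vector(crossprod(eng$RVL, ry))
  ssr0 <- ryy - a^2 / eng$G11
  Djj <- diag(eng$D)
  det <- eng$G11 * Djj - eng$Gj^2
  ssr <- ryy - (Djj * a^2 - 2 * eng$Gj * a * cv + eng$G11 * cv^2) / det
  ssr[det <= 1e-10 * eng$G11 * pmax(Djj, 1e-300)] <- ssr0  # degenerate split
  list(ssr0 = ssr0, ssr = ssr, ryy = ryy, a = a, cv = cv)
}

## SSR of the best two-threshold model with the first threshold fixed at
## index i1 of the grid; regressors are v plus the v*1(v <= .) columns at the
## sorted candidate pair, a rank-3 system after residualisation
engine_ssr2 <- function(eng, s1, i1) {
  n_g <- length(eng$grid)
  best <- Inf; i2_best <- NA_integer_
  for (i2 in seq_len(n_g)) {
    if (i2 == i1) next
    lohi <- sort(c(i1, i2))
    idx <- c(lohi[1], lohi[2])
    G <- rbind(c(eng$G11, eng$Gj[idx]),
               cbind(eng$Gj[idx], eng$D[idx, idx]))
    rhs <- c(s1$a, s1$cv[idx])
    b <- tryCatch(solve(G, rhs), error = function(e) NULL)
    if (is.null(b)) next
    ssr <- s1$ryy - sum(b * rhs)
    if (ssr < best) { best <- ssr; i2_best <- i2 }
  }
  list(ssr = best, i2 = i2_best)
}

#' Threshold regression with bootstrap existence test
#'
#' Piecewise-linear (Hansen-type) panel threshold model: the threshold
#' variable enters with one slope below and another above an estimated cut
#' point. The cut point is found by least-squares grid search over the
#' trimmed unique values of the threshold variable; the existence F statistic
#' `F = n (SSR0 - SSR1) / SSR1` is compared against a fixed-regressor residual
#' bootstrap null distribution. Testing proceeds sequentially (single, then
#' double threshold) and stops at the first insignificant stage.
#'
#' @param panel panel data.frame.
#' @param outcome `"vrs"` or `"crs"`.
#' @param thr_var threshold variable column (default `"inni"`, the innovation
#'   sub-index).
#' @param n_boot bootstrap replications (>= 100; default 300).
#' @param trim fraction of candidate values trimmed from each tail
#'   (default 0.01).
#' @param max_thresholds maximum number of thresholds tested sequentially
#'   (default 2).
#' @param seed RNG seed for the bootstrap.
#' @param level significance level of the sequential decision (default 0.05).
#' @param controls control column names.
#' @return object of class `threshold_fit`: `theta_hat`, `regime_coefs`
#'   (below/above slopes with SEs and t), `f_stat`, `boot_p`, `n_boot`,
#'   `grid`, `n_thresholds` accepted, and per-stage `stages` details.
#' @export
threshold_fit <- function(panel, outcome = c("vrs", "crs"), thr_var = "inni",
                          n_boot = 300L, trim = 0.01, max_thresholds = 2L,
                          seed = 1L, level = 0.05,
                          controls = controls_default) {
  ycol <- outcome_col(outcome)
  assert_that(n_boot >= 100L, "n_boot must be at least 100")
  assert_that(is_number(trim) && trim >= 0 && trim < 0.5,
              "trim must lie in [0, 0.5)")
  v <- panel[[thr_var]]
  assert_that(!is.null(v), paste("threshold variable", thr_var, "not found"))
  qs <- stats::quantile(v, c(trim, 1 - trim), type = 7)
  grid <- sort(unique(v[v >= qs[1] & v <= qs[2]]))
  # candidates must leave observations on both sides
  grid <- grid[grid > min(v) & grid < max(v)]
  assert_that(length(grid) >= 20L,
              "threshold variable has fewer than 20 distinct values after trimming")
  y <- panel[[ycol]]
  n <- length(y)

  W <- cbind("(Intercept)" = 1, as.matrix(panel[controls]))
  eng <- threshold_engine(v, W, grid)
  s1 <- engine_ssr1(eng, y)
  i_hat <- which.min(s1$ssr)
  theta_hat <- grid[i_hat]
  ssr0 <- s1$ssr0
  ssr1 <- s1$ssr[i_hat]
  f_stat <- n * (ssr0 - ssr1) / ssr1

  X1 <- regime_design(panel, thr_var, theta_hat, controls)
  fit1 <- ols_engine(y, X1, model = "threshold[1]")

  X0 <- cbind(W[, 1, drop = FALSE], thr = v, W[, -1, drop = FALSE])
  fitted0 <- y - stats::lm.fit(X0, y)$residuals
  boot_p <- with_seed(seed, {
    e <- fit1$residuals
    f_boot <- vapply(seq_len(n_boot), function(b) {
      ystar <- fitted0 + sample(e, n, replace = TRUE)
      sb <- engine_ssr1(eng, ystar)
      smin <- min(sb$ssr)
      n * (sb$ssr0 - smin) / smin
    }, numeric(1))
    mean(f_boot >= f_stat)
  })

  stages <- list(list(theta = theta_hat, f_stat = f_stat, boot_p = boot_p))
  n_thr <- if (boot_p <= level) 1L else 0L

  if (n_thr == 1L && max_thresholds >= 2L) {
    # second threshold conditional on the first (three regimes)
    d2 <- engine_ssr2(eng, s1, i_hat)
    theta2 <- grid[d2$i2]
    ssr2 <- d2$ssr
    f2 <- n * (ssr1 - ssr2) / ssr2
    ths <- sort(c(theta_hat, theta2))
    X2 <- cbind("(Intercept)" = 1,
                r1 = v * (v <= ths[1]),
                r2 = v * (v > ths[1] & v <= ths[2]),
                r3 = v * (v > ths[2]),
                as.matrix(panel[controls]))
    p2 <- with_seed(seed + 1L, {
      fitted1 <- fit1$fitted
      e2 <- stats::lm.fit(X2, y)$residuals
      fb <- vapply(seq_len(n_boot), function(b) {
        ystar <- fitted1 + sample(e2, n, replace = TRUE)
        sb <- engine_ssr1(eng, ystar)
        ib <- which.min(sb$ssr)
        sb1 <- sb$ssr[ib]
        sb2 <- engine_ssr2(eng, sb, ib)$ssr
        n * (sb1 - sb2) / sb2
      }, numeric(1))
      mean(fb >= f2)
    })
    stages[[2]] <- list(theta = theta2, f_stat = f2, boot_p = p2)
    if (p2 <= level) n_thr <- 2L
  }

  structure(list(
    theta_hat = theta_hat,
    regime_coefs = fit1$coefficients[c("reg_low", "reg_high")],
    regime_se = fit1$se[c("reg_low", "reg_high")],
    regime_t = fit1$t[c("reg_low", "reg_high")],
    f_stat = f_stat, boot_p = boot_p, n_boot = as.integer(n_boot),
    grid = grid, n_thresholds = n_thr, stages = stages,
    fit = fit1, n_obs = n
  ), class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat("<threshold_fit> theta =", round(x$theta_hat, 4),
      "| F =", round(x$f_stat, 2), " bootstrap p =", round(x$boot_p, 4),
      "(", x$n_boot, "reps ) thresholds accepted:", x$n_thresholds, "\n")
  cat("  slope below:", round(x$regime_coefs[1], 4),
      "( t =", round(x$regime_t[1], 2), ")\n")
  cat("  slope above:", round(x$regime_coefs[2], 4),
      "( t =", round(x$regime_t[2], 2), ")\n")
  invisible(x)
}

#' Moderation (interaction) regression
#'
#' Fits eco-efficiency on the index, the moderator (urbanisation level),
#' their interaction and the controls, optionally with year fixed effects.
#' The interaction coefficient is the moderation effect; the marginal effect
#' of the index at moderator level `m` is `alpha1 + alpha3 * m` (see
#' [marginal_effect()]).
#'
#' @param panel panel data.frame.
#' @param outcome `"vrs"` or `"crs"`.
#' @param regressor index column (default `"ndi"`).
#' @param moderator moderator column (default `"lu"`).
#' @param time_fe include year indicator variables (default TRUE).
#' @param winsor winsorization fraction.
#' @param controls control column names.
#' @return an `aee_fit`; the interaction coefficient is named
#'   `"<regressor>:<moderator>"`.
#' @export
moderation_fit <- function(panel, outcome = c("vrs", "crs"),
                           regressor = "ndi", moderator = "lu",
                           time_fe = TRUE, winsor = 0,
                           controls = controls_default) {
  ycol <- outcome_col(outcome)
  panel <- winsorize_panel(panel, c(ycol, regressor, moderator, controls),
                           winsor)
  inter <- panel[[regressor]] * panel[[moderator]]
  X <- cbind("(Intercept)" = 1,
             as.matrix(panel[c(regressor, moderator)]),
             inter,
             as.matrix(panel[controls]))
  colnames(X)[4] <- paste0(regressor, ":", moderator)
  if (time_fe) {
    yrs <- sort(unique(panel$year))
    assert_that(length(yrs) >= 2L, "time fixed effects need at least 2 years")
    D <- stats::model.matrix(~ factor(panel$year))[, -1, drop = FALSE]
    colnames(D) <- paste0("year", yrs[-1])
    X <- cbind(X, D)
  }
  ols_engine(panel[[ycol]], X,
             model = paste0("moderation[", regressor, "x", moderator,
                            if (time_fe) ", time FE" else "", "]"))
}

#' Marginal effect of the index at a moderator level
#'
#' @param fit an `aee_fit` from [moderation_fit()].
#' @param at moderator value(s).
#' @param regressor,moderator names used in the fit.
#' @return numeric vector `alpha1 + alpha3 * at`.
#' @export
marginal_effect <- function(fit, at, regressor = "ndi", moderator = "lu") {
  a1 <- fit$coefficients[[regressor]]
  a3 <- fit$coefficients[[paste0(regressor, ":", moderator)]]
  a1 + a3 * at
}

#' Pooled OLS with the index lagged one year
#'
#' Replaces the index by its within-unit one-year lag; the first year of each
#' unit is dropped, so a balanced `n_units x n_years` panel yields
#' `n_units x (n_years - 1)` observations.
#'
#' @inheritParams pooled_ols
#' @return an `aee_fit` (the lagged regressor keeps its column name).
#' @export
lagged_regressor_fit <- function(panel, outcome = c("vrs", "crs"),
                                 regressor = "ndi", winsor = 0.01,
                                 robust = FALSE, controls = controls_default) {
  assert_that(all(c("unit", "year") %in% names(panel)),
              "panel needs 'unit' and 'year' columns")
  panel <- panel[order(panel$unit, panel$year), , drop = FALSE]
  yrs_per_unit <- tapply(panel$year, panel$unit, length)
  assert_that(all(yrs_per_unit >= 2L),
              "lagging needs at least 2 years per unit")
  lagged <- stats::ave(panel[[regressor]], panel$unit,
                       FUN = function(x) c(NA, x[-length(x)]))
  panel[[regressor]] <- lagged
  panel <- panel[!is.na(lagged), , drop = FALSE]
  fit <- pooled_ols(panel, outcome = outcome, regressor = regressor,
                    winsor = winsor, robust = robust, controls = controls)
  fit$model <- sub("pooled_ols", "lagged_ols", fit$model)
  fit
}

#' Tobit censoring specification
#'
#' @param lower lower censoring bound (default 0).
#' @param upper upper bound (default `Inf`).
#' @return list of class `tobit_spec`.
#' @export
tobit_spec <- function(lower = 0, upper = Inf) {
  assert_that(lower < upper, "lower bound must be below upper bound")
  structure(list(lower = lower, upper = upper), class = "tobit_spec")
}

#' Censored (Tobit) regression
#'
#' Censored-normal maximum likelihood for an outcome observed only above a
#' lower bound (and optionally below an upper bound): latent
#' `y* = X beta + u`, `u ~ N(0, sigma^2)`, observed `y = max(y*, lower)`.
#' Estimated with [survival::survreg()] (gaussian, interval coding), which is
#' exactly this likelihood; with no censored observations the coefficients
#' coincide with OLS.
#'
#' @param panel panel data.frame.
#' @param spec a [tobit_spec()].
#' @param outcome `"vrs"` or `"crs"`.
#' @param regressor index column.
#' @param winsor winsorization fraction (applied to regressors only; the
#'   censored outcome is never altered).
#' @param controls control column names.
#' @return an `aee_fit` with extras `sigma`, `n_censored`, `loglik`.
#' @export
tobit_fit <- function(panel, spec = tobit_spec(), outcome = c("vrs", "crs"),
                      regressor = "ndi", winsor = 0,
                      controls = controls_default) {
  ycol <- outcome_col(outcome)
  panel <- winsorize_panel(panel, c(regressor, controls), winsor)
  y <- panel[[ycol]]
  lo <- spec$lower; hi <- spec$upper
  cens_lo <- y <= lo + 1e-12
  cens_hi <- is.finite(hi) & y >= hi - 1e-12
  assert_that(sum(!cens_lo & !cens_hi) >= 10L,
              "need at least 10 uncensored observations",
              class = "agrecoeff_estimation_error")
  # interval coding: left-censored rows are (-Inf, lo]; right-censored [hi, Inf)
  t1 <- ifelse(cens_lo, lo, ifelse(cens_hi, hi, y))
  t2 <- ifelse(cens_lo, NA, ifelse(cens_hi, NA, y))
  ev <- ifelse(cens_lo, 2L, ifelse(cens_hi, 0L, 1L))  # survreg interval codes
  rhs <- paste(c(regressor, controls), collapse = " + ")
  dat <- panel[c(regressor, controls)]
  dat$.t1 <- t1; dat$.t2 <- t2; dat$.ev <- ev
  X <- cbind(1, as.matrix(panel[c(regressor, controls)]))
  check_full_rank(X)
  fit <- survival::survreg(
    stats::as.formula(paste("survival::Surv(.t1, .t2, .ev, type = 'interval') ~", rhs)),
    data = dat, dist = "gaussian")
  if (is.na(fit$scale) || any(is.na(fit$coefficients)))
    stop_agrecoeff("Tobit estimation did not converge",
                   "agrecoeff_estimation_error")
  coefs <- fit$coefficients
  se <- sqrt(diag(fit$var))[seq_along(coefs)]
  names(se) <- names(coefs)
  new_aee_fit(coefs, se, nrow(panel),
              model = paste0("tobit[", regressor, "->", ycol, "]"),
              extra = list(sigma = fit$scale,
                           n_censored = sum(cens_lo) + sum(cens_hi),
                           loglik = fit$loglik[2]))
}

#' Two-stage least squares with a single instrument
#'
#' Stage 1 regresses the index on the instrument plus controls and reports
#' the excluded-instrument F statistic (with a weak-instrument warning below
#' 10); stage 2 replaces the index by its stage-1 fitted values, with the
#' 2SLS covariance computed from structural residuals (so an instrument
#' identical to the regressor reproduces OLS exactly).
#'
#' @param panel panel data.frame.
#' @param instrument instrument column name (default `"iv"`).
#' @param outcome `"vrs"` or `"crs"`.
#' @param regressor endogenous index column.
#' @param winsor winsorization fraction.
#' @param controls control column names (enter both stages).
#' @return list of class `iv_fit` with `first_stage` (an `aee_fit` carrying
#'   `f_stat`) and `second_stage` (an `aee_fit`).
#' @export
iv_2sls <- function(panel, instrument = "iv", outcome = c("vrs", "crs"),
                    regressor = "ndi", winsor = 0,
                    controls = controls_default) {
  ycol <- outcome_col(outcome)
  assert_that(instrument %in% names(panel),
              paste("instrument column", instrument, "not found"))
  z <- panel[[instrument]]
  assert_that(stats::var(z) > 0, "instrument must be nonconstant")
  panel <- winsorize_panel(panel, c(ycol, regressor, instrument, controls),
                           winsor)
  z <- panel[[instrument]]
  y <- panel[[ycol]]
  d <- panel[[regressor]]
  C <- as.matrix(panel[controls])

  X1 <- cbind("(Intercept)" = 1, z, C)
  colnames(X1)[2] <- instrument
  fs <- ols_engine(d, X1, model = paste0("iv_first_stage[", instrument, "->",
                                         regressor, "]"))
  f_excl <- (fs$coefficients[[instrument]] / fs$se[[instrument]])^2
  fs$f_stat <- f_excl
  if (f_excl < 10)
    warning("weak instrument: excluded-instrument F = ",
            round(f_excl, 2), " < 10", call. = FALSE)

  dhat <- fs$fitted
  Z2 <- cbind("(Intercept)" = 1, dhat, C)
  colnames(Z2)[2] <- regressor
  check_full_rank(Z2)
  b <- qr.solve(Z2, y)
  # 2SLS covariance from structural residuals (original regressor)
  Xorig <- cbind(1, d, C)
  u <- y - Xorig %*% b
  n <- length(y); k <- ncol(Z2)
  sigma2 <- sum(u^2) / (n - k)
  V <- sigma2 * chol2inv(chol(crossprod(Z2)))
  se <- sqrt(diag(V)); names(se) <- colnames(Z2)
  names(b) <- colnames(Z2)
  ss <- new_aee_fit(b, se, n, model = paste0("iv_2sls[", regressor, "->",
                                             ycol, "]"),
                    extra = list(residuals = as.vector(u), vcov = V))
  structure(list(first_stage = fs, second_stage = ss), class = "iv_fit")
}

#' @export
print.iv_fit <- function(x, ...) {
  cat("== first stage (excluded-instrument F =",
      round(x$first_stage$f_stat, 3), ") ==\n")
  print(x$first_stage)
  cat("== second stage ==\n")
  print(x$second_stage)
  invisible(x)
}

#' Subsample regressions
#'
#' Runs the pooled baseline separately on the two sides of a row split (for
#' example an early/late period split or a region split).
#'
#' @param panel panel data.frame.
#' @param split logical vector (length `nrow(panel)`) or a predicate function
#'   applied to the panel returning one; `TRUE` rows form the first
#'   subsample.
#' @param ... passed to [pooled_ols()].
#' @return list of class `subsample_fit` with `fit_a`, `fit_b` and `n` (the
#'   two subsample sizes).
#' @export
subsample_fit <- function(panel, split, ...) {
  sel <- if (is.function(split)) split(panel) else split
  assert_that(is.logical(sel) && length(sel) == nrow(panel) && !anyNA(sel),
              "split must give one TRUE/FALSE per row")
  na <- sum(sel); nb <- sum(!sel)
  assert_that(na >= 20L && nb >= 20L,
              paste0("both subsamples need at least 20 rows (got ", na, " / ",
                     nb, ")"))
  fa <- pooled_ols(panel[sel, , drop = FALSE], ...)
  fb <- pooled_ols(panel[!sel, , drop = FALSE], ...)
  structure(list(fit_a = fa, fit_b = fb, n = c(na, nb)),
            class = "subsample_fit")
}

#' @export
print.subsample_fit <- function(x, ...) {
  cat("== subsample A (N =", x$n[1], ") ==\n"); print(x$fit_a)
  cat("== subsample B (N =", x$n[2], ") ==\n"); print(x$fit_b)
  invisible(x)
}

#' Plain-text regression table
#'
#' Coefficients with t-values in parentheses and significance stars at the
#' 10/5/1% levels, one column per fit.
#'
#' @param fits named list of `aee_fit` objects.
#' @param digits rounding for coefficients.
#' @return character vector of table lines (also printed invisibly-friendly).
#' @export
regression_table <- function(fits, digits = 4) {
  assert_that(length(fits) >= 1L, "at least one fit is required")
  if (is.null(names(fits))) names(fits) <- paste0("(", seq_along(fits), ")")
  rows <- unique(unlist(lapply(fits, function(f) names(f$coefficients))))
  lines <- sprintf("%-18s %s", "", paste(sprintf("%14s", names(fits)),
                                         collapse = " "))
  for (r in rows) {
    cf <- vapply(fits, function(f) {
      if (r %in% names(f$coefficients)) {
        p <- 2 * stats::pnorm(-abs(f$t[[r]]))
        sprintf("%14s", paste0(round(f$coefficients[[r]], digits), stars(p)))
      } else sprintf("%14s", "")
    }, character(1))
    tv <- vapply(fits, function(f) {
      if (r %in% names(f$coefficients))
        sprintf("%14s", paste0("(", round(f$t[[r]], 2), ")"))
      else sprintf("%14s", "")
    }, character(1))
    lines <- c(lines, sprintf("%-18s %s", r, paste(cf, collapse = " ")),
               sprintf("%-18s %s", "", paste(tv, collapse = " ")))
  }
  lines <- c(lines, sprintf("%-18s %s", "N",
                            paste(sprintf("%14d", vapply(fits, function(f)
                              as.integer(f$n_obs), 1L)), collapse = " ")))
  lines
}
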