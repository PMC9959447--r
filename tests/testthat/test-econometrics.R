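make_panel <- function(seed = 1, ...) {
  generate_regression_panel(synthetic_config(seed = seed, ...))
}

test_that("winsorization clips both tails and is idempotent", {
  set.seed(201)
  x <- c(rnorm(200), -50, 60)
  w <- winsorize(x, 0.01)
  q <- quantile(x, c(0.01, 0.99), type = 1)  # order-statistic clipping
  expect_equal(min(w), q[[1]])
  expect_equal(max(w), q[[2]])
  expect_equal(winsorize(w, 0.01), w)
  expect_identical(winsorize(x, 0), x)
  expect_error(winsorize(x, 0.6), class = "agrecoeff_validation_error")
})

test_that("pooled OLS identifies the truth in the noise-free limit", {
  p <- make_panel(seed = 3, sigma_eps = 0, gamma_interact = 0,
                  beta_low = 0, beta_high = 0)
  f <- pooled_ols(p, winsor = 0)
  expect_equal(f$coefficients[["ndi"]], 1.0237, tolerance = 1e-8)
  # regressing a variable on itself: unit coefficient, zero residuals
  p2 <- p; p2$aee_vrs <- p2$ndi
  f2 <- pooled_ols(p2, winsor = 0)
  expect_equal(f2$coefficients[["ndi"]], 1, tolerance = 1e-10)
  expect_lt(max(abs(f2$residuals)), 1e-10)
})

test_that("pooled OLS covers the truth and reports consistent t-values", {
  p <- make_panel(seed = 11, beta_ndi = 1.0, sigma_eps = 0.3,
                  gamma_interact = 0, beta_low = 0, beta_high = 0)
  f <- pooled_ols(p, winsor = 0.01)
  expect_lt(abs(f$coefficients[["ndi"]] - 1.0), 2 * f$se[["ndi"]])
  expect_equal(f$t, f$coefficients / f$se, tolerance = 1e-10)
  expect_equal(f$n_obs, 300)
  fr <- pooled_ols(p, robust = TRUE)
  expect_equal(fr$t, fr$coefficients / fr$se, tolerance = 1e-10)
  expect_false(identical(f$se, fr$se))
  # guards
  expect_error(pooled_ols(p[1:20, ]), class = "agrecoeff_validation_error")
  expect_error(pooled_ols(p, winsor = 0.2),
               class = "agrecoeff_validation_error")
  p3 <- p; p3$AED <- p3$PS  # collinear controls
  expect_error(pooled_ols(p3, winsor = 0),
               class = "agrecoeff_singularity_error")
})

test_that("the two-regime fit at the true threshold is exact without noise", {
  p <- make_panel(seed = 5, sigma_eps = 0, theta_true = 0.28,
                  beta_low = 15, beta_high = -4, gamma_interact = 0,
                  beta_ndi = 0)
  X <- agrecoeff:::regime_design(p, "inni", 0.28, ctrl_cols)
  f <- agrecoeff:::ols_engine(p$aee_vrs, X, "check")
  expect_equal(f$coefficients[["reg_low"]], 15, tolerance = 1e-8)
  expect_equal(f$coefficients[["reg_high"]], -4, tolerance = 1e-8)
})

test_that("threshold search finds the cut point and its bootstrap test has power", {
  p <- make_panel(seed = 8, theta_true = 0.28, beta_low = 15, beta_high = -4,
                  sigma_eps = 0.5)
  tf <- threshold_fit(p, n_boot = 120, seed = 2, max_thresholds = 1)
  expect_lt(abs(tf$theta_hat - 0.28), 0.03)
  expect_lte(tf$boot_p, 0.05)
  expect_true(tf$theta_hat %in% tf$grid)
  expect_gte(tf$n_boot, 100)
  expect_equal(tf$n_thresholds, 1L)
  # guards
  expect_error(threshold_fit(p, n_boot = 50),
               class = "agrecoeff_validation_error")
  p5 <- p; p5$inni <- round(p5$inni, 1)  # too few distinct values
  expect_error(threshold_fit(p5, n_boot = 120),
               class = "agrecoeff_validation_error")
})

test_that("the bootstrap keeps its size when no threshold exists", {
  # absence of a regime change: p should usually be insignificant
  ok <- 0L
  for (s in 1:12) {
    p <- make_panel(seed = 700 + s, beta_low = 1, beta_high = 1,
                    sigma_eps = 0.5)
    tf <- threshold_fit(p, n_boot = 120, seed = s, max_thresholds = 1)
    if (tf$boot_p > 0.10) ok <- ok + 1L
  }
  expect_gte(ok, 9L)  # 85% nominal, small-sample slack
})

test_that("moderation fit recovers the interaction and flags degenerate moderators", {
  p <- make_panel(seed = 4, sigma_eps = 0, beta_low = 0, beta_high = 0)
  f <- moderation_fit(p, time_fe = FALSE)
  expect_equal(f$coefficients[["ndi:lu"]], 0.158, tolerance = 1e-8)
  expect_equal(marginal_effect(f, 50), 1.0237 + 0.158 * 50, tolerance = 1e-6)
  # stochastic coverage at 2 SE
  ps <- make_panel(seed = 33, beta_low = 0, beta_high = 0)
  fs <- moderation_fit(ps, time_fe = TRUE)
  expect_lt(abs(fs$coefficients[["ndi:lu"]] - 0.158), 2 * fs$se[["ndi:lu"]])
  expect_true(any(grepl("^year", names(fs$coefficients))))
  # constant moderator makes the interaction collinear
  pc <- p; pc$lu <- 55
  expect_error(moderation_fit(pc, time_fe = FALSE),
               class = "agrecoeff_singularity_error")
})

test_that("lagging the regressor drops exactly one year per unit", {
  p <- make_panel(seed = 6)
  f <- lagged_regressor_fit(p)
  expect_equal(f$n_obs, 270)  # 30 x 9
  # a time-constant regressor makes the lag fit equal the pooled fit on the
  # truncated sample
  p2 <- p
  p2$ndi <- ave(p2$ndi, p2$unit)  # constant within unit
  f2 <- lagged_regressor_fit(p2, winsor = 0)
  keep <- p2$year > min(p2$year)
  f3 <- pooled_ols(p2[keep, ], winsor = 0)
  expect_equal(f2$coefficients, f3$coefficients, tolerance = 1e-10)
  expect_error(lagged_regressor_fit(p[p$year == min(p$year), ]),
               class = "agrecoeff_validation_error")
})

test_that("tobit equals OLS without censoring and recovers a censored slope", {
  p <- make_panel(seed = 7)
  ft <- tobit_fit(p, spec = tobit_spec(lower = min(p$aee_vrs) - 1))
  fo <- pooled_ols(p, winsor = 0)
  expect_lt(max(abs(ft$coefficients - fo$coefficients)), 1e-4)
  expect_equal(ft$n_censored, 0L)
  expect_equal(ft$t, ft$coefficients / ft$se, tolerance = 1e-10)
  # censored DGP: slope recovered within 2 SE
  pc <- make_panel(seed = 14, censor_frac = 0.2, gamma_interact = 0,
                   beta_low = 0, beta_high = 0)
  bound <- attr(pc, "truth")$censor_bound
  fc <- tobit_fit(pc, spec = tobit_spec(lower = bound))
  expect_gt(fc$n_censored, 0L)
  expect_lt(abs(fc$coefficients[["ndi"]] - 1.0237), 2 * fc$se[["ndi"]])
  # everything censored is unidentified
  expect_error(tobit_fit(p, spec = tobit_spec(lower = max(p$aee_vrs) + 1)),
               class = "agrecoeff_estimation_error")
  expect_error(tobit_spec(lower = 1, upper = 0),
               class = "agrecoeff_validation_error")
})

test_that("2SLS collapses to OLS for a perfect instrument and warns when weak", {
  p <- make_panel(seed = 9)
  p$self <- p$ndi
  fi <- iv_2sls(p, instrument = "self")
  fo <- pooled_ols(p, winsor = 0)
  expect_equal(fi$second_stage$coefficients, fo$coefficients,
               tolerance = 1e-12)
  expect_equal(fi$second_stage$se, fo$se, tolerance = 1e-12)
  # shipped instrument is strong on the default DGP
  fs <- iv_2sls(p)
  expect_gt(fs$first_stage$f_stat, 10)
  # independent noise is a weak instrument
  set.seed(15); p$noise <- rnorm(nrow(p))
  expect_warning(iv_2sls(p, instrument = "noise"), "weak instrument")
  expect_error(iv_2sls(p, instrument = "nope"),
               class = "agrecoeff_validation_error")
})

test_that("2SLS reduces the endogeneity bias relative to OLS", {
  bias_ols <- bias_iv <- numeric(100)
  for (s in 1:100) {
    p <- generate_regression_panel(synthetic_config(
      seed = 500 + s, n_units = 15, n_years = 8, endog_rho = 1,
      gamma_interact = 0, beta_low = 0, beta_high = 0, sigma_eps = 0.3))
    bias_ols[s] <- pooled_ols(p, winsor = 0)$coefficients[["ndi"]] - 1.0237
    bias_iv[s] <- iv_2sls(p)$second_stage$coefficients[["ndi"]] - 1.0237
  }
  expect_lt(abs(mean(bias_iv)), abs(mean(bias_ols)))
  expect_gt(abs(mean(bias_ols)), 0.5)  # the confounding is material
})

test_that("subsample splits report the right sizes and agree under one DGP", {
  p <- make_panel(seed = 10)
  yrs <- sort(unique(p$year))
  sf <- subsample_fit(p, p$year <= yrs[6], winsor = 0.01)
  expect_equal(sf$n, c(180, 120))
  # same DGP on both sides: difference within a joint 95% band
  dA <- sf$fit_a$coefficients[["ndi"]] - sf$fit_b$coefficients[["ndi"]]
  joint <- sqrt(sf$fit_a$se[["ndi"]]^2 + sf$fit_b$se[["ndi"]]^2)
  expect_lt(abs(dA), 1.96 * joint)
  # predicate form
  sf2 <- subsample_fit(p, function(d) d$year <= yrs[6], winsor = 0.01)
  expect_equal(sf2$fit_a$coefficients, sf$fit_a$coefficients)
  expect_error(subsample_fit(p, rep(TRUE, nrow(p))),
               class = "agrecoeff_validation_error")
})

test_that("the regression table prints coefficients, t-values and stars", {
  p <- make_panel(seed = 13)
  tab <- regression_table(list(VRS = pooled_ols(p),
                               CRS = pooled_ols(p, outcome = "crs")))
  expect_true(any(grepl("ndi", tab)))
  expect_true(any(grepl("\\(", tab)))
  expect_true(any(grepl("N", tab)))
})
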