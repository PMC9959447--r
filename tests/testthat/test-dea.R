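test_that("duplicate DMUs each score exactly 1 under super-efficiency", {
  set.seed(21)
  for (rep in 1:5) {
    # twins constructed on the frontier: least input, most good output,
    # least bad output in the set
    x <- runif(1, 1, 2); yd <- runif(1, 3, 4); yu <- runif(1, 1, 2)
    d <- dmu_set(data.frame(id = 1:4,
                            x1 = c(x, x, x * runif(1, 1.5, 3), x * 2),
                            yd = c(yd, yd, yd * runif(1, 0.3, 0.8), yd * 0.5),
                            yu = c(yu, yu, yu * runif(1, 1.5, 3), yu * 2)),
                 inputs = "x1", good_outputs = "yd", bad_outputs = "yu")
    r1 <- sbm_super_efficiency(1, d)
    r2 <- sbm_super_efficiency(2, d)
    # the excluded twin reproduces the evaluated point, capping the score at 1
    expect_lte(abs(r1$score - 1), 1e-9)
    expect_lte(abs(r2$score - 1), 1e-9)
  }
  # a dominated twin pair shares its (sub-frontier) score instead
  d <- dmu_set(data.frame(id = 1:3, x1 = c(2, 2, 1), yd = c(1, 1, 3),
                          yu = c(2, 2, 1)),
               inputs = "x1", good_outputs = "yd", bad_outputs = "yu")
  ra <- sbm_super_efficiency(1, d); rb <- sbm_super_efficiency(2, d)
  expect_equal(ra$score, rb$score, tolerance = 1e-9)
  expect_lt(ra$score, 1)
})

test_that("single-ratio CRS instance matches the closed form", {
  d <- dmu_set(data.frame(id = c("A", "B", "C"), x = c(1, 1, 2),
                          y = c(2, 1, 1)),
               inputs = "x", good_outputs = "y")
  expect_equal(sbm_super_efficiency("B", d)$score, 0.5, tolerance = 1e-9)
  expect_equal(sbm_super_efficiency("C", d)$score, 0.25, tolerance = 1e-9)
  # frontier unit A re-scored against {B, C}: ratio 2 vs best remaining 1
  expect_equal(sbm_super_efficiency("A", d)$score, 2, tolerance = 1e-9)
})

test_that("CRS scores equal the best-ratio oracle on random 1x1 instances", {
  set.seed(31)
  for (rep in 1:40) {
    d <- random_ratio_dmus(sample(3:10, 1))
    oracle <- ratio_oracle(d$X[1, ], d$Yd[1, ])
    for (k in seq_along(oracle)) {
      expect_equal(sbm_super_efficiency(k, d)$score, oracle[k],
                   tolerance = 1e-6)
    }
  }
})

test_that("strict dominance forces a score below 1", {
  set.seed(41)
  for (rep in 1:5) {
    n <- 4
    base <- data.frame(id = 1:n,
                       x1 = runif(n, 1, 3), x2 = runif(n, 1, 3),
                       yd = runif(n, 1, 3), yu = runif(n, 1, 3))
    # make unit 1 strictly worse than unit 2 in every coordinate
    base[1, c("x1", "x2")] <- base[2, c("x1", "x2")] * 1.3
    base[1, "yd"] <- base[2, "yd"] * 0.7
    base[1, "yu"] <- base[2, "yu"] * 1.4
    d <- dmu_set(base, inputs = c("x1", "x2"), good_outputs = "yd",
                 bad_outputs = "yu")
    expect_lt(sbm_super_efficiency(1, d)$score, 1)
  }
})

test_that("scores are invariant to rescaling any column (units invariance)", {
  set.seed(51)
  base <- data.frame(id = 1:5, x1 = runif(5, 1, 3), x2 = runif(5, 1, 3),
                     yd = runif(5, 1, 3), yu = runif(5, 1, 3))
  d <- dmu_set(base, inputs = c("x1", "x2"), good_outputs = "yd",
               bad_outputs = "yu")
  s0 <- vapply(1:5, function(k) sbm_super_efficiency(k, d)$score, numeric(1))
  for (col in c("x2", "yd", "yu")) {
    scaled <- base
    scaled[[col]] <- scaled[[col]] * 137.5
    ds <- dmu_set(scaled, inputs = c("x1", "x2"), good_outputs = "yd",
                  bad_outputs = "yu")
    s1 <- vapply(1:5, function(k) sbm_super_efficiency(k, ds)$score, numeric(1))
    expect_equal(s1, s0, tolerance = 1e-7)
  }
})

test_that("worsening one input of a DMU never raises its score", {
  set.seed(61)
  for (rep in 1:5) {
    base <- data.frame(id = 1:5, x1 = runif(5, 1, 3), x2 = runif(5, 1, 3),
                       yd = runif(5, 1, 3), yu = runif(5, 1, 3))
    d <- dmu_set(base, inputs = c("x1", "x2"), good_outputs = "yd",
                 bad_outputs = "yu")
    s0 <- sbm_super_efficiency(3, d)$score
    worse <- base; worse$x1[3] <- worse$x1[3] * 1.5
    dw <- dmu_set(worse, inputs = c("x1", "x2"), good_outputs = "yd",
                  bad_outputs = "yu")
    expect_lte(sbm_super_efficiency(3, dw)$score, s0 + 1e-8)
  }
})

test_that("VRS scores envelop CRS scores for interior units", {
  set.seed(71)
  base <- data.frame(id = 1:8, x1 = runif(8, 1, 5), x2 = runif(8, 1, 5),
                     yd = runif(8, 1, 5), yu = runif(8, 1, 5))
  d <- dmu_set(base, inputs = c("x1", "x2"), good_outputs = "yd",
               bad_outputs = "yu")
  for (k in 1:8) {
    crs <- agrecoeff:::sbm_standard_lp(k, d, "crs")$rho
    vrs <- agrecoeff:::sbm_standard_lp(k, d, "vrs")$rho
    expect_gte(vrs, crs - 1e-8)
  }
})

test_that("excluding an interior DMU from its own reference set changes nothing", {
  set.seed(81)
  base <- data.frame(id = 1:6, x1 = runif(6, 1, 3), x2 = runif(6, 1, 3),
                     yd = runif(6, 1, 3), yu = runif(6, 1, 3))
  d <- dmu_set(base, inputs = c("x1", "x2"), good_outputs = "yd",
               bad_outputs = "yu")
  tested <- 0L
  for (k in 1:6) {
    std <- agrecoeff:::sbm_standard_lp(k, d, "crs", exclude = FALSE)
    if (std$rho < 1 - 1e-7) {
      excl <- agrecoeff:::sbm_standard_lp(k, d, "crs", exclude = TRUE)
      expect_equal(excl$rho, std$rho, tolerance = 1e-6)
      tested <- tested + 1L
    }
  }
  expect_gte(tested, 2L)
})

test_that("small instances with bad outputs match the brute-force oracle", {
  set.seed(91)
  for (rep in 1:3) {
    n <- sample(3:4, 1)
    d <- dmu_set(data.frame(id = seq_len(n),
                            x1 = runif(n, 1, 4), x2 = runif(n, 1, 4),
                            yd = runif(n, 1, 4), yu = runif(n, 1, 4)),
                 inputs = c("x1", "x2"), good_outputs = "yd",
                 bad_outputs = "yu")
    for (k in seq_len(n)) {
      lpv <- agrecoeff:::sbm_standard_lp(k, d, "crs")$rho
      expect_equal(lpv, sbm_brute_force(k, d), tolerance = 1e-6)
    }
  }
})

test_that("VRS super-efficiency infeasibility is a status, not a crash", {
  d <- dmu_set(data.frame(id = 1:3, x = c(1, 2, 2), yd = c(2, 1, 1),
                          yu = c(0.5, 2, 3)),
               inputs = "x", good_outputs = "yd", bad_outputs = "yu")
  r <- sbm_super_efficiency(1, d, rts = "vrs")
  expect_identical(r$status, "infeasible_super")
  expect_true(is.na(r$score))
  expect_equal(r$standard_score, 1, tolerance = 1e-9)
  expect_warning(
    sc <- score_panel(d, rts = "vrs"),
    "infeasible"
  )
  expect_equal(sc$score[1], 1, tolerance = 1e-9)  # substituted standard score
})

test_that("panel scoring is grouped, complete and guarded", {
  d <- replicated_panel_dmus(3)
  pooled <- score_panel(d, rts = "crs", frontier = "pooled")
  byyear <- score_panel(d, rts = "crs", frontier = "by_year")
  expect_equal(nrow(pooled), 12)
  expect_true(all(is.finite(pooled$score)))
  expect_gte(max(pooled$score), 0.99)  # a frontier always exists
  # identical yearly cross-sections: by-year frontier reproduces pooled scores
  expect_equal(byyear$score, pooled$score, tolerance = 1e-7)
  # group smaller than 3 is refused, naming the group
  tiny <- dmu_set(data.frame(id = 1:4, x = c(1, 2, 3, 4), y = c(1, 2, 3, 4),
                             year = c(1, 1, 1, 2)),
                  inputs = "x", good_outputs = "y", year = "year")
  expect_error(score_panel(tiny, frontier = "by_year"), "2")
})

test_that("dmu_set validates structure and positivity", {
  expect_error(dmu_set(data.frame(id = 1:3, x = c(1, 0, 2), y = 1:3),
                       inputs = "x", good_outputs = "y"),
               class = "agrecoeff_validation_error")
  expect_error(dmu_set(data.frame(id = 1:3, x = 1:3), inputs = "x",
                       good_outputs = "missing_col"),
               class = "agrecoeff_validation_error")
  expect_error(dmu_set(data.frame(id = c(1, 1, 2), x = 1:3, y = 1:3),
                       inputs = "x", good_outputs = "y"),
               class = "agrecoeff_validation_error")
})
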