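test_that("min-max normalisation follows the direction flags and epsilon shift", {
  eps <- 1e-4
  M <- indicator_matrix(cbind(a = c(0, 5, 10), b = c(0, 5, 10)),
                        directions = c("positive", "negative"))
  N <- minmax_normalize(M, eps = eps)
  expect_equal(N$values[, "a"],
               (c(0, 0.5, 1) + eps) / (1 + eps))
  expect_equal(N$values[, "b"],
               (c(1, 0.5, 0) + eps) / (1 + eps))
  expect_true(all(N$values > 0 & N$values <= 1))
  # two-point column hits the shifted endpoints
  M2 <- indicator_matrix(cbind(c(0, 1)))
  N2 <- minmax_normalize(M2, eps = eps)
  expect_equal(N2$values[, 1], c(eps / (1 + eps), 1))
})

test_that("constant columns are flagged degenerate and get zero weight", {
  M <- indicator_matrix(cbind(a = c(1, 2, 3), b = c(7, 7, 7)))
  N <- minmax_normalize(M)
  expect_identical(N$degenerate, c(FALSE, TRUE))
  w <- entropy_weights(N)
  expect_equal(unname(w), c(1, 0))
})

test_that("entropy weights match the hand-computed two-unit example", {
  # pre-normalised matrix: column 2 is uniform, so e = 1 and w = (1, 0)
  M <- indicator_matrix(cbind(c(0.9, 0.1), c(0.5, 0.5)))
  M$values <- cbind(c(0.9, 0.1), c(0.5, 0.5))
  w <- entropy_weights(M)
  e1 <- -(0.9 * log(0.9) + 0.1 * log(0.1)) / log(2)
  expect_equal(unname(w), c((1 - e1), 0) / (1 - e1))
  expect_equal(unname(w), c(1, 0))
})

test_that("entropy weights are symmetric, normalised and relabel-invariant", {
  set.seed(101)
  for (rep in 1:10) {
    V <- matrix(runif(24, 0.05, 1), 8, 3)
    M <- indicator_matrix(V)
    N <- minmax_normalize(M)
    w <- entropy_weights(N)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
    # relabeling units leaves weights unchanged
    perm <- sample(8)
    Mp <- indicator_matrix(V[perm, ])
    expect_equal(unname(entropy_weights(minmax_normalize(Mp))), unname(w))
  }
  # identical columns share the weight equally
  Mtwin <- indicator_matrix(cbind(c(1, 4, 2, 6), c(1, 4, 2, 6)))
  expect_equal(unname(entropy_weights(minmax_normalize(Mtwin))), c(0.5, 0.5))
})

test_that("a strictly more dispersed column never gets less weight", {
  # column 2 is column 1 shrunk toward the centre (same range, less spread)
  set.seed(111)
  for (rep in 1:10) {
    x <- sort(runif(10))
    shrink <- 0.5 + (x - 0.5) * runif(1, 0.2, 0.8)
    shrink[which.min(x)] <- min(x); shrink[which.max(x)] <- max(x)
    M <- indicator_matrix(cbind(wide = x, narrow = shrink))
    w <- entropy_weights(minmax_normalize(M))
    expect_gte(w[["wide"]], w[["narrow"]] - 1e-10)
  }
})

test_that("coupled coordination reproduces the canonical two-system form", {
  r <- coupling_coordination(0.5, 0.5)
  expect_equal(r$coupling_C, 1)
  expect_equal(r$composite_T, 0.5)
  expect_equal(r$coordination_D, sqrt(0.5))
  # degenerate coupling
  r0 <- coupling_coordination(0, 0.7)
  expect_equal(r0$coupling_C, 0)
  expect_equal(r0$coordination_D, 0)
  expect_equal(coupling_coordination(0, 0)$coupling_C, 0)
  # symmetry and range
  set.seed(121)
  u1 <- runif(50); u2 <- runif(50)
  a <- coupling_coordination(u1, u2)
  b <- coupling_coordination(u2, u1)
  expect_equal(a$coupling_C, b$coupling_C)
  expect_true(all(a$coupling_C >= 0 & a$coupling_C <= 1 + 1e-12))
  expect_true(all(a$coordination_D >= 0 & a$coordination_D <= 1 + 1e-12))
  # C = 1 iff the subsystems are equal (both positive)
  expect_equal(coupling_coordination(0.3, 0.3)$coupling_C, 1)
  expect_lt(coupling_coordination(0.3, 0.6)$coupling_C, 1)
  expect_error(coupling_coordination(1.2, 0.5),
               class = "agrecoeff_validation_error")
  expect_error(coupling_coordination(0.5, 0.5, alpha = 0.7, beta = 0.5),
               class = "agrecoeff_validation_error")
})

test_that("the composite index is the expert-weighted convex combination", {
  expect_equal(composite_ndi(1, 0, 0)$ndi, 0.4)
  expect_equal(composite_ndi(0, 1, 0)$ndi, 0.3)
  expect_equal(composite_ndi(0, 0, 0)$ndi, 0)
  expect_equal(composite_ndi(1, 1, 1)$ndi, 1)
  # monotone nondecreasing in each sub-index
  base <- composite_ndi(0.2, 0.3, 0.4)$ndi
  expect_gte(composite_ndi(0.3, 0.3, 0.4)$ndi, base)
  expect_gte(composite_ndi(0.2, 0.4, 0.4)$ndi, base)
  expect_gte(composite_ndi(0.2, 0.3, 0.5)$ndi, base)
  expect_error(composite_ndi(1, 0, 0, weights = c(0.5, 0.3, 0.3)),
               class = "agrecoeff_validation_error")
  # invariant: ndi equals the weighted sum to machine precision
  set.seed(131)
  r <- composite_ndi(runif(20), runif(20), runif(20))
  expect_equal(r$ndi, 0.4 * r$infi + 0.3 * r$ci + 0.3 * r$inni,
               tolerance = 1e-12)
})

test_that("build_ndi assembles block scores into a bounded composite", {
  set.seed(141)
  ind <- data.frame(unit = rep(sprintf("U%02d", 1:10), each = 3),
                    year = rep(1:3, 10),
                    i1 = runif(30), i2 = runif(30),
                    t1 = runif(30), t2 = runif(30),
                    z1 = runif(30), z2 = runif(30),
                    n1 = runif(30), n2 = runif(30))
  blocks <- list(information = c("i1", "i2"), traditional = c("t1", "t2"),
                 informatization = c("z1", "z2"), innovation = c("n1", "n2"))
  out <- build_ndi(ind, blocks)
  expect_equal(nrow(out), 30)
  expect_true(all(out$ndi >= 0 & out$ndi <= 1))
  expect_equal(out$ndi, 0.4 * out$infi + 0.3 * out$ci + 0.3 * out$inni,
               tolerance = 1e-12)
  expect_error(build_ndi(ind, blocks[-1]),
               class = "agrecoeff_validation_error")
})
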