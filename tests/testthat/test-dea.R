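test_that("CCR scores match hand-solved examples", {
  # single input/output: score is each ratio over the best ratio
  p <- facility_panel(matrix(c(1, 1), 2), matrix(c(2, 1), 2))
  expect_equal(dea_scores(p)$scores, c(1, 0.5), tolerance = 1e-9)
  # unit inputs, outputs A(2,1) B(1,2) C(1,1): C scores 2/3 at u = (1/3, 1/3)
  p2 <- facility_panel(matrix(1, 3, 1), matrix(c(2, 1, 1, 1, 2, 1), 3, 2))
  r2 <- dea_scores(p2)
  expect_equal(r2$scores, c(1, 1, 2 / 3), tolerance = 1e-9)
  # identical facilities are all mutually efficient
  p3 <- facility_panel(matrix(1, 5, 2), matrix(1, 5, 2))
  expect_equal(dea_scores(p3)$scores, rep(1, 5), tolerance = 1e-12)
})

test_that("multiplier weights attain the score and satisfy the normalization", {
  p <- random_panel(8, 2, 3, seed = 21)
  r <- dea_scores(p)
  for (i in 1:8) {
    expect_equal(sum(r$v[i, ] * p$inputs[i, ]), 1, tolerance = 1e-8)
    expect_equal(sum(r$u[i, ] * p$outputs[i, ]), r$scores[i],
                 tolerance = 1e-8)
    # feasibility of the returned weights against every peer
    expect_true(all(p$outputs %*% r$u[i, ] - p$inputs %*% r$v[i, ] <= 1e-8))
  }
})

test_that("envelopment path agrees with an independent multiplier-form LP", {
  for (s in 1:12) {
    n <- sample(4:15, 1)
    p <- random_panel(n, sample(1:3, 1), sample(1:3, 1), seed = 200 + s)
    r <- dea_scores(p)
    for (o in sample(n, 3)) {
      expect_equal(r$scores[o], min(multiplier_ccr_oracle(p, o), 1),
                   tolerance = 1e-6)
    }
  }
})

test_that("generic simplex agrees with brute-force vertex enumeration", {
  set.seed(33)
  for (s in 1:20) {
    nv <- sample(2:4, 1)
    nc <- sample(2:5, 1)
    A <- matrix(round(runif(nc * nv, -2, 4), 2), nc, nv)
    b <- round(runif(nc, 1, 5), 2)
    cvec <- round(runif(nv, 0.1, 2), 2)
    # maximize c'w s.t. A w <= b, w >= 0 (bounded since c > 0, diag-ish A)
    A2 <- rbind(A, diag(nv))  # keep the region bounded
    b2 <- c(b, rep(6, nv))
    full_A <- rbind(A2, -diag(nv))
    full_dir <- c(rep(-1L, nrow(A2)), rep(-1L, nv))
    full_b <- c(b2, rep(0, nv))
    oracle <- brute_lp_max(cvec, full_A, full_dir, full_b)
    got <- effsim:::.lp_solve_cpp(cvec, A2, rep(-1L, nrow(A2)), b2,
                                  maximize = TRUE)
    expect_equal(got$objective, oracle$objective, tolerance = 1e-7)
  }
})

test_that("unrestricted DEA is units invariant and always has a frontier", {
  p <- random_panel(12, 3, 2, seed = 5)
  r <- dea_scores(p)
  expect_gte(max(r$scores), 1 - 1e-9)
  q <- facility_panel(sweep(p$inputs, 2, c(100, 0.01, 7), "*"),
                      sweep(p$outputs, 2, c(0.5, 2000), "*"))
  expect_equal(dea_scores(q)$scores, r$scores, tolerance = 1e-9)
})

test_that("super-efficiency filter removes extremes under the cap rule", {
  # all identical: leave-one-out frontier unchanged, no removals
  p0 <- facility_panel(matrix(1, 6, 1), matrix(1, 6, 1))
  f0 <- super_efficiency_filter(p0)
  expect_equal(sum(f0$outlier_flags), 0)
  expect_equal(unname(f0$super_scores), rep(1, 6), tolerance = 1e-9)
  # n = 20: one facility ten times as productive, cap floor(1) = 1
  p <- facility_panel(matrix(1, 20, 1), matrix(c(rep(1, 19), 10), 20, 1))
  f <- super_efficiency_filter(p)
  expect_equal(which(f$outlier_flags), 20L)
  expect_equal(f$super_scores[20], 10, tolerance = 1e-9)
  expect_equal(f$scores, rep(1, 20), tolerance = 1e-9)
  # n = 19: cap floor(0.95) = 0 forbids any removal
  p19 <- facility_panel(matrix(1, 19, 1), matrix(c(rep(1, 18), 10), 19, 1))
  f19 <- super_efficiency_filter(p19)
  expect_equal(sum(f19$outlier_flags), 0)
  expect_equal(f19$scores[1], 0.1, tolerance = 1e-9)
})

test_that("percentile ratio bounds follow the interpolation convention", {
  # synthetic weight set with ratios u2/u1 = 1..5
  u <- cbind(rep(1, 5), 1:5)
  v <- cbind(rep(1, 5), rep(2, 5))
  res <- structure(list(scores = rep(0.5, 5), u = u, v = v,
                        outlier_flags = rep(FALSE, 5),
                        super_scores = rep(NA_real_, 5)),
                   class = "dea_result")
  b <- relative_weight_bounds(res, 40, 60)
  expect_equal(b$output_lower, 2.6)
  expect_equal(b$output_upper, 3.4)
  expect_equal(b$input_lower, 2)   # degenerate distribution: L = U
  expect_equal(b$input_upper, 2)
  b2 <- relative_weight_bounds(res, 0, 100)
  expect_equal(b2$output_lower, 1)
  expect_equal(b2$output_upper, 5)
  # an all-zero weight column is an estimation error naming the dimension
  res$u[, 2] <- 0
  expect_error(relative_weight_bounds(res, 40, 60), "output 2")
})

test_that("restricted DEA never exceeds unrestricted and tightens monotonically", {
  p <- random_panel(15, 2, 3, seed = 77)
  filt <- super_efficiency_filter(p)
  d <- filt$scores
  prev <- d
  for (pcts in list(c(10, 90), c(30, 70), c(40, 60), c(50, 50))) {
    b <- relative_weight_bounds(filt, pcts[1], pcts[2])
    r <- rdea_scores(p, b, filter = filt)$scores
    expect_true(all(r <= prev + 1e-9))
    prev <- r
  }
})

test_that("equal lower and upper bounds reduce to fixed-weight scoring", {
  p <- random_panel(10, 2, 2, seed = 9)
  # L = U pins u2/u1 and v2/v1: score is the fixed-weight productivity
  # index over the sample maximum
  b <- weight_bounds(0.7, 0.7, 1.3, 1.3)
  r <- rdea_scores(p, b)$scores
  idx <- drop(p$outputs %*% c(1, 0.7)) / drop(p$inputs %*% c(1, 1.3))
  expect_equal(r, idx / max(idx), tolerance = 1e-8)
  # restricted multiplier form agrees with the independent oracle LP
  for (o in c(1, 4, 8))
    expect_equal(r[o], min(multiplier_ccr_oracle(p, o, b), 1),
                 tolerance = 1e-6)
})

test_that("single input and output leave restricted DEA identical to DEA", {
  p <- facility_panel(matrix(c(1, 2, 3), 3), matrix(c(3, 2, 1), 3))
  b <- weight_bounds(numeric(0), numeric(0), numeric(0), numeric(0))
  expect_equal(rdea_scores(p, b)$scores, dea_scores(p)$scores,
               tolerance = 1e-12)
})
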