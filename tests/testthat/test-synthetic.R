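test_that("input draws are uniform on their supports, independent or correlated", {
  spec <- input_spec(c(0, 0, 0), c(5, 10, 8))
  set.seed(101)
  X <- draw_inputs(spec, 1e5)
  se <- 5 / sqrt(12 * 1e5)
  expect_lt(abs(mean(X[, 1]) - 2.5), 3 * se)
  expect_true(all(X >= 0) && all(X[, 1] <= 5) && all(X[, 2] <= 10) &&
                all(X[, 3] <= 8))
  # marginal uniformity at scale (fixed seed chosen in advance)
  # (ties warning suppressed: runif draws collide on the 2^32 grid at this n)
  expect_gt(suppressWarnings(stats::ks.test(X[, 2], "punif", 0, 10))$p.value, 0.01)
  # one-row draw stays within bounds
  expect_true(all(draw_inputs(spec, 1) >= c(0, 0, 0)))

  C <- diag(3); C[1, 2] <- C[2, 1] <- 0.6; C[1, 3] <- C[3, 1] <- 0.4
  C[2, 3] <- C[3, 2] <- 0.1
  set.seed(102)
  Xc <- draw_inputs(input_spec(c(0, 0, 0), c(5, 10, 8),
                               correlation_matrix = C), 1e5)
  expect_lt(abs(cor(Xc[, 1], Xc[, 2], method = "spearman") - 0.60), 0.01)
  expect_lt(abs(cor(Xc[, 1], Xc[, 3], method = "spearman") - 0.40), 0.01)
  expect_gt(suppressWarnings(stats::ks.test(Xc[, 1], "punif", 0, 5))$p.value, 0.01)

  bad <- matrix(c(1, 0.99, -0.99, 0.99, 1, 0.99, -0.99, 0.99, 1), 3, 3)
  expect_error(draw_inputs(input_spec(c(0, 0, 0), c(1, 1, 1),
                                      correlation_matrix = bad), 10),
               "positive definite")
})

test_that("true-efficiency draws follow the requested distribution", {
  set.seed(103)
  th <- draw_true_efficiency(efficiency_spec("uniform01"), 1e5)
  expect_true(all(th > 0 & th <= 1))
  expect_lt(abs(mean(th) - 0.5), 0.005)

  # independent oracle for E exp(-|N(0, 0.05^2)|) by numeric integration
  m <- stats::integrate(function(z) 2 * exp(-z) * dnorm(z, 0, 0.05),
                        0, Inf)$value
  set.seed(104)
  th2 <- draw_true_efficiency(efficiency_spec("half_normal_exp",
                                              sigma_u = 0.05), 1e5)
  expect_lt(abs(mean(th2) - m), 0.002)
  expect_lt(abs(m - 0.960), 0.002)
  set.seed(105)
  th3 <- draw_true_efficiency(efficiency_spec("half_normal_exp",
                                              sigma_u = 0.2), 1e4)
  expect_true(all(th3 <= 1 & th3 > 0))
  expect_error(efficiency_spec("half_normal_exp", sigma_u = -1), "sigma_u")
})

test_that("capacity evaluates each technology, including fixed components and CRS", {
  lin <- production_spec("linear", c(0.2, 0.5, 0.3))
  expect_equal(compute_capacity(matrix(c(1, 1, 1), 1), lin), 1.0)
  lf <- production_spec("linear_fixed", c(0.2, 0.5, 0.3),
                        fixed_offsets = c(0.5, 2.0, 0.1))
  expect_equal(compute_capacity(matrix(c(0.5, 2.0, 0.1), 1), lf), 0)
  expect_equal(compute_capacity(matrix(c(1.5, 4.0, 2.1), 1), lf), 1.8)
  # constant returns to scale: doubling inputs doubles capacity
  X <- matrix(runif(30, 1, 4), 10, 3)
  expect_equal(compute_capacity(2 * X, lin), 2 * compute_capacity(X, lin))
  cd <- production_spec("cobb_douglas", c(0.2, 0.5, 0.3),
                        output_exponents = rep(-1 / 3, 3))
  expect_equal(compute_capacity(2 * X, cd), 2 * compute_capacity(X, cd),
               tolerance = 1e-12)
  expect_error(compute_capacity(matrix(c(0, 1, 1), 1), cd), "positive")
  # piecewise form is continuous at its breakpoints
  pw <- production_spec("piecewise_cobb_douglas", c(0.2, 0.5, 0.3),
                        output_exponents = rep(-1 / 3, 3),
                        piecewise_breakpoints = c(8, 8, 8))
  lo <- compute_capacity(matrix(8 - 1e-9, 1, 3), pw)
  hi <- compute_capacity(matrix(8 + 1e-9, 1, 3), pw)
  expect_equal(lo, hi, tolerance = 1e-6)
})

test_that("output allocation conserves capacity and honours portfolios", {
  mix <- output_mix_spec()  # p = (0.5, 0.5, 1), intensities (0.25, 0.5, 1)
  set.seed(106)
  a <- allocate_outputs(rep(2, 500), mix)
  expect_true(all(a$outputs[, 3] > 0))
  expect_equal(rowSums(a$shares), rep(2, 500))
  # conservation: sum_j intensity_j * y_j = effective capacity, exactly
  expect_equal(drop(a$outputs %*% c(0.25, 0.5, 1)), rep(2, 500),
               tolerance = 1e-12)
  # portfolio frequencies within binomial error
  p1 <- mean(a$shares[, 1] > 0)
  expect_lt(abs(p1 - 0.5), 3 * sqrt(0.25 / 500))
  # a facility producing only y3 puts everything there
  mix3 <- output_mix_spec(production_probabilities = c(0, 0, 1))
  set.seed(107)
  a3 <- allocate_outputs(2, mix3)
  expect_equal(unname(drop(a3$outputs)), c(0, 0, 2))
  # worked share example: shares (0.25, 0.25, 0.5) of capacity 1
  sh <- c(0.25, 0.25, 0.5)
  expect_equal(sh / c(0.25, 0.5, 1), c(1.0, 0.5, 0.5))
})

test_that("measurement error clamps, scales, and assigns the sigma mixture", {
  p <- random_panel(50, 3, 3, seed = 108)
  same <- apply_measurement_error(p, error_spec("none"))
  expect_identical(same$outputs, p$outputs)
  set.seed(109)
  zero <- apply_measurement_error(p, error_spec("multiplicative", 0))
  expect_equal(zero$inputs, p$inputs)
  expect_equal(zero$outputs, p$outputs)
  # additive noise floors negatives at the clamp value
  tiny <- facility_panel(matrix(1e-4, 4, 2), matrix(1e-4, 4, 2))
  set.seed(110)
  noisy <- apply_measurement_error(tiny, error_spec("additive", 0.5))
  expect_true(all(noisy$outputs > 0))
  expect_true(any(noisy$outputs == 0.01))
  # outputs-only errors leave inputs untouched
  set.seed(111)
  oo <- apply_measurement_error(p, error_spec("multiplicative", 0.1,
                                              apply_to = "outputs_only"))
  expect_identical(oo$inputs, p$inputs)
  expect_false(identical(oo$outputs, p$outputs))
  # mixed assignment: the high-sigma fraction follows the tau rule
  big <- random_panel(1e5, 1, 1, seed = 112)
  spec <- error_spec("mixed", sigma_low = 1e-9, sigma_high = 1,
                     high_fraction = 0.15)
  set.seed(113)
  mx <- apply_measurement_error(big, spec)
  frac_high <- mean(abs(log(mx$outputs / big$outputs)) > 1e-5)
  expect_lt(abs(frac_high - 0.15), 0.004)
})

test_that("panel generation is seed-deterministic with truth populated", {
  p1 <- generate_panel("baseline", seed = 42)
  p2 <- generate_panel("baseline", seed = 42)
  expect_identical(p1, p2)
  expect_equal(dim(p1$inputs), c(200L, 3L))
  expect_equal(dim(p1$outputs), c(200L, 3L))
  expect_true(all(p1$outputs[, 3] > 0))
  expect_true(!is.null(p1$theta_true) && all(p1$theta_true > 0 &
                                               p1$theta_true <= 1))
  # error-free linear panels conserve intensity-weighted output exactly
  Y <- compute_capacity(p1$inputs, production_spec("linear", c(0.2, 0.5, 0.3)))
  expect_equal(drop(p1$outputs %*% c(0.25, 0.5, 1)), p1$theta_true * Y,
               tolerance = 1e-12)
  expect_error(generate_panel("no_such_scenario", 1), "unknown scenario")
  # Cobb-Douglas panels satisfy the distance regression identically
  pf <- generate_panel("cobb_douglas", seed = 43)
  dat <- prepare_distance_regression(pf)
  fitted <- drop(dat$input_logs %*% c(-0.2, -0.5, -0.3)) +
    drop(dat$output_ratio_logs %*% c(1 / 3, 1 / 3)) - log(pf$theta_true)
  expect_equal(dat$dependent, fitted, tolerance = 1e-9)
})

test_that("panels round-trip through CSV", {
  p <- generate_panel(scenario_preset("baseline", n = 12), seed = 5)
  f <- tempfile(fileext = ".csv")
  write_panel(p, f)
  q <- read_panel(f)
  expect_equal(unname(q$inputs), unname(p$inputs), tolerance = 1e-12)
  expect_equal(unname(q$outputs), unname(p$outputs), tolerance = 1e-12)
  expect_equal(q$theta_true, p$theta_true, tolerance = 1e-12)
  unlink(f)
})
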