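test_that("distance regression applies the zero-replacement rule without mutation", {
  X <- matrix(c(1, 2, 1, 3), 2, 2)
  Y <- matrix(c(0, 1, 2, 1, 1, 1), 2, 3)
  p <- facility_panel(rbind(X, X, X, X), rbind(Y, Y, Y, Y))
  snap <- p$outputs
  d <- prepare_distance_regression(p)
  expect_equal(d$dependent[1], -log(1e-10), tolerance = 1e-12)
  expect_equal(d$dependent[1], 23.026, tolerance = 1e-3)
  expect_identical(p$outputs, snap)  # purity: the panel is untouched
  # all-ones facility maps to the origin of the regression
  p1 <- facility_panel(matrix(1, 8, 3), matrix(1, 8, 3))
  d1 <- prepare_distance_regression(p1)
  expect_equal(d1$dependent, rep(0, 8))
  expect_true(all(d1$input_logs == 0) && all(d1$output_ratio_logs == 0))
})

test_that("JLMS conditional mean matches its frozen value and the integration oracle", {
  # sigma_u = sigma_v = 1, eps = 0
  expect_equal(jlms_inefficiency(0, sqrt(2), 1),
               sqrt(2) / 2 * dnorm(0) / (1 - pnorm(0)), tolerance = 1e-12)
  expect_equal(jlms_inefficiency(0, sqrt(2), 1), 0.5642, tolerance = 1e-4)
  expect_equal(exp(-jlms_inefficiency(0, sqrt(2), 1)), 0.5688,
               tolerance = 1e-4)
  # brute-force numeric integration of u * f(u | eps) over a grid
  for (su in c(0.1, 0.5, 1)) {
    for (sv in c(0.05, 0.5, 2)) {
      for (eps in c(-2, -0.5, 0, 0.5, 2)) {
        got <- jlms_inefficiency(eps, sqrt(su^2 + sv^2), su / sv)
        expect_lt(abs(got - jlms_oracle(eps, su, sv)), 1e-6)
      }
    }
  }
})

test_that("JLMS is monotone, positive, and stable deep in the tails", {
  g <- seq(-5, 5, by = 0.05)
  u <- jlms_inefficiency(g, 1, 1)
  expect_true(all(diff(u) > 0))
  expect_true(all(u > 0))
  extreme <- jlms_inefficiency(c(-1e6, -50, 50, 1e6), 1, 1)
  expect_true(all(is.finite(extreme) & extreme > 0))
  # lambda -> 0: no inefficiency signal, conditional mean flat in eps
  flat <- jlms_inefficiency(c(-3, 0, 3), 1, 1e-8)
  expect_lt(diff(range(flat)), 1e-7)
})

test_that("constrained MLE recovers known frontier parameters", {
  fits <- lapply(1:8, function(s)
    fit_rsdf_cd(simulate_sdf_data(2000, seed = 400 + s)))
  expect_true(all(vapply(fits, `[[`, TRUE, "converged")))
  avg <- function(f) Reduce(`+`, f) / length(f)
  expect_lt(abs(avg(lapply(fits, `[[`, "beta0")) - 1), 0.05)
  expect_true(all(abs(avg(lapply(fits, `[[`, "beta")) -
                        c(-0.3, -0.4, -0.3)) < 0.05))
  expect_true(all(abs(avg(lapply(fits, `[[`, "alpha")) -
                        c(0.4, 0.6)) < 0.05))
  expect_lt(abs(avg(lapply(fits, `[[`, "sigma_u")) - 0.2), 0.05)
  expect_lt(abs(avg(lapply(fits, `[[`, "sigma_v")) - 0.05), 0.05)
  # constraints hold strictly at every optimum
  for (f in fits) {
    expect_true(all(f$beta < 0) && all(f$alpha > 0) && f$lam > 0)
    expect_true(all(f$theta > 0 & f$theta <= 1))
  }
})

test_that("near-noiseless efficient data yields near-unit efficiencies", {
  set.seed(55)
  d <- simulate_sdf_data(300, sigma_u = 1e-9, sigma_v = 1e-9, seed = 56)
  d$dependent <- d$dependent + rnorm(300, 0, 1e-6)
  f <- fit_rsdf_cd(d)
  expect_lt(max(abs(f$residuals)), 1e-4)
  expect_gte(mean(f$theta), 0.99)
})

test_that("likelihood peaks at the truth on large samples", {
  d <- simulate_sdf_data(5000, seed = 99)
  Z <- cbind(1, d$input_logs, d$output_ratio_logs)
  ll <- function(coefs, su, sv) {
    s <- sqrt(su^2 + sv^2)
    e <- d$dependent - drop(Z %*% coefs)
    sum(log(2) - log(s) + dnorm(e / s, log = TRUE) +
          pnorm(e * (su / sv) / s, log.p = TRUE))
  }
  truth <- ll(c(1, -0.3, -0.4, -0.3, 0.4, 0.6), 0.2, 0.05)
  expect_gt(truth, ll(c(1.1, -0.3, -0.4, -0.3, 0.4, 0.6), 0.2, 0.05))
  expect_gt(truth, ll(c(1, -0.3, -0.4, -0.3, 0.4, 0.6), 0.4, 0.05))
  expect_gt(truth, ll(c(1, -0.2, -0.5, -0.3, 0.4, 0.6), 0.2, 0.10))
})

test_that("rank-deficient regressors raise an estimation error", {
  d <- simulate_sdf_data(100, seed = 7)
  d$input_logs[, 2] <- 2 * d$input_logs[, 1]
  expect_error(fit_rsdf_cd(d), "rank deficient")
})
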