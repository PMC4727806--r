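# Shared fixtures and independent oracles used across test files.

# Random small panel with strictly positive data.
random_panel <- function(n, R = 2, J = 2, seed = 1) {
  set.seed(seed)
  facility_panel(matrix(runif(n * R, 0.5, 5), n, R),
                 matrix(runif(n * J, 0.5, 5), n, J))
}

# Brute-force LP oracle by vertex enumeration: maximize c'w subject to
# A w (dir) b, where dir is -1/0/1 for <=/=/>= and nonnegativity (if wanted)
# is passed as explicit rows. Only for tiny problems.
brute_lp_max <- function(c, A, dir, b) {
  p <- length(c)
  eq <- which(dir == 0)
  best <- -Inf
  bestw <- NULL
  for (S in utils::combn(nrow(A), p, simplify = FALSE)) {
    if (!all(eq %in% S)) next
    M <- A[S, , drop = FALSE]
    if (abs(det(M)) < 1e-10) next
    w <- tryCatch(solve(M, b[S]), error = function(e) NULL)
    if (is.null(w)) next
    lhs <- drop(A %*% w)
    feas <- all(ifelse(dir == -1, lhs <= b + 1e-7,
                       ifelse(dir == 1, lhs >= b - 1e-7,
                              abs(lhs - b) <= 1e-7)))
    if (feas && sum(c * w) > best) {
      best <- sum(c * w)
      bestw <- w
    }
  }
  list(objective = best, solution = bestw)
}

# Independent multiplier-form CCR score: builds the multiplier LP directly
# (normalization v'x_o = 1, frontier rows, optional assurance-region rows)
# and solves it as a maximization with the generic simplex entry point. The
# package's own path solves the envelopment dual instead, so agreement checks
# the primal/dual construction end to end.
multiplier_ccr_oracle <- function(panel, o, bounds = NULL) {
  X <- panel$inputs
  Y <- panel$outputs
  n <- nrow(X); R <- ncol(X); J <- ncol(Y)
  cvec <- c(Y[o, ], rep(0, R))
  A <- rbind(c(rep(0, J), X[o, ]),        # v'x_o = 1
             cbind(Y, -X))                # u'y_k - v'x_k <= 0
  dir <- c(0L, rep(-1L, n))
  b <- c(1, rep(0, n))
  if (!is.null(bounds)) {
    for (j in seq_along(bounds$output_lower)) {
      lo <- rep(0, J + R); lo[1] <- bounds$output_lower[j]; lo[j + 1] <- -1
      hi <- rep(0, J + R); hi[1] <- -bounds$output_upper[j]; hi[j + 1] <- 1
      A <- rbind(A, lo, hi); dir <- c(dir, -1L, -1L); b <- c(b, 0, 0)
    }
    for (r in seq_along(bounds$input_lower)) {
      lo <- rep(0, J + R); lo[J + 1] <- bounds$input_lower[r]; lo[J + r + 1] <- -1
      hi <- rep(0, J + R); hi[J + 1] <- -bounds$input_upper[r]; hi[J + r + 1] <- 1
      A <- rbind(A, lo, hi); dir <- c(dir, -1L, -1L); b <- c(b, 0, 0)
    }
  }
  res <- effsim:::.lp_solve_cpp(cvec, A, dir, b, maximize = TRUE)
  stopifnot(res$status == 0)
  res$objective
}

# Numeric-integration oracle for the JLMS conditional mean: E(u | eps) under
# u ~ half-normal(sigma_u), v ~ N(0, sigma_v^2), eps = u + v. The unnormalized
# log-density is rescaled by its maximum over u >= 0 so the integrands stay
# representable even when P(eps) underflows.
jlms_oracle <- function(eps, sigma_u, sigma_v) {
  logf <- function(u) -(eps - u)^2 / (2 * sigma_v^2) - u^2 / (2 * sigma_u^2)
  peak <- stats::optimize(logf, c(0, abs(eps) + 6 * (sigma_u + sigma_v)),
                          maximum = TRUE)$objective
  peak <- max(peak, logf(0))
  num <- stats::integrate(function(u) u * exp(logf(u) - peak), 0, Inf,
                          rel.tol = 1e-12, abs.tol = 0)$value
  den <- stats::integrate(function(u) exp(logf(u) - peak), 0, Inf,
                          rel.tol = 1e-12, abs.tol = 0)$value
  num / den
}

# Simulate a Cobb-Douglas distance regression with known parameters.
simulate_sdf_data <- function(n, beta0 = 1, beta = c(-0.3, -0.4, -0.3),
                              alpha = c(0.4, 0.6), sigma_u = 0.2,
                              sigma_v = 0.05, seed = 1) {
  set.seed(seed)
  lx <- matrix(rnorm(n * length(beta), 1, 0.5), n, length(beta))
  lr <- matrix(rnorm(n * length(alpha), 0, 0.7), n, length(alpha))
  u <- abs(rnorm(n, 0, sigma_u))
  v <- rnorm(n, 0, sigma_v)
  d <- beta0 + drop(lx %*% beta) + drop(lr %*% alpha) + u + v
  structure(list(dependent = d, input_logs = lx, output_ratio_logs = lr,
                 zero_replacement = 1e-10),
            class = "regression_data")
}
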