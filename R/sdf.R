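#' Build the Cobb-Douglas distance regression from a panel
#'
#' The output distance function in Cobb-Douglas form, normalized on output 1,
#' is linear in logs: the dependent variable is `-ln y1`, the regressors are
#' the log inputs and the log ratios `ln(y_j / y1)` for `j >= 2`. Zeros in
#' any input or output are replaced by a small positive value before taking
#' logs (the logarithm is undefined at zero; non-produced outputs are a
#' designed feature of the data). The panel itself is not modified.
#'
#' @param panel a [facility_panel()].
#' @param zero_replacement positive value substituted for zero cells.
#' @return A `regression_data` object with fields `dependent`, `input_logs`,
#'   `output_ratio_logs`, `zero_replacement`.
#' @export
prepare_distance_regression <- function(panel, zero_replacement = 1e-10) {
  stopifnot(inherits(panel, "facility_panel"), zero_replacement > 0)
  X <- panel$inputs
  Y <- panel$outputs
  if (any(X < 0) || any(Y < 0))
    stop("negative inputs or outputs cannot enter the log regression",
         call. = FALSE)
  n <- nrow(X); R <- ncol(X); J <- ncol(Y)
  if (n < R + J + 2)
    stop("too few facilities for the distance regression", call. = FALSE)
  X[X == 0] <- zero_replacement
  Y[Y == 0] <- zero_replacement
  structure(list(
    dependent = -log(Y[, 1]),
    input_logs = log(X),
    output_ratio_logs = log(Y[, -1, drop = FALSE] / Y[, 1]),
    zero_replacement = zero_replacement), class = "regression_data")
}

# E(u | eps) for the normal/half-normal composed error eps = u + v, where the
# one-sided term raises the distance residual. gamma = eps * lambda / sigma;
# sigma_star = sigma * lambda / (1 + lambda^2). The inverse Mills ratio
# phi/Phi switches to its asymptotic expansion deep in the left tail, where
# the log-scale difference cancels catastrophically.
.jlms_core <- function(gamma) {
  mills <- numeric(length(gamma))
  deep <- gamma < -15
  g <- gamma[deep]
  mills[deep] <- -g / (1 - 1 / g^2 + 3 / g^4)
  g <- gamma[!deep]
  mills[!deep] <- exp(dnorm(g, log = TRUE) - pnorm(g, log.p = TRUE))
  mills + gamma
}

#' JLMS conditional inefficiency
#'
#' Expected inefficiency given the composed residual,
#' `E(u | eps) = sigma_star * (phi(gamma)/Phi(gamma) + gamma)` with
#' `gamma = eps * lambda / sigma` and
#' `sigma_star = sigma * lambda / (1 + lambda^2)`, under the normal /
#' half-normal model in which inefficiency enters the distance residual with
#' positive sign. Monotone increasing in the residual and strictly positive.
#'
#' @param residuals composed residuals of the distance regression.
#' @param sigma total standard deviation `sqrt(sigma_u^2 + sigma_v^2)`.
#' @param lam signal-to-noise ratio `sigma_u / sigma_v` (> 0).
#' @return vector of conditional mean inefficiencies.
#' @export
jlms_inefficiency <- function(residuals, sigma, lam) {
  stopifnot(sigma > 0, lam > 0)
  gamma <- residuals * lam / sigma
  sigma_star <- sigma * lam / (1 + lam^2)
  sigma_star * .jlms_core(gamma)
}

#' Per-facility efficiency from a fitted distance function
#'
#' @param fit an `rsdf_fit` from [fit_rsdf_cd()].
#' @return vector of efficiencies `exp(-E(u|eps))`, clipped to (0, 1].
#' @export
jlms_efficiency <- function(fit) {
  stopifnot(inherits(fit, "rsdf_fit"))
  u <- jlms_inefficiency(fit$residuals, fit$sigma, fit$lam)
  pmin(pmax(exp(-u), .Machine$double.xmin), 1)
}

#' Fit the restricted Cobb-Douglas stochastic output distance function
#'
#' Maximizes the normal/half-normal composed-error log-likelihood of the
#' log-linear distance model by bounded quasi-Newton optimization, under the
#' economic-interpretability restrictions that every input coefficient is
#' negative, every output-ratio coefficient positive, and the signal-to-noise
#' ratio `lambda = sigma_u / sigma_v` strictly positive (enforced as box
#' constraints offset slightly from zero). Starting values come from ordinary
#' least squares with the variance split by the method of moments on the
#' residual skewness; additional jittered restarts guard against local
#' optima, and the best converged likelihood wins.
#'
#' @param data a `regression_data` from [prepare_distance_regression()].
#' @param n_starts number of optimizer starts (first is the OLS start).
#' @param maxit iteration cap per start.
#' @return An `rsdf_fit` with frontier coefficients (`beta0`, `beta`,
#'   `alpha`), variance components (`sigma_u`, `sigma_v`, `sigma`, `lam`),
#'   per-facility `residuals`, `u_hat`, and `theta`, the attained `loglik`,
#'   and a `converged` flag (optimizer stalls are reported, not raised).
#' @export
fit_rsdf_cd <- function(data, n_starts = 5, maxit = 500) {
  stopifnot(inherits(data, "regression_data"))
  d <- data$dependent
  Z <- cbind(1, data$input_logs, data$output_ratio_logs)
  n <- nrow(Z)
  R <- ncol(data$input_logs)
  Jm1 <- ncol(data$output_ratio_logs)
  p <- ncol(Z)
  if (qr(Z)$rank < p)
    stop("distance regressors are rank deficient", call. = FALSE)

  negll <- function(par) {
    gam <- par[1:p]
    sigma <- sqrt(exp(par[p + 1]))
    lam <- exp(par[p + 2])
    eps <- d - drop(Z %*% gam)
    ll <- sum(log(2) - log(sigma) + dnorm(eps / sigma, log = TRUE) +
                pnorm(eps * lam / sigma, log.p = TRUE))
    if (!is.finite(ll)) 1e10 else -ll
  }

  # OLS start with method-of-moments variance split: for eps = u + v the
  # third central moment equals sqrt(2/pi) * (4/pi - 1) * sigma_u^3 > 0.
  ols <- lm.fit(Z, d)
  e <- ols$residuals
  m2 <- mean(e^2)
  m3 <- mean(e^3)
  k3 <- sqrt(2 / pi) * (4 / pi - 1)
  su2 <- if (m3 > 0) (m3 / k3)^(2 / 3) else 0.5 * m2
  sv2 <- m2 - su2 * (1 - 2 / pi)
  if (sv2 <= 1e-8 * m2) sv2 <- 0.1 * m2
  start_coef <- ols$coefficients
  start_coef[1] <- start_coef[1] - sqrt(su2) * sqrt(2 / pi)
  start_coef[2:(1 + R)] <- pmin(start_coef[2:(1 + R)], -1e-3)
  if (Jm1 > 0)
    start_coef[(2 + R):p] <- pmax(start_coef[(2 + R):p], 1e-3)
  start <- c(start_coef, log(su2 + sv2), 0.5 * log(su2 / sv2))

  eps0 <- 1e-8
  lower <- c(-Inf, rep(-Inf, R), rep(eps0, Jm1), -40, log(eps0))
  upper <- c(Inf, rep(-eps0, R), rep(Inf, Jm1), 20, log(1e8))
  start <- pmin(pmax(start, lower + 1e-6), upper - 1e-6)

  best <- NULL
  best_conv <- FALSE
  for (s in seq_len(n_starts)) {
    par0 <- if (s == 1) start else {
      j <- start + rnorm(length(start)) * (0.2 * abs(start) + 0.1)
      pmin(pmax(j, lower + 1e-6), upper - 1e-6)
    }
    fit <- tryCatch(
      optim(par0, negll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (fit$convergence != 0) {
      # boundary optima (lambda -> infinity in noise-free data) abort the
      # quasi-Newton line search; polish on the box-projected objective
      proj <- function(par) negll(pmin(pmax(par, lower), upper))
      nm <- tryCatch(optim(fit$par, proj, control = list(maxit = 4000)),
                     error = function(e) NULL)
      if (!is.null(nm) && is.finite(nm$value) && nm$value <= fit$value) {
        nm$par <- pmin(pmax(nm$par, lower), upper)
        fit <- nm
      }
    }
    conv <- fit$convergence == 0
    if (is.null(best) || (conv && !best_conv) ||
        (conv == best_conv && fit$value < best$value)) {
      best <- fit
      best_conv <- conv
    }
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)

  par <- best$par
  gam <- par[1:p]
  sigma <- sqrt(exp(par[p + 1]))
  lam <- exp(par[p + 2])
  eps <- d - drop(Z %*% gam)
  fit <- structure(list(
    beta0 = unname(gam[1]),
    beta = unname(gam[2:(1 + R)]),
    alpha = if (Jm1 > 0) unname(gam[(2 + R):p]) else numeric(0),
    sigma = sigma,
    lam = lam,
    sigma_u = sigma * lam / sqrt(1 + lam^2),
    sigma_v = sigma / sqrt(1 + lam^2),
    residuals = eps,
    loglik = -best$value,
    converged = best_conv,
    n = n), class = "rsdf_fit")
  fit$u_hat <- jlms_inefficiency(eps, sigma, lam)
  fit$theta <- pmin(pmax(exp(-fit$u_hat), .Machine$double.xmin), 1)
  fit
}

#' @export
print.rsdf_fit <- function(x, ...) {
  cat(sprintf(
    "<rsdf_fit: n = %d, logLik = %.3f, sigma_u = %.4f, sigma_v = %.4f, lambda = %.3f%s>\n",
    x$n, x$loglik, x$sigma_u, x$sigma_v, x$lam,
    if (!x$converged) ", NOT converged" else ""))
  cat("beta0:", format(x$beta0, digits = 4),
      " beta:", format(x$beta, digits = 4),
      " alpha:", format(x$alpha, digits = 4), "\n")
  invisible(x)
}
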