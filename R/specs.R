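#' Production technology specification
#'
#' Describes how the input vector is transformed into total productive
#' capacity `Y`. Four forms are supported:
#' \describe{
#'   \item{`linear`}{`Y = sum_r coef_r * x_r` (constant returns to scale).}
#'   \item{`linear_fixed`}{`Y = sum_r coef_r * (x_r - offset_r)`; each input
#'     has a fixed component that produces nothing.}
#'   \item{`cobb_douglas`}{`Y = A * prod_r x_r^coef_r`.}
#'   \item{`piecewise_cobb_douglas`}{Cobb-Douglas whose input exponent
#'     switches at a per-input breakpoint, joined continuously.}
#' }
#'
#' @param form one of `"linear"`, `"linear_fixed"`, `"cobb_douglas"`,
#'   `"piecewise_cobb_douglas"`.
#' @param input_coefficients length-`R` nonnegative vector: linear
#'   coefficients, or Cobb-Douglas exponents.
#' @param fixed_offsets length-`R` vector of fixed input components
#'   (`linear_fixed` only).
#' @param scale_constant positive scale constant `A` (Cobb-Douglas forms).
#' @param output_exponents length-`J` vector of distance-function output
#'   exponents summing to -1 (Cobb-Douglas forms).
#' @param piecewise_breakpoints length-`R` vector of input levels at which the
#'   exponent switches (piecewise form only).
#' @param piecewise_shift exponent offset: below the breakpoint the exponent
#'   is `coef + shift`, above it `coef - shift` (piecewise form only).
#' @return A `production_spec` object.
#' @export
production_spec <- function(form = c("linear", "linear_fixed", "cobb_douglas",
                                     "piecewise_cobb_douglas"),
                            input_coefficients,
                            fixed_offsets = NULL,
                            scale_constant = 1,
                            output_exponents = NULL,
                            piecewise_breakpoints = NULL,
                            piecewise_shift = 0.1) {
  form <- match.arg(form)
  input_coefficients <- as.numeric(input_coefficients)
  if (any(input_coefficients < 0))
    stop("input coefficients must be nonnegative", call. = FALSE)
  if (form == "linear_fixed") {
    if (is.null(fixed_offsets) ||
        length(fixed_offsets) != length(input_coefficients))
      stop("linear_fixed needs one fixed offset per input", call. = FALSE)
  }
  cd <- form %in% c("cobb_douglas", "piecewise_cobb_douglas")
  if (cd) {
    if (!is.numeric(scale_constant) || scale_constant <= 0)
      stop("scale_constant must be positive", call. = FALSE)
    if (!is.null(output_exponents) &&
        abs(sum(output_exponents) + 1) > 1e-12)
      stop("Cobb-Douglas output exponents must sum to -1", call. = FALSE)
  }
  if (form == "piecewise_cobb_douglas" && is.null(piecewise_breakpoints))
    stop("piecewise form needs breakpoints", call. = FALSE)
  structure(list(form = form, input_coefficients = input_coefficients,
                 fixed_offsets = fixed_offsets,
                 scale_constant = scale_constant,
                 output_exponents = output_exponents,
                 piecewise_breakpoints = piecewise_breakpoints,
                 piecewise_shift = piecewise_shift),
            class = "production_spec")
}

#' True-efficiency distribution specification
#'
#' @param distribution `"uniform01"` draws theta ~ unif(0,1) (the dispersed
#'   efficiency regime of low-resource settings); `"half_normal_exp"` draws
#'   theta = exp(-|N(0, sigma_u^2)|) (the traditional right-skewed regime in
#'   which most units operate near the frontier).
#' @param sigma_u standard deviation of the latent normal
#'   (`half_normal_exp` only).
#' @return An `efficiency_spec` object.
#' @export
efficiency_spec <- function(distribution = c("uniform01", "half_normal_exp"),
                            sigma_u = NULL) {
  distribution <- match.arg(distribution)
  if (distribution == "half_normal_exp") {
    if (is.null(sigma_u) || !is.numeric(sigma_u) || sigma_u <= 0)
      stop("half_normal_exp requires sigma_u > 0", call. = FALSE)
  }
  structure(list(distribution = distribution, sigma_u = sigma_u),
            class = "efficiency_spec")
}

#' Measurement-error specification
#'
#' @param kind `"none"`, `"additive"` (cell + N(0, sigma^2), negatives clamped
#'   to `negative_clamp`), `"multiplicative"` (cell * exp(N(0, sigma^2))), or
#'   `"mixed"` (a per-facility sigma mixture in which a fraction
#'   `high_fraction` of facilities receives `sigma_high` and the rest
#'   `sigma_low`, applied per `mixed_base`).
#' @param sigma_low noise standard deviation (the only sigma for non-mixed
#'   kinds).
#' @param sigma_high high-noise standard deviation (`mixed` only).
#' @param high_fraction fraction of facilities assigned `sigma_high`
#'   (`mixed` only); assignment uses a per-facility tau ~ unif(0,1) with
#'   threshold `1 - high_fraction`.
#' @param apply_to `"inputs_and_outputs"` or `"outputs_only"`.
#' @param negative_clamp replacement for negative cells after additive noise.
#' @param mixed_base perturbation type used by `kind = "mixed"`.
#' @return An `error_spec` object.
#' @export
error_spec <- function(kind = c("none", "additive", "multiplicative", "mixed"),
                       sigma_low = 0, sigma_high = NULL, high_fraction = 0,
                       apply_to = c("inputs_and_outputs", "outputs_only"),
                       negative_clamp = 0.01,
                       mixed_base = c("multiplicative", "additive")) {
  kind <- match.arg(kind)
  apply_to <- match.arg(apply_to)
  mixed_base <- match.arg(mixed_base)
  if (sigma_low < 0) stop("sigma_low must be nonnegative", call. = FALSE)
  if (kind == "mixed") {
    if (is.null(sigma_high) || sigma_high < 0 ||
        !is.numeric(high_fraction) || high_fraction < 0 || high_fraction > 1)
      stop("mixed errors need sigma_high >= 0 and high_fraction in [0,1]",
           call. = FALSE)
  }
  if (!is.numeric(negative_clamp) || negative_clamp <= 0)
    stop("negative_clamp must be positive", call. = FALSE)
  structure(list(kind = kind, sigma_low = sigma_low, sigma_high = sigma_high,
                 high_fraction = high_fraction, apply_to = apply_to,
                 negative_clamp = negative_clamp, mixed_base = mixed_base),
            class = "error_spec")
}

#' Input-distribution specification
#'
#' Inputs are marginally uniform on per-input supports, optionally correlated
#' through a Gaussian copula.
#'
#' @param lower_bounds,upper_bounds length-`R` support bounds,
#'   `lower < upper` componentwise.
#' @param correlation_matrix optional `R x R` target Pearson correlation
#'   matrix for the uniform margins (identity = independent).
#' @return An `input_spec` object.
#' @export
input_spec <- function(lower_bounds, upper_bounds, correlation_matrix = NULL) {
  lower_bounds <- as.numeric(lower_bounds)
  upper_bounds <- as.numeric(upper_bounds)
  if (length(lower_bounds) != length(upper_bounds))
    stop("bound vectors must have equal length", call. = FALSE)
  if (any(lower_bounds >= upper_bounds))
    stop("lower bounds must be below upper bounds", call. = FALSE)
  R <- length(lower_bounds)
  if (!is.null(correlation_matrix)) {
    correlation_matrix <- as.matrix(correlation_matrix)
    if (!all(dim(correlation_matrix) == c(R, R)) ||
        any(abs(diag(correlation_matrix) - 1) > 1e-12) ||
        any(abs(correlation_matrix - t(correlation_matrix)) > 1e-12))
      stop("correlation matrix must be symmetric with unit diagonal",
           call. = FALSE)
  }
  structure(list(lower_bounds = lower_bounds, upper_bounds = upper_bounds,
                 correlation_matrix = correlation_matrix),
            class = "input_spec")
}

#' Output-portfolio specification
#'
#' Controls which outputs each facility produces and how effective capacity is
#' split among them. One output (by default the last) is produced by every
#' facility; the remaining outputs enter a facility's portfolio independently
#' with the given probabilities. Capacity is divided among the produced
#' outputs by a flat Dirichlet draw, and each output's observed volume equals
#' its capacity share divided by its resource intensity.
#'
#' @param production_probabilities length-`J` vector of portfolio
#'   probabilities; the `always_produced` entry must be 1.
#' @param intensities length-`J` vector of positive resource intensities (the
#'   per-unit capacity cost of each output).
#' @param always_produced index of the universally produced output.
#' @return An `output_mix_spec` object.
#' @export
output_mix_spec <- function(production_probabilities = c(0.5, 0.5, 1),
                            intensities = c(0.25, 0.5, 1),
                            always_produced = length(production_probabilities)) {
  p <- as.numeric(production_probabilities)
  intensities <- as.numeric(intensities)
  if (length(p) != length(intensities))
    stop("probabilities and intensities must have equal length", call. = FALSE)
  if (any(p < 0) || any(p > 1))
    stop("production probabilities must lie in [0, 1]", call. = FALSE)
  if (p[always_produced] != 1)
    stop("the always-produced output must have probability 1", call. = FALSE)
  if (any(intensities <= 0))
    stop("intensities must be strictly positive", call. = FALSE)
  structure(list(production_probabilities = p, intensities = intensities,
                 always_produced = always_produced),
            class = "output_mix_spec")
}
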