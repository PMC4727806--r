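#' Draw facility inputs
#'
#' Inputs are marginally uniform on the supports in `spec`. When a target
#' correlation matrix is present, draws go through a Gaussian copula: the
#' latent normal correlation is set to `2 * sin(pi * r / 6)` so the uniform
#' margins attain the target Pearson correlation `r`, then mapped through the
#' normal CDF onto each support.
#'
#' Uses R's global random-number stream; seed with [set.seed()] or via
#' [generate_panel()].
#'
#' @param spec an [input_spec()].
#' @param n number of facilities.
#' @return `n x R` matrix of inputs.
#' @export
draw_inputs <- function(spec, n) {
  stopifnot(inherits(spec, "input_spec"), n >= 1)
  R <- length(spec$lower_bounds)
  C <- spec$correlation_matrix
  if (is.null(C)) {
    U <- matrix(runif(n * R), n, R)
  } else {
    Cz <- 2 * sin(pi * C / 6)
    diag(Cz) <- 1
    ch <- tryCatch(chol(Cz), error = function(e) NULL)
    if (is.null(ch))
      stop("correlation matrix is not positive definite under the copula map",
           call. = FALSE)
    Z <- matrix(rnorm(n * R), n, R) %*% ch
    U <- pnorm(Z)
  }
  X <- sweep(U, 2, spec$upper_bounds - spec$lower_bounds, "*")
  X <- sweep(X, 2, spec$lower_bounds, "+")
  colnames(X) <- paste0("x", seq_len(R))
  X
}

#' Draw true facility efficiencies
#'
#' @param spec an [efficiency_spec()].
#' @param n number of facilities.
#' @return length-`n` vector of efficiencies in (0, 1].
#' @export
draw_true_efficiency <- function(spec, n) {
  stopifnot(inherits(spec, "efficiency_spec"), n >= 1)
  theta <- switch(spec$distribution,
    uniform01 = runif(n),
    half_normal_exp = exp(-abs(rnorm(n, 0, spec$sigma_u))))
  theta[theta == 0] <- .Machine$double.eps
  theta
}

#' Total productive capacity of each facility
#'
#' Evaluates the frontier technology of `spec` at the given inputs: the
#' maximal capacity a fully efficient facility could convert into outputs.
#'
#' @param inputs `n x R` input matrix.
#' @param spec a [production_spec()].
#' @return length-`n` capacity vector.
#' @export
compute_capacity <- function(inputs, spec) {
  stopifnot(inherits(spec, "production_spec"))
  inputs <- as.matrix(inputs)
  b <- spec$input_coefficients
  if (ncol(inputs) != length(b))
    stop("input matrix width does not match the technology", call. = FALSE)
  switch(spec$form,
    linear = drop(inputs %*% b),
    linear_fixed = {
      off <- spec$fixed_offsets
      if (any(sweep(inputs, 2, off, "-") < -1e-12))
        stop("inputs below their fixed components", call. = FALSE)
      drop(sweep(inputs, 2, off, "-") %*% b)
    },
    cobb_douglas = {
      if (any(inputs <= 0))
        stop("Cobb-Douglas technology requires strictly positive inputs",
             call. = FALSE)
      spec$scale_constant * exp(drop(log(inputs) %*% b))
    },
    piecewise_cobb_douglas = {
      if (any(inputs <= 0))
        stop("Cobb-Douglas technology requires strictly positive inputs",
             call. = FALSE)
      brk <- spec$piecewise_breakpoints
      s <- spec$piecewise_shift
      lg <- matrix(0, nrow(inputs), ncol(inputs))
      for (r in seq_along(b)) {
        e_lo <- b[r] + s
        e_hi <- b[r] - s
        x <- inputs[, r]
        # continuous join at the breakpoint
        lg[, r] <- ifelse(x <= brk[r], e_lo * log(x),
                          (e_lo - e_hi) * log(brk[r]) + e_hi * log(x))
      }
      spec$scale_constant * exp(rowSums(lg))
    })
}

#' Allocate effective capacity to outputs
#'
#' Each facility's portfolio contains the universally produced output plus
#' each other output independently with its portfolio probability. Effective
#' capacity is split over the portfolio by a flat Dirichlet draw, and the
#' observed volume of output `j` is its capacity share divided by its
#' resource intensity, so that `sum_j intensity_j * y_j` equals effective
#' capacity exactly.
#'
#' @param capacity_effective length-`n` vector of effective capacity
#'   (true efficiency times frontier capacity).
#' @param mix an [output_mix_spec()].
#' @param intensities per-output resource intensities; defaults to the ones
#'   carried by `mix`.
#' @return list with `shares` (`n x J` capacity shares) and `outputs`
#'   (`n x J` observed volumes).
#' @export
allocate_outputs <- function(capacity_effective, mix,
                             intensities = mix$intensities) {
  stopifnot(inherits(mix, "output_mix_spec"))
  if (any(capacity_effective < 0))
    stop("effective capacity must be nonnegative", call. = FALSE)
  n <- length(capacity_effective)
  J <- length(mix$production_probabilities)
  produced <- matrix(runif(n * J), n, J) <
    matrix(mix$production_probabilities, n, J, byrow = TRUE)
  produced[, mix$always_produced] <- TRUE
  # flat Dirichlet over the produced set: normalized unit exponentials
  w <- matrix(rexp(n * J), n, J)
  w[!produced] <- 0
  w <- w / rowSums(w)
  shares <- w * capacity_effective
  outputs <- sweep(shares, 2, intensities, "/")
  colnames(outputs) <- paste0("y", seq_len(J))
  colnames(shares) <- paste0("y", seq_len(J))
  list(shares = shares, outputs = outputs)
}

#' Perturb a panel with measurement error
#'
#' Applies the noise model in `spec` to the observed inputs and outputs while
#' leaving the simulation truth (true efficiency, capacity, shares)
#' untouched. Additive noise adds `N(0, sigma^2)` to every cell and replaces
#' resulting negatives with the configured small positive clamp;
#' multiplicative noise scales every cell by `exp(N(0, sigma^2))`. Under the
#' mixed kind each facility first draws `tau ~ unif(0, 1)` and receives the
#' high sigma when `tau` exceeds `1 - high_fraction`.
#'
#' @param panel a [facility_panel()].
#' @param spec an [error_spec()].
#' @return a new [facility_panel()] with perturbed observables.
#' @export
apply_measurement_error <- function(panel, spec) {
  stopifnot(inherits(panel, "facility_panel"), inherits(spec, "error_spec"))
  if (spec$kind == "none") return(panel)
  n <- n_facilities(panel)
  if (spec$kind == "mixed") {
    tau <- runif(n)
    sig <- ifelse(tau > 1 - spec$high_fraction, spec$sigma_high, spec$sigma_low)
    type <- spec$mixed_base
  } else {
    sig <- rep(spec$sigma_low, n)
    type <- spec$kind
  }
  perturb <- function(M) {
    noise <- matrix(rnorm(length(M)), nrow(M), ncol(M)) * sig  # sig recycles by row
    if (type == "additive") {
      M <- M + noise
      M[M < 0] <- spec$negative_clamp
    } else {
      M <- M * exp(noise)
    }
    M
  }
  inputs <- panel$inputs
  if (spec$apply_to == "inputs_and_outputs") inputs <- perturb(inputs)
  outputs <- perturb(panel$outputs)
  facility_panel(inputs, outputs, theta_true = panel$theta_true,
                 capacity = panel$capacity, shares = panel$shares)
}

#' Generate one replication of a simulation scenario
#'
#' Draws a complete facility panel with known true efficiency under the
#' data-generating process described by a [scenario_config()]. For linear
#' technologies, effective capacity is split across the output portfolio by
#' [allocate_outputs()]. For Cobb-Douglas technologies the panel follows the
#' distance-function construction: all outputs but the first are drawn
#' uniformly on the configured support and the first output is solved from
#' the distance identity `D(x, y) = theta`, so the Cobb-Douglas distance
#' regression holds exactly by construction.
#'
#' @param config a [scenario_config()] or preset name (see
#'   [scenario_preset()]).
#' @param seed integer replication seed; the same seed reproduces the panel
#'   bit for bit.
#' @return a [facility_panel()] with truth fields populated.
#' @export
generate_panel <- function(config, seed) {
  if (is.character(config)) config <- scenario_preset(config)
  stopifnot(inherits(config, "scenario_config"))
  set.seed(seed)
  n <- config$n
  X <- draw_inputs(config$inputs, n)
  theta <- draw_true_efficiency(config$efficiency, n)
  Y <- compute_capacity(X, config$production)
  Yeff <- theta * Y
  cd <- config$production$form %in% c("cobb_douglas", "piecewise_cobb_douglas")
  if (!cd) {
    alloc <- allocate_outputs(Yeff, config$mix)
    panel <- facility_panel(X, alloc$outputs, theta_true = theta,
                            capacity = Yeff, shares = alloc$shares)
  } else {
    a <- config$production$output_exponents
    J <- length(a)
    sup <- config$cd_output_support
    # draw a provisional uniform output vector to fix each facility's output
    # mix, then rescale it radially so the output distance equals theta:
    # with y = s * ytilde, D(x, y) = theta gives
    # s = theta * Y * prod_j ytilde_j^(a_j). The mix ratios stay independent
    # of efficiency, so the distance regression has exogenous regressors.
    Ytilde <- matrix(runif(n * J, sup[1], sup[2]), n, J)
    s <- theta * Y * exp(drop(log(Ytilde) %*% a))
    Yout <- Ytilde * s
    colnames(Yout) <- paste0("y", seq_len(J))
    panel <- facility_panel(X, Yout, theta_true = theta, capacity = Yeff)
  }
  apply_measurement_error(panel, config$error)
}
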