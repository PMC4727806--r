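#' Simulation scenario configuration
#'
#' Bundles every ingredient of a Monte-Carlo scenario: the data-generating
#' process (input distribution, technology, efficiency distribution,
#' measurement error, output portfolio), the sample size, the replication
#' count and base seed, and the estimators to run.
#'
#' @param name scenario identifier.
#' @param n number of facilities per replication (>= 3).
#' @param production a [production_spec()].
#' @param efficiency an [efficiency_spec()].
#' @param inputs an [input_spec()].
#' @param mix an [output_mix_spec()] (ignored by Cobb-Douglas technologies,
#'   which use the distance-function construction).
#' @param error an [error_spec()].
#' @param reps number of replications (>= 1).
#' @param seed base seed; replication `k` uses the derived child seed
#'   [child_seed()]`(seed, k)`.
#' @param methods subset of `"DEA"`, `"rDEA"`, `"rSDF-CD"`, `"ENS"`.
#' @param rdea_percentiles percentile pair for the rDEA weight restrictions;
#'   `c(0, 0)` means unrestricted DEA.
#' @param cd_output_support uniform support on which the non-normalizing
#'   outputs are drawn under Cobb-Douglas technologies.
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(name, n, production, efficiency, inputs,
                            mix = output_mix_spec(),
                            error = error_spec("none"),
                            reps = 2000, seed = 1,
                            methods = c("DEA", "rDEA", "rSDF-CD", "ENS"),
                            rdea_percentiles = c(40, 60),
                            cd_output_support = c(1, 15)) {
  stopifnot(inherits(production, "production_spec"),
            inherits(efficiency, "efficiency_spec"),
            inherits(inputs, "input_spec"),
            inherits(mix, "output_mix_spec"),
            inherits(error, "error_spec"))
  if (n < 3) stop("scenarios need n >= 3", call. = FALSE)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  methods <- match.arg(methods, c("DEA", "rDEA", "rSDF-CD", "ENS"),
                       several.ok = TRUE)
  structure(list(name = name, n = n, production = production,
                 efficiency = efficiency, inputs = inputs, mix = mix,
                 error = error, reps = reps, seed = seed, methods = methods,
                 rdea_percentiles = rdea_percentiles,
                 cd_output_support = cd_output_support),
            class = "scenario_config")
}

#' Derived replication seed
#'
#' Deterministic child seed for replication `k` of base seed `base`,
#' independent of the total replication count, so replications can be run
#' serially or in parallel with identical results.
#'
#' @param base integer base seed.
#' @param k replication number (1-based).
#' @return integer seed below 2^31.
#' @export
child_seed <- function(base, k) {
  as.integer((1009 * (base %% 2^31) + 7919 * k) %% 2147483647)
}

#' Named scenario presets
#'
#' Ready-made configurations for the baseline low-resource scenario and all
#' its studied variations. `scenario_presets()` lists the available names.
#'
#' Presets: `baseline` (n = 200, linear CRS technology
#' `Y = 0.2 x1 + 0.5 x2 + 0.3 x3`, inputs uniform on (0,5)/(0,10)/(0,8),
#' theta ~ unif(0,1), portfolio allocation with intensities 0.25/0.5/1, no
#' noise); `correlated_inputs` (input correlations 0.60/0.40/0.10);
#' `fixed_inputs` (fixed input components 0.5/2.0/0.1 with shifted supports);
#' `additive_error_low`/`_high`, `multiplicative_error_low`/`_high`
#' (sigma 0.02 / 0.08), `mixed_error` (85% low, 15% high);
#' `halfnormal_low`/`_high` (theta = exp(-|N(0, sigma_u^2)|), sigma_u 0.05 /
#' 0.20); `cobb_douglas` and `piecewise_cobb_douglas` (inputs unif(1,15),
#' exponents 0.2/0.5/0.3, output exponents -1/3 each);
#' `traditional_hn_low`/`_high` and `traditional_unif_low`/`_high`
#' (Cobb-Douglas technology with multiplicative output-only noise 0.02 /
#' 0.08 and half-normal 0.05 / 0.20 or uniform efficiency).
#'
#' @param name preset name.
#' @param n,reps,seed,methods,rdea_percentiles overrides of the preset
#'   defaults.
#' @return A [scenario_config()].
#' @export
scenario_preset <- function(name, n = NULL, reps = NULL, seed = NULL,
                            methods = NULL, rdea_percentiles = NULL) {
  base_inputs <- input_spec(c(0, 0, 0), c(5, 10, 8))
  linear <- production_spec("linear", c(0.2, 0.5, 0.3))
  unif_eff <- efficiency_spec("uniform01")
  cd <- production_spec("cobb_douglas", c(0.2, 0.5, 0.3),
                        output_exponents = rep(-1 / 3, 3))
  cd_inputs <- input_spec(c(1, 1, 1), c(15, 15, 15))
  args <- switch(name,
    baseline = list(production = linear, efficiency = unif_eff,
                    inputs = base_inputs),
    correlated_inputs = {
      C <- diag(3)
      C[1, 2] <- C[2, 1] <- 0.60
      C[1, 3] <- C[3, 1] <- 0.40
      C[2, 3] <- C[3, 2] <- 0.10
      list(production = linear, efficiency = unif_eff,
           inputs = input_spec(c(0, 0, 0), c(5, 10, 8),
                               correlation_matrix = C))
    },
    fixed_inputs = list(
      production = production_spec("linear_fixed", c(0.2, 0.5, 0.3),
                                   fixed_offsets = c(0.5, 2.0, 0.1)),
      efficiency = unif_eff,
      inputs = input_spec(c(0.5, 2.0, 0.1), c(5, 10, 8))),
    additive_error_low = list(production = linear, efficiency = unif_eff,
      inputs = base_inputs, error = error_spec("additive", 0.02)),
    additive_error_high = list(production = linear, efficiency = unif_eff,
      inputs = base_inputs, error = error_spec("additive", 0.08)),
    multiplicative_error_low = list(production = linear,
      efficiency = unif_eff, inputs = base_inputs,
      error = error_spec("multiplicative", 0.02)),
    multiplicative_error_high = list(production = linear,
      efficiency = unif_eff, inputs = base_inputs,
      error = error_spec("multiplicative", 0.08)),
    mixed_error = list(production = linear, efficiency = unif_eff,
      inputs = base_inputs,
      error = error_spec("mixed", 0.02, 0.08, high_fraction = 0.15)),
    halfnormal_low = list(production = linear,
      efficiency = efficiency_spec("half_normal_exp", sigma_u = 0.05),
      inputs = base_inputs),
    halfnormal_high = list(production = linear,
      efficiency = efficiency_spec("half_normal_exp", sigma_u = 0.20),
      inputs = base_inputs),
    cobb_douglas = list(production = cd, efficiency = unif_eff,
                        inputs = cd_inputs),
    piecewise_cobb_douglas = list(
      production = production_spec("piecewise_cobb_douglas", c(0.2, 0.5, 0.3),
                                   output_exponents = rep(-1 / 3, 3),
                                   piecewise_breakpoints = c(8, 8, 8)),
      efficiency = unif_eff, inputs = cd_inputs),
    traditional_hn_low = list(production = cd,
      efficiency = efficiency_spec("half_normal_exp", sigma_u = 0.05),
      inputs = cd_inputs,
      error = error_spec("multiplicative", 0.02, apply_to = "outputs_only")),
    traditional_hn_high = list(production = cd,
      efficiency = efficiency_spec("half_normal_exp", sigma_u = 0.20),
      inputs = cd_inputs,
      error = error_spec("multiplicative", 0.08, apply_to = "outputs_only")),
    traditional_unif_low = list(production = cd, efficiency = unif_eff,
      inputs = cd_inputs,
      error = error_spec("multiplicative", 0.02, apply_to = "outputs_only")),
    traditional_unif_high = list(production = cd, efficiency = unif_eff,
      inputs = cd_inputs,
      error = error_spec("multiplicative", 0.08, apply_to = "outputs_only")),
    stop(sprintf("unknown scenario preset '%s'", name), call. = FALSE))
  base <- list(name = name, n = 200, reps = 2000, seed = 1)
  if (!is.null(n)) base$n <- n
  if (!is.null(reps)) base$reps <- reps
  if (!is.null(seed)) base$seed <- seed
  if (!is.null(methods)) base$methods <- methods
  if (!is.null(rdea_percentiles)) base$rdea_percentiles <- rdea_percentiles
  do.call(scenario_config, c(base, args))
}

#' @rdname scenario_preset
#' @export
scenario_presets <- function() {
  c("baseline", "correlated_inputs", "fixed_inputs",
    "additive_error_low", "additive_error_high",
    "multiplicative_error_low", "multiplicative_error_high", "mixed_error",
    "halfnormal_low", "halfnormal_high",
    "cobb_douglas", "piecewise_cobb_douglas",
    "traditional_hn_low", "traditional_hn_high",
    "traditional_unif_low", "traditional_unif_high")
}

#' Estimate efficiency on one panel with the requested methods
#'
#' Runs the shared super-efficiency filter once, scores DEA, derives
#' percentile weight bounds from the filtered unrestricted weights, scores
#' rDEA, fits the restricted distance function, and forms the ensemble.
#'
#' @param panel a [facility_panel()].
#' @param methods subset of `"DEA"`, `"rDEA"`, `"rSDF-CD"`, `"ENS"`.
#' @param rdea_percentiles percentile pair for the weight restrictions;
#'   `c(0, 0)` reproduces unrestricted DEA.
#' @return named list of per-facility score vectors, one per requested
#'   method.
#' @export
estimate_scores <- function(panel, methods = c("DEA", "rDEA", "rSDF-CD", "ENS"),
                            rdea_percentiles = c(40, 60)) {
  methods <- match.arg(methods, c("DEA", "rDEA", "rSDF-CD", "ENS"),
                       several.ok = TRUE)
  need_rdea <- any(c("rDEA", "ENS") %in% methods)
  need_sdf <- any(c("rSDF-CD", "ENS") %in% methods)
  need_dea <- "DEA" %in% methods
  out <- list()
  if (need_dea || need_rdea) {
    filt <- super_efficiency_filter(panel)
    if (need_dea) out$DEA <- filt$scores
    if (need_rdea) {
      out$rDEA <- if (all(rdea_percentiles == 0)) filt$scores else {
        b <- relative_weight_bounds(filt, rdea_percentiles[1],
                                    rdea_percentiles[2])
        rdea_scores(panel, b, filter = filt)$scores
      }
    }
  }
  if (need_sdf) {
    fit <- fit_rsdf_cd(prepare_distance_regression(panel))
    if (!fit$converged)
      stop("distance-function fit did not converge", call. = FALSE)
    out[["rSDF-CD"]] <- fit$theta
  }
  if ("ENS" %in% methods)
    out$ENS <- ensemble_scores(out$rDEA, out[["rSDF-CD"]])
  out[methods]
}

perf_row <- function(scenario, method, summary, n_failed = 0L) {
  data.frame(scenario = scenario, method = method,
             mad = summary$mad, notfront = summary$notfront,
             pu20 = summary$pu20, po20 = summary$po20,
             spearman = summary$spearman,
             n_replications = summary$n_replications,
             n_failed = n_failed, stringsAsFactors = FALSE)
}

#' Run a Monte-Carlo scenario
#'
#' Generates `reps` independent panels, estimates efficiency with every
#' requested method, evaluates the five performance criteria against the
#' known truth, and averages them over replications. Replications that fail
#' (a non-converged distance-function fit or an LP failure) are logged and
#' excluded; the run aborts if more than `max_failure_rate` of replications
#' fail.
#'
#' @param config a [scenario_config()] or preset name.
#' @param verbose print per-replication progress.
#' @param max_failure_rate abort threshold for the excluded-replication
#'   fraction.
#' @return data frame with one row per method: scenario, method, the five
#'   averaged criteria, the replication and failure counts.
#' @export
run_scenario <- function(config, verbose = FALSE, max_failure_rate = 0.05) {
  if (is.character(config)) config <- scenario_preset(config)
  stopifnot(inherits(config, "scenario_config"))
  sums <- list()
  n_failed <- 0L
  for (k in seq_len(config$reps)) {
    panel <- generate_panel(config, child_seed(config$seed, k))
    est <- tryCatch(
      estimate_scores(panel, config$methods, config$rdea_percentiles),
      error = function(e) e)
    if (inherits(est, "error")) {
      n_failed <- n_failed + 1L
      message(sprintf("replication %d excluded: %s", k, conditionMessage(est)))
      if (n_failed > max_failure_rate * config$reps)
        stop(sprintf("aborting: %d of %d replications failed", n_failed, k),
             call. = FALSE)
      next
    }
    sums[[length(sums) + 1L]] <-
      lapply(est, function(th) performance_metrics(panel$theta_true, th))
    if (verbose && k %% 50 == 0)
      message(sprintf("%s: replication %d/%d", config$name, k, config$reps))
  }
  if (length(sums) == 0) stop("all replications failed", call. = FALSE)
  rows <- lapply(config$methods, function(m) {
    perf_row(config$name, m,
             aggregate_replications(lapply(sums, `[[`, m)), n_failed)
  })
  out <- do.call(rbind, rows)
  if (n_failed > 0)
    message(sprintf("%s: excluded %d of %d replications", config$name,
                    n_failed, config$reps))
  out
}

#' Sweep rDEA percentile pairs on one scenario
#'
#' Re-uses each replication's panel, super-efficiency filter and first-stage
#' weights across all percentile pairs, scoring rDEA once per pair. The
#' `(0, 0)` pair denotes unrestricted DEA.
#'
#' @param config a [scenario_config()] or preset name.
#' @param pairs list of percentile pairs `c(p_low, p_high)`.
#' @param verbose print progress.
#' @return data frame with one row per pair carrying the averaged criteria
#'   and the pair in columns `p_low`, `p_high`.
#' @export
percentile_sweep <- function(config,
                             pairs = list(c(0, 0), c(20, 80), c(25, 75),
                                          c(30, 70), c(35, 65), c(40, 60),
                                          c(45, 55), c(50, 50)),
                             verbose = FALSE) {
  if (is.character(config)) config <- scenario_preset(config)
  stopifnot(inherits(config, "scenario_config"))
  sums <- lapply(pairs, function(p) list())
  for (k in seq_len(config$reps)) {
    panel <- generate_panel(config, child_seed(config$seed, k))
    filt <- super_efficiency_filter(panel)
    for (i in seq_along(pairs)) {
      p <- pairs[[i]]
      th <- if (all(p == 0)) filt$scores else {
        b <- relative_weight_bounds(filt, p[1], p[2])
        rdea_scores(panel, b, filter = filt)$scores
      }
      sums[[i]][[k]] <- performance_metrics(panel$theta_true, th)
    }
    if (verbose && k %% 50 == 0)
      message(sprintf("sweep: replication %d/%d", k, config$reps))
  }
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    lab <- if (all(p == 0)) "0-0 (DEA)" else sprintf("%g-%g", p[1], p[2])
    cbind(perf_row(config$name, sprintf("rDEA %s", lab),
                   aggregate_replications(sums[[i]])),
          p_low = p[1], p_high = p[2])
  })
  do.call(rbind, rows)
}

#' Write a results table as CSV
#'
#' @param results data frame from [run_scenario()] or [percentile_sweep()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  write.csv(results, path, row.names = FALSE)
  invisible(path)
}
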