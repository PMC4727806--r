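#' Ensemble efficiency scores
#'
#' The ensemble estimator is the per-facility arithmetic mean of the
#' restricted-DEA and restricted-SDF efficiency scores.
#'
#' @param theta_rdea,theta_rsdf equal-length score vectors in (0, 1].
#' @return elementwise mean vector.
#' @export
ensemble_scores <- function(theta_rdea, theta_rsdf) {
  if (length(theta_rdea) != length(theta_rsdf))
    stop("score vectors must have equal length", call. = FALSE)
  if (anyNA(theta_rdea) || anyNA(theta_rsdf))
    stop("score vectors must not contain missing values", call. = FALSE)
  if (any(theta_rdea <= 0 | theta_rdea > 1) ||
      any(theta_rsdf <= 0 | theta_rsdf > 1))
    stop("scores must lie in (0, 1]", call. = FALSE)
  (theta_rdea + theta_rsdf) / 2
}

#' Performance criteria for one replication
#'
#' Five criteria comparing estimated to true efficiency:
#' \describe{
#'   \item{mad}{median absolute deviation `median(|theta_true - theta_est|)`.}
#'   \item{pu20}{percentage of facilities whose efficiency is underestimated
#'     by more than 20 percent of its true value
#'     (`(theta_true - theta_est) / theta_true > 0.20`, strict); deviations
#'     of this size would typically move a facility across efficiency-grade
#'     boundaries.}
#'   \item{po20}{percentage overestimated by more than 20 percent of true
#'     efficiency.}
#'   \item{notfront}{percentage scored fully efficient (within `1e-6` of one,
#'     absorbing LP round-off) whose true efficiency is below 0.80.}
#'   \item{spearman}{Spearman rank correlation with average ranks for ties;
#'     reported as `NA` (with a warning) when either vector has fewer than
#'     two distinct values.}
#' }
#'
#' @param theta_true,theta_est equal-length vectors (length >= 2).
#' @return A one-replication `perf_summary` (named list).
#' @export
performance_metrics <- function(theta_true, theta_est) {
  if (length(theta_true) != length(theta_est) || length(theta_true) < 2)
    stop("need two equal-length vectors of at least two facilities",
         call. = FALSE)
  if (anyNA(theta_true) || anyNA(theta_est))
    stop("missing values in efficiency vectors", call. = FALSE)
  dev <- theta_true - theta_est
  sp <- if (length(unique(theta_true)) < 2 || length(unique(theta_est)) < 2) {
    warning("fewer than two distinct values; Spearman correlation undefined",
            call. = FALSE)
    NA_real_
  } else {
    cor(theta_true, theta_est, method = "spearman")
  }
  structure(list(
    mad = median(abs(dev)),
    notfront = 100 * mean(theta_est >= 1 - 1e-6 & theta_true < 0.80),
    pu20 = 100 * mean(dev / theta_true > 0.20),
    po20 = 100 * mean(-dev / theta_true > 0.20),
    spearman = sp,
    n_replications = 1L), class = "perf_summary")
}

#' Average performance criteria over replications
#'
#' Unweighted mean of each criterion; replications whose Spearman correlation
#' is undefined are excluded from that criterion's average only.
#'
#' @param summaries non-empty list of `perf_summary` objects.
#' @return A `perf_summary` with `n_replications` set to the list length.
#' @export
aggregate_replications <- function(summaries) {
  if (length(summaries) == 0) stop("no replications to aggregate", call. = FALSE)
  stopifnot(all(vapply(summaries, inherits, TRUE, "perf_summary")))
  get <- function(f) vapply(summaries, `[[`, numeric(1), f)
  structure(list(
    mad = mean(get("mad")),
    notfront = mean(get("notfront")),
    pu20 = mean(get("pu20")),
    po20 = mean(get("po20")),
    spearman = mean(get("spearman"), na.rm = TRUE),
    n_replications = sum(vapply(summaries, `[[`, integer(1),
                                "n_replications"))), class = "perf_summary")
}

#' @export
print.perf_summary <- function(x, ...) {
  cat(sprintf(
    "MAD %.3f | NOTFront %.1f%% | PU20 %.1f%% | PO20 %.1f%% | rs %.3f (%d reps)\n",
    x$mad, x$notfront, x$pu20, x$po20, x$spearman, x$n_replications))
  invisible(x)
}
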