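#' Output-oriented CRS DEA scores (CCR multiplier form)
#'
#' For every evaluated facility the CCR multiplier linear program is solved:
#' maximize the weighted output sum `u'y_o` subject to the normalization
#' `v'x_o = 1`, the frontier constraints `u'y_k - v'x_k <= 0` for every
#' facility `k` in the reference set, and nonnegative weights. Under constant
#' returns to scale this optimum equals the output-oriented efficiency score
#' on (0, 1]. Computation solves the (much smaller) envelopment dual and
#' reads the multiplier weights off its dual prices.
#'
#' @param panel a [facility_panel()].
#' @param reference integer indices of the facilities spanning the
#'   technology (default: all).
#' @param evaluate integer indices of the facilities to score (default: all).
#' @param exclude_self drop each evaluated facility from its own reference
#'   set (super-efficiency mode; scores may exceed 1, and a facility whose
#'   output mix no peer can span gets `Inf`).
#' @param bounds optional [weight_bounds()] adding assurance-region
#'   restrictions (restricted DEA).
#' @return A `dea_result`: per-facility `scores`, multiplier weight matrices
#'   `u` (`n x J`) and `v` (`n x R`), `outlier_flags`, and `super_scores`
#'   (populated by [super_efficiency_filter()]).
#' @export
dea_scores <- function(panel, reference = NULL, evaluate = NULL,
                       exclude_self = FALSE, bounds = NULL) {
  stopifnot(inherits(panel, "facility_panel"))
  n <- n_facilities(panel)
  if (n < 2) stop("DEA needs at least two facilities", call. = FALSE)
  if (is.null(reference)) reference <- seq_len(n)
  if (is.null(evaluate)) evaluate <- seq_len(n)
  Lout <- Uout <- Lin <- Uin <- numeric(0)
  if (!is.null(bounds)) {
    stopifnot(inherits(bounds, "weight_bounds"))
    Lout <- bounds$output_lower; Uout <- bounds$output_upper
    Lin <- bounds$input_lower; Uin <- bounds$input_upper
  }
  res <- .ccr_batch_cpp(panel$inputs, panel$outputs,
                        as.integer(reference), as.integer(evaluate),
                        exclude_self, Lout, Uout, Lin, Uin)
  bad <- res$status > 1
  if (any(bad))
    stop(sprintf("LP solver failed for facility %d",
                 evaluate[which(bad)[1]]), call. = FALSE)
  scores <- as.numeric(res$scores)
  u <- res$u; v <- res$v
  u[u < 0 & u > -1e-9] <- 0
  v[v < 0 & v > -1e-9] <- 0
  if (!exclude_self) scores <- pmin(scores, 1)
  J <- ncol(panel$outputs); R <- ncol(panel$inputs)
  out <- list(scores = rep(NA_real_, n),
              u = matrix(NA_real_, n, J), v = matrix(NA_real_, n, R),
              outlier_flags = rep(FALSE, n),
              super_scores = rep(NA_real_, n),
              evaluated = evaluate)
  out$scores[evaluate] <- scores
  out$u[evaluate, ] <- u
  out$v[evaluate, ] <- v
  colnames(out$u) <- colnames(panel$outputs)
  colnames(out$v) <- colnames(panel$inputs)
  structure(out, class = "dea_result")
}

#' @export
print.dea_result <- function(x, ...) {
  sc <- x$scores[!is.na(x$scores)]
  cat(sprintf(
    "<dea_result: %d facilities scored, %d on frontier, %d flagged outliers>\n",
    length(sc), sum(sc >= 1 - 1e-6), sum(x$outlier_flags)))
  invisible(x)
}

#' Iterative super-efficiency outlier filter
#'
#' Computes leave-one-out (super-efficiency) CRS scores, in which each
#' facility is scored against the frontier spanned by all other retained
#' facilities and can exceed 1. While any super-score exceeds `threshold` and
#' fewer than `floor(cap_fraction * n)` facilities have been removed, the
#' facility with the largest super-score is removed and the analysis is
#' repeated. Removed facilities are flagged and assigned a final efficiency
#' score of one; the remaining facilities are scored in-sample against the
#' filtered reference set.
#'
#' @param panel a [facility_panel()].
#' @param threshold super-efficiency removal threshold.
#' @param cap_fraction maximum fraction of facilities removable.
#' @return A `dea_result` whose `outlier_flags` marks removed facilities and
#'   whose `super_scores` holds each facility's last computed leave-one-out
#'   score.
#' @export
super_efficiency_filter <- function(panel, threshold = 1.5,
                                    cap_fraction = 0.05) {
  n <- n_facilities(panel)
  if (n < 3) stop("super-efficiency filtering needs n >= 3", call. = FALSE)
  cap <- floor(cap_fraction * n)
  kept <- seq_len(n)
  removed <- integer(0)
  super <- rep(NA_real_, n)
  repeat {
    loo <- dea_scores(panel, reference = kept, evaluate = kept,
                      exclude_self = TRUE)
    super[kept] <- loo$scores[kept]
    worst <- kept[which.max(loo$scores[kept])]
    if (length(removed) >= cap || super[worst] <= threshold) break
    removed <- c(removed, worst)
    kept <- setdiff(kept, worst)
  }
  res <- dea_scores(panel, reference = kept, evaluate = kept)
  res$scores[removed] <- 1
  res$outlier_flags[removed] <- TRUE
  res$super_scores <- super
  res$kept <- kept
  res
}

#' Percentile bounds on relative DEA weights
#'
#' Pools, over the facilities scored in `result`, the ratios of each output
#' weight to the first output weight and each input weight to the first input
#' weight, keeping only facilities where both weights in a ratio exceed a
#' zero tolerance, and returns the requested lower/upper percentiles of each
#' ratio distribution (linear interpolation between order statistics).
#'
#' @param result a `dea_result` from [dea_scores()] or
#'   [super_efficiency_filter()] on the same panel.
#' @param p_low,p_high percentiles in [0, 100].
#' @param zero_tol weights at or below this value count as zero.
#' @return A `weight_bounds` object.
#' @export
relative_weight_bounds <- function(result, p_low = 40, p_high = 60,
                                   zero_tol = 1e-9) {
  stopifnot(inherits(result, "dea_result"),
            p_low >= 0, p_high <= 100, p_low <= p_high)
  use <- !is.na(result$scores) & !result$outlier_flags
  ratio_bounds <- function(W, what) {
    k <- ncol(W) - 1
    lo <- hi <- numeric(k)
    for (j in seq_len(k) + 1) {
      ok <- use & W[, 1] > zero_tol & W[, j] > zero_tol
      if (!any(ok))
        stop(sprintf("no facility has non-zero weights for %s %d and %s 1",
                     what, j, what), call. = FALSE)
      q <- quantile(W[ok, j] / W[ok, 1], c(p_low, p_high) / 100,
                    names = FALSE, type = 7)
      lo[j - 1] <- q[1]; hi[j - 1] <- q[2]
    }
    list(lo = lo, hi = hi)
  }
  ob <- ratio_bounds(result$u, "output")
  ib <- ratio_bounds(result$v, "input")
  weight_bounds(ob$lo, ob$hi, ib$lo, ib$hi, percentile_pair = c(p_low, p_high))
}

#' Assurance-region weight bounds
#'
#' Lower and upper bounds on the ratios of DEA multiplier weights: for each
#' output `j >= 2`, `L_j <= u_j / u_1 <= U_j`, and likewise for inputs
#' relative to input 1.
#'
#' @param output_lower,output_upper length `J - 1` bounds on output weight
#'   ratios.
#' @param input_lower,input_upper length `R - 1` bounds on input weight
#'   ratios.
#' @param percentile_pair optional record of the percentiles that produced
#'   the bounds.
#' @return A `weight_bounds` object.
#' @export
weight_bounds <- function(output_lower, output_upper,
                          input_lower, input_upper,
                          percentile_pair = NULL) {
  chk <- function(lo, hi, what) {
    if (length(lo) != length(hi) || any(lo < 0) || any(lo > hi) ||
        any(!is.finite(lo)) || any(!is.finite(hi)))
      stop(sprintf("invalid %s bounds: need finite 0 <= L <= U", what),
           call. = FALSE)
  }
  chk(output_lower, output_upper, "output")
  chk(input_lower, input_upper, "input")
  structure(list(output_lower = as.numeric(output_lower),
                 output_upper = as.numeric(output_upper),
                 input_lower = as.numeric(input_lower),
                 input_upper = as.numeric(input_upper),
                 percentile_pair = percentile_pair),
            class = "weight_bounds")
}

#' Restricted DEA (assurance-region weight restrictions)
#'
#' Re-solves the CCR multiplier program with the relative weight-ratio
#' constraints of `bounds` added. Because restrictions only shrink the
#' feasible weight set, restricted scores never exceed the unrestricted ones.
#' When a super-efficiency `filter` result is supplied, its flagged outliers
#' keep their assigned score of one and the remaining facilities are scored
#' against the filtered reference set.
#'
#' @param panel a [facility_panel()].
#' @param bounds a [weight_bounds()].
#' @param filter optional `dea_result` from [super_efficiency_filter()] on
#'   the same panel.
#' @return A `dea_result`.
#' @export
rdea_scores <- function(panel, bounds, filter = NULL) {
  stopifnot(inherits(bounds, "weight_bounds"))
  if (is.null(filter)) {
    return(dea_scores(panel, bounds = bounds))
  }
  stopifnot(inherits(filter, "dea_result"))
  kept <- filter$kept
  res <- dea_scores(panel, reference = kept, evaluate = kept, bounds = bounds)
  removed <- which(filter$outlier_flags)
  res$scores[removed] <- 1
  res$outlier_flags[removed] <- TRUE
  res$super_scores <- filter$super_scores
  res$kept <- kept
  res
}
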