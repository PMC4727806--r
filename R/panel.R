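#' Facility panel
#'
#' The exchange object of the package: `n` facilities described by an
#' `n x R` input matrix and an `n x J` output matrix, optionally carrying the
#' simulation truth (true efficiency, productive capacity, capacity shares).
#'
#' @param inputs numeric `n x R` matrix of nonnegative inputs.
#' @param outputs numeric `n x J` matrix of nonnegative outputs.
#' @param theta_true optional length-`n` vector of true efficiencies in (0, 1].
#' @param capacity optional length-`n` vector of effective productive capacity
#'   (true efficiency times frontier capacity).
#' @param shares optional `n x J` matrix of capacity allocated to each output;
#'   rows must sum to `capacity`.
#' @return An object of class `facility_panel`.
#' @export
facility_panel <- function(inputs, outputs, theta_true = NULL,
                           capacity = NULL, shares = NULL) {
  inputs <- as.matrix(inputs)
  outputs <- as.matrix(outputs)
  storage.mode(inputs) <- "double"
  storage.mode(outputs) <- "double"
  n <- nrow(inputs)
  if (nrow(outputs) != n)
    stop("inputs and outputs must have the same number of rows", call. = FALSE)
  if (anyNA(inputs) || anyNA(outputs))
    stop("panel contains missing values", call. = FALSE)
  if (any(inputs < 0) || any(outputs < 0))
    stop("inputs and outputs must be nonnegative", call. = FALSE)
  if (!is.null(theta_true)) {
    theta_true <- as.numeric(theta_true)
    if (length(theta_true) != n)
      stop("theta_true must have one entry per facility", call. = FALSE)
    if (anyNA(theta_true) || any(theta_true <= 0) || any(theta_true > 1))
      stop("theta_true must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(capacity)) {
    capacity <- as.numeric(capacity)
    if (length(capacity) != n) stop("capacity length mismatch", call. = FALSE)
  }
  if (!is.null(shares)) {
    shares <- as.matrix(shares)
    if (!all(dim(shares) == dim(outputs)))
      stop("shares must match the output matrix dimensions", call. = FALSE)
    if (is.null(capacity))
      stop("shares require the capacity vector", call. = FALSE)
    if (any(abs(rowSums(shares) - capacity) > 1e-9 * pmax(1, abs(capacity))))
      stop("share rows must sum to the effective capacity", call. = FALSE)
  }
  if (is.null(colnames(inputs))) colnames(inputs) <- paste0("x", seq_len(ncol(inputs)))
  if (is.null(colnames(outputs))) colnames(outputs) <- paste0("y", seq_len(ncol(outputs)))
  structure(list(inputs = inputs, outputs = outputs, theta_true = theta_true,
                 capacity = capacity, shares = shares),
            class = "facility_panel")
}

#' @export
print.facility_panel <- function(x, ...) {
  cat(sprintf("<facility_panel: %d facilities, %d inputs, %d outputs%s>\n",
              nrow(x$inputs), ncol(x$inputs), ncol(x$outputs),
              if (!is.null(x$theta_true)) ", truth attached" else ""))
  invisible(x)
}

#' Number of facilities in a panel
#' @param panel a [facility_panel()].
#' @return integer count.
#' @export
n_facilities <- function(panel) nrow(panel$inputs)

#' Read or write a facility panel as CSV
#'
#' The delimited layout is one row per facility with columns `facility_id`,
#' `x1..xR`, `y1..yJ` and an optional `theta_true` column.
#'
#' @param path file path.
#' @return `read_panel` returns a [facility_panel()]; `write_panel` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  xc <- grep("^x[0-9]+$", names(d), value = TRUE)
  yc <- grep("^y[0-9]+$", names(d), value = TRUE)
  if (length(xc) == 0 || length(yc) == 0)
    stop("panel file must contain x1..xR and y1..yJ columns", call. = FALSE)
  facility_panel(as.matrix(d[xc]), as.matrix(d[yc]),
                 theta_true = if ("theta_true" %in% names(d)) d$theta_true)
}

#' @rdname read_panel
#' @param panel a [facility_panel()].
#' @export
write_panel <- function(panel, path) {
  d <- data.frame(facility_id = seq_len(n_facilities(panel)),
                  panel$inputs, panel$outputs, check.names = FALSE)
  if (!is.null(panel$theta_true)) d$theta_true <- panel$theta_true
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
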