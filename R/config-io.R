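#' Read a scenario from a structured config file
#'
#' Loads a YAML scenario definition. The file either names a `preset` with
#' optional overrides (`n`, `reps`, `seed`, `methods`, `rdea_percentiles`),
#' or specifies the full data-generating process under nested keys
#' `production`, `efficiency`, `inputs`, `mix`, `error`, whose fields mirror
#' the corresponding constructor arguments ([production_spec()],
#' [efficiency_spec()], [input_spec()], [output_mix_spec()],
#' [error_spec()]).
#'
#' @param path path to a YAML file.
#' @return A [scenario_config()].
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines(c("preset: baseline", "n: 50", "reps: 10"), f)
#' cfg <- read_scenario_config(f)
#' unlink(f)
#' @export
read_scenario_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files", call. = FALSE)
  # keep YAML 1.1 yes/no literals (notably the key "n") as plain strings
  y <- yaml::read_yaml(path, handlers = list("bool#no" = function(x) x,
                                             "bool#yes" = function(x) x))
  if (!is.null(y$preset)) {
    return(scenario_preset(y$preset, n = y$n, reps = y$reps, seed = y$seed,
                           methods = unlist(y$methods),
                           rdea_percentiles = unlist(y$rdea_percentiles)))
  }
  build <- function(block, ctor) do.call(ctor, lapply(block, unlist))
  inp <- y$inputs
  cm <- inp$correlation_matrix
  inp$correlation_matrix <- NULL
  inp <- lapply(inp, unlist)
  if (!is.null(cm)) {
    R <- length(inp$lower_bounds)
    inp$correlation_matrix <- matrix(unlist(cm), R, R, byrow = TRUE)
  }
  args <- list(
    name = if (is.null(y$name)) basename(path) else y$name,
    n = y$n,
    production = build(y$production, production_spec),
    efficiency = build(y$efficiency, efficiency_spec),
    inputs = do.call(input_spec, inp))
  if (!is.null(y$mix)) args$mix <- build(y$mix, output_mix_spec)
  if (!is.null(y$error)) args$error <- build(y$error, error_spec)
  for (f in c("reps", "seed", "rdea_percentiles", "cd_output_support"))
    if (!is.null(y[[f]])) args[[f]] <- unlist(y[[f]])
  if (!is.null(y$methods)) args$methods <- unlist(y$methods)
  do.call(scenario_config, args)
}
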