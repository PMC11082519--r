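#' Write an analysis configuration to a YAML file
#'
#' Serializes an [analysis_config()] (including its prior set and
#' population panel) to a human-editable key-per-field YAML file, with
#' units as documented in [prior_set()].
#'
#' @param config An `analysis_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  x <- unclass(config)
  x$priors <- unclass(x$priors)
  x$populations <- as.list(x$populations)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read an analysis configuration from a YAML file
#'
#' @param path A file written by [write_config()].
#' @return An [analysis_config()].
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  priors <- do.call(prior_set, x$priors)
  populations <- tibble::as_tibble(x$populations)
  base <- x[setdiff(names(x), c("priors", "populations", "net_args"))]
  cfg <- do.call(analysis_config,
                 c(base, list(priors = priors,
                              populations = populations),
                   x$net_args))
  cfg
}
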