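#' Pipeline configuration
#'
#' Bundles every tunable threshold of the pipeline with its default:
#' the positivity multiplier (2.5x background), the deconvoluted-zero
#' fraction, the out-neighbour consistency tolerance, the replicate-CV
#' quality limit, the weak-link floor of the cross-reactivity matrix, the
#' spot-table dialect and the simulation seed. Serializes to YAML and
#' round-trips stably.
#'
#' @param multiplier positivity multiplier (> 0, default 2.5).
#' @param dec_fraction theta_dec as a fraction of theta_pos (default 0.5).
#' @param consistency_tolerance consistency check tolerance (default 0.5).
#' @param replicate_cv_limit replicate CV flag limit (default 0.25).
#' @param weak_link_floor minimum retained off-diagonal weight
#'   (default 0.01).
#' @param dialect spot-table dialect (`"tsv"` or `"genepix_like"`).
#' @param seed integer simulation seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(multiplier = 2.5, dec_fraction = 0.5,
                            consistency_tolerance = 0.5,
                            replicate_cv_limit = 0.25,
                            weak_link_floor = 0.01,
                            dialect = c("tsv", "genepix_like"), seed = 1L) {
  dialect <- match.arg(dialect)
  thresholds <- c(multiplier = multiplier, dec_fraction = dec_fraction,
                  consistency_tolerance = consistency_tolerance,
                  replicate_cv_limit = replicate_cv_limit,
                  weak_link_floor = weak_link_floor)
  if (any(thresholds <= 0)) {
    bad <- names(thresholds)[thresholds <= 0][1]
    stop(bad, " must be > 0")
  }
  structure(list(multiplier = multiplier, dec_fraction = dec_fraction,
                 consistency_tolerance = consistency_tolerance,
                 replicate_cv_limit = replicate_cv_limit,
                 weak_link_floor = weak_link_floor, dialect = dialect,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(unclass(x))) cat(sprintf("  %s: %s\n", nm, x[[nm]]))
  invisible(x)
}
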