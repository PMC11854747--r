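#' Analysis configuration
#'
#' Bundles the tunable model parameters of the pipeline.
#'
#' @param deltas Denominator weights, a [delta_coefficients()]. Default
#'   `(1, 1, 1)`: the weights are first-class configuration (calibrate them
#'   with [calibrate_deltas()] when observed coefficient values exist).
#' @param sigma_threshold Resistance classification threshold (gf/mm2),
#'   default 2.
#' @param epsilon_translation Displacement difference (mm) below which a
#'   movement counts as pure translation, default 1e-9.
#' @param force_day Day of the cycle whose predicted chain force enters the
#'   coefficient computation. Default 1 (the initial force); set later days
#'   to use a decayed force.
#' @param decay_model Force-decay model, `"exponential"` or
#'   `"piecewise_linear"`.
#' @param length_tolerance Geometry decomposition tolerance (mm).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(deltas = delta_coefficients(),
                            sigma_threshold = 2,
                            epsilon_translation = 1e-9,
                            force_day = 1,
                            decay_model = c("exponential", "piecewise_linear"),
                            length_tolerance = 0.5) {
  decay_model <- match.arg(decay_model)
  deltas <- as_deltas(deltas)
  stopifnot(sigma_threshold > 0, epsilon_translation >= 0, force_day >= 1,
            length_tolerance >= 0)
  structure(list(deltas = deltas, sigma_threshold = sigma_threshold,
                 epsilon_translation = epsilon_translation,
                 force_day = force_day, decay_model = decay_model,
                 length_tolerance = length_tolerance),
            class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat(sprintf("<analysis_config> threshold %g gf/mm2, force day %g, %s decay, eps %g mm\n",
              x$sigma_threshold, x$force_day, x$decay_model, x$epsilon_translation))
  print(x$deltas)
  invisible(x)
}

#' Read an analysis configuration from a YAML or JSON file
#'
#' Recognized keys: `delta0`, `delta1`, `delta2`, `sigma_threshold`,
#' `epsilon_translation`, `force_day`, `decay_model`, `length_tolerance`.
#' Missing keys keep their [analysis_config()] defaults.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return An [analysis_config()].
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  pick <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]
  analysis_config(
    deltas = delta_coefficients(pick("delta0", 1), pick("delta1", 1), pick("delta2", 1)),
    sigma_threshold = pick("sigma_threshold", 2),
    epsilon_translation = pick("epsilon_translation", 1e-9),
    force_day = pick("force_day", 1),
    decay_model = pick("decay_model", "exponential"),
    length_tolerance = pick("length_tolerance", 0.5))
}
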