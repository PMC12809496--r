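#' Layered run configuration
#'
#' Builds the effective configuration for a run by layering package
#' defaults, an optional YAML configuration file, and explicit overrides
#' (e.g. command-line flags), in that precedence order. The effective
#' configuration is echoed as YAML into every output directory so runs are
#' reproducible.
#'
#' Recognized keys (dots denote nesting): `elements`, `incident_energy`,
#' `n_channels`, `seed`, `output`, `fit.iterations`, `fit.learning_rate`,
#' `fit.optimizer`, `fit.lr_decay`, `fit.init`, `fit.amp_init_range`,
#' `model.escape`, `model.escape_scatter`, `model.fit_range`,
#' `background.base_width`, `background.boxcar_width`,
#' `background.initial_reps`, `background.width_decay`,
#' `background.min_width`, `synth.amp_range`, `synth.continuum_amplitude`,
#' `synth.continuum_tau`, `synth.noise`, `synth.rows`, `synth.cols`,
#' `synth.pattern`.
#'
#' @param file optional YAML file path.
#' @param overrides named list of overrides (nested lists allowed).
#' @return a nested list of class `run_config`.
#' @export
run_config <- function(file = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(file)) {
    if (!file.exists(file)) stop("no such config file: ", file)
    cfg <- modify_deep(cfg, yaml::read_yaml(file))
  }
  cfg <- modify_deep(cfg, overrides)
  structure(cfg, class = "run_config")
}

default_run_config <- function() {
  list(
    elements = "Fe,Cu,Zn",
    incident_energy = 12,
    n_channels = 2048L,
    seed = 1L,
    output = "xrf_out",
    fit = list(iterations = 500L, learning_rate = 0.02, optimizer = "adam",
               lr_decay = "cosine", init = "heuristic",
               amp_init_range = c(2, 6)),
    model = list(escape = TRUE, escape_scatter = TRUE, fit_range = NULL),
    background = list(base_width = 2, boxcar_width = 5L, initial_reps = 16L,
                      width_decay = 1 / sqrt(2), min_width = 0.5),
    synth = list(amp_range = c(2, 6), continuum_amplitude = 200,
                 continuum_tau = 4, noise = TRUE, rows = 32L, cols = 32L,
                 pattern = "blobs")
  )
}

modify_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

# translate a run_config into the xrf_fit_config the fitting module takes
fit_config_of <- function(rc) {
  xrf_fit_config(
    n_iterations = rc$fit$iterations,
    learning_rate = rc$fit$learning_rate,
    optimizer = rc$fit$optimizer,
    lr_decay = rc$fit$lr_decay,
    init = rc$fit$init,
    seed = rc$seed,
    amp_init_range = unlist(rc$fit$amp_init_range),
    snip = snip_config(
      base_width = rc$background$base_width,
      boxcar_width = rc$background$boxcar_width,
      initial_reps = rc$background$initial_reps,
      width_decay = rc$background$width_decay,
      min_width = rc$background$min_width
    ),
    escape = rc$model$escape,
    escape_scatter = rc$model$escape_scatter,
    fit_range = if (!is.null(rc$model$fit_range)) unlist(rc$model$fit_range)
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

echo_config <- function(rc, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(rc), file.path(dir, "config.yaml"))
  invisible(rc)
}
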