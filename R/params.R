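#' Fitting-parameter metadata: defaults, bounds, scales
#'
#' One row per instrument/model parameter ("theta"): the energy-calibration
#' coefficients, peak-shape (detector-resolution, step, tail) coefficients,
#' scatter-peak parameters and the escape fraction. `lower`/`upper` are the
#' box constraints enforced during optimization and the ranges used for
#' random initialization and synthetic-truth sampling. Parameters flagged
#' `log10` (the scatter amplitudes) are optimized and sampled on a log10
#' scale, which keeps them positive by construction.
#'
#' Units: `offset` keV; `slope` keV/channel; `quad` keV/channel^2;
#' `fwhm_offset` keV (electronic-noise FWHM); `fwhm_fano` dimensionless;
#' `compton_angle` degrees; amplitudes counts; everything else
#' dimensionless.
#'
#' @return a tibble with columns `name`, `default`, `lower`, `upper`,
#'   `optimizable`, `log10`.
#' @export
param_table <- function() {
  tibble::tribble(
    ~name,                  ~default, ~lower,  ~upper, ~optimizable, ~log10,
    "offset",                 0,      -0.1,     0.1,    TRUE,  FALSE,
    "slope",                  0.010,   0.008,   0.012,  TRUE,  FALSE,
    "quad",                   0,      -2e-8,    2e-8,   TRUE,  FALSE,
    "fwhm_offset",            0.12,    0.06,    0.20,   TRUE,  FALSE,
    "fwhm_fano",              0.114,   0.05,    0.25,   TRUE,  FALSE,
    "step_height",            0.02,    0,       0.05,   TRUE,  FALSE,
    "tail_fraction",          0.05,    0,       0.15,   TRUE,  FALSE,
    "tail_slope",             1.0,     0.3,     2.5,    TRUE,  FALSE,
    "elastic_amplitude",      1e4,     2,       6,      TRUE,  TRUE,
    "compton_amplitude",      1e4,     2,       6,      TRUE,  TRUE,
    "compton_angle",          120,     90,      160,    TRUE,  FALSE,
    "compton_fwhm_corr",      1.4,     1.0,     2.5,    TRUE,  FALSE,
    "compton_step",           0.00,    0,       0.05,   TRUE,  FALSE,
    "compton_tail_fraction",  0.05,    0,       0.3,    TRUE,  FALSE,
    "compton_tail_slope",     1.5,     0.3,     3.0,    TRUE,  FALSE,
    "escape_fraction",        0.01,    0,       0.05,   TRUE,  FALSE
  )
}

#' Construct a fitting-parameter set
#'
#' Collects the spectrum-model parameters ("theta") into a validated named
#' list. Any parameter not supplied takes its default from [param_table()].
#' `incident_energy` (keV) is part of the set but is never optimized.
#'
#' @param ... named parameter values overriding the defaults, e.g.
#'   `slope = 0.0102`.
#' @param incident_energy beam energy in keV (default 12).
#' @return an object of class `xrf_params` (a named list).
#' @export
#' @examples
#' th <- xrf_params(fwhm_offset = 0.15)
#' th$slope
xrf_params <- function(..., incident_energy = 12) {
  tab <- param_table()
  p <- as.list(stats::setNames(tab$default, tab$name))
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), tab$name)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  p$incident_energy <- incident_energy
  validate_params(p)
  structure(p, class = "xrf_params")
}

validate_params <- function(p) {
  stopifnot(
    p$slope > 0,
    p$fwhm_offset > 0, p$fwhm_fano >= 0,
    p$step_height >= 0, p$tail_fraction >= 0, p$tail_slope > 0,
    p$elastic_amplitude >= 0, p$compton_amplitude >= 0,
    p$compton_angle > 0, p$compton_angle <= 180,
    p$compton_fwhm_corr > 0,
    p$escape_fraction >= 0, p$escape_fraction <= 0.05,
    p$incident_energy > 0
  )
  if (abs(p$quad) * 2048^2 > p$slope * 2048) {
    warning("quadratic calibration term dominates the linear term")
  }
  invisible(p)
}

#' @export
print.xrf_params <- function(x, ...) {
  cat("<xrf_params>\n")
  nm <- names(x)
  for (n in nm) cat(sprintf("  %-22s %g\n", n, x[[n]]))
  invisible(x)
}

# ---- internal: unit-interval scaling of theta for the optimizer ------------
# each optimizable scalar is mapped to z in [0,1] over its bound interval
# (log10 interval for log-scale parameters), so Adam steps are comparable
# across parameters with very different magnitudes.

theta_to_z <- function(params, tab = param_table()) {
  z <- numeric(nrow(tab))
  names(z) <- tab$name
  for (i in seq_len(nrow(tab))) {
    v <- params[[tab$name[i]]]
    if (tab$log10[i]) v <- log10(max(v, 1e-12))
    z[i] <- (v - tab$lower[i]) / (tab$upper[i] - tab$lower[i])
  }
  pmin(pmax(z, 0), 1)
}

# z entries may be numerics or ad scalars; returns a named list usable as
# theta inside the computation graph
z_to_theta <- function(z, tab, incident_energy) {
  th <- vector("list", nrow(tab) + 1L)
  names(th) <- c(tab$name, "incident_energy")
  for (i in seq_len(nrow(tab))) {
    v <- tab$lower[i] + z[[i]] * (tab$upper[i] - tab$lower[i])
    if (tab$log10[i]) v <- 10^v
    th[[i]] <- v
  }
  th$incident_energy <- incident_energy
  th
}
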