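#' @export
print.xrf_fit <- function(x, ...) {
  cat("<xrf_fit> ", nrow(x$spectrum), " channels, ",
      nrow(x$elements), " element specs\n", sep = "")
  cat(sprintf("  R^2 = %.5f, MSE = %.4g (best iteration %d/%d)\n",
              x$r_squared, x$loss, x$best_iteration,
              x$config$n_iterations))
  amps <- sort(x$amplitudes, decreasing = TRUE)
  cat("  amplitudes: ",
      paste0(names(amps), " = ", signif(amps, 4), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Tidy a spectrum fit into a term/estimate table
#'
#' One row per fitted quantity: element amplitudes (counts) and instrument
#' parameters, with the unit-interval position inside the bound interval
#' for bounded parameters.
#'
#' @param x an `xrf_fit`.
#' @param ... unused.
#' @return a tibble with `term`, `type` (`"amplitude"` or `"parameter"`),
#'   and `estimate`.
#' @export
tidy.xrf_fit <- function(x, ...) {
  tab <- param_table()
  dplyr::bind_rows(
    tibble::tibble(term = names(x$amplitudes), type = "amplitude",
                   estimate = unname(x$amplitudes)),
    tibble::tibble(term = tab$name, type = "parameter",
                   estimate = vapply(tab$name, function(n) x$params[[n]],
                                     numeric(1)))
  )
}

#' One-row summary of a spectrum fit
#'
#' @param x an `xrf_fit`.
#' @param ... unused.
#' @return a tibble with `r_squared`, `mse`, `n_iterations`,
#'   `best_iteration`, `n_channels`, `n_elements`.
#' @export
glance.xrf_fit <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared,
    mse = x$loss,
    n_iterations = x$config$n_iterations,
    best_iteration = x$best_iteration,
    n_channels = nrow(x$spectrum),
    n_elements = nrow(x$elements)
  )
}

#' Plot a spectrum fit
#'
#' Observed counts, fitted model and background on a log10(counts + 1)
#' scale versus energy, the conventional display for energy-dispersive
#' spectra.
#'
#' @param object an `xrf_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.xrf_fit <- function(object, ...) {
  d <- object$spectrum[object$mask, ]
  long <- tidyr::pivot_longer(
    d[, c("energy", "observed", "model", "background")],
    -"energy", names_to = "curve", values_to = "counts"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$energy, y = log10(.data$counts + 1),
    colour = .data$curve, linewidth = .data$curve
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(observed = "grey40", model = "#d1447e",
                 background = "#4477aa")
    ) +
    ggplot2::scale_linewidth_manual(
      values = c(observed = 0.3, model = 0.7, background = 0.5),
      guide = "none"
    ) +
    ggplot2::labs(x = "energy (keV)", y = "log10(counts + 1)",
                  colour = NULL,
                  subtitle = sprintf("R² = %.4f", object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot elemental maps
#'
#' Per-element amplitude rasters of a per-pixel linear mapping, one facet
#' per element specification.
#'
#' @param object an `xrf_map` from [map_amplitudes()].
#' @param terms which terms to show (default: the element specs, excluding
#'   the scatter terms).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.xrf_map <- function(object, terms = NULL, ...) {
  all_terms <- attr(object, "terms")
  terms <- terms %||% setdiff(all_terms, c("elastic", "compton"))
  long <- tidyr::pivot_longer(object, dplyr::all_of(terms),
                              names_to = "term", values_to = "amplitude")
  ggplot2::ggplot(long, ggplot2::aes(.data$col, .data$row,
                                     fill = .data$amplitude)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "counts") +
    ggplot2::theme_minimal()
}

#' @export
print.xrf_scan <- function(x, ...) {
  cat("<xrf_scan> ", x$rows, " x ", x$cols, " pixels, ", x$n_channels,
      " channels, total ", format(sum(x$counts), big.mark = ","),
      " counts\n", sep = "")
  invisible(x)
}

#' @export
print.xrf_pipeline <- function(x, ...) {
  cat("<xrf_pipeline>\n")
  cat(sprintf("  first-pass fit: R^2 = %.4f\n", x$first_pass$r_squared))
  cat("  map terms: ", paste(attr(x$map, "terms"), collapse = ", "), "\n",
      sep = "")
  cat("  ROIs refined: ", length(x$roi_fits), " (R^2 = ",
      paste(sprintf("%.4f", vapply(x$roi_fits, function(f) f$r_squared,
                                   numeric(1))), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' @export
print.xrf_truth <- function(x, ...) {
  cat("<xrf_truth> seed ", x$seed, ", elements ",
      paste(x$elements$spec, collapse = ","),
      if (isTRUE(x$noise)) ", Poisson noise" else ", noise-free", "\n",
      sep = "")
  invisible(x)
}
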