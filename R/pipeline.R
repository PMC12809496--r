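#' Integrate a raster scan into a single spectrum
#'
#' Channel-wise sum of the per-pixel spectra, over the whole scan or a
#' rectangular region of interest.
#'
#' @param scan an `xrf_scan` (see [synth_scan()] or [read_scan()]).
#' @param roi optional [roi_box()].
#' @return a tibble (`channel`, `energy` when calibration is known,
#'   `counts`).
#' @export
integrate_scan <- function(scan, roi = NULL) {
  stopifnot(inherits(scan, "xrf_scan"))
  cube <- scan$counts
  if (!is.null(roi)) {
    check_roi(roi, scan)
    cube <- cube[roi$row0:(roi$row0 + roi$height - 1L),
                 roi$col0:(roi$col0 + roi$width - 1L), , drop = FALSE]
  }
  counts <- apply(cube, 3, sum)
  out <- tibble::tibble(channel = seq_len(scan$n_channels) - 1L,
                        counts = as.numeric(counts))
  if (!is.null(scan$truth)) {
    out$energy <- energy_axis(scan$truth$params, scan$n_channels)
    out <- out[, c("channel", "energy", "counts")]
  }
  class(out) <- c("xrf_spectrum", class(out))
  out
}

#' Rectangular region of interest
#'
#' @param row0,col0 top-left pixel (1-based).
#' @param height,width box size in pixels (default 25 x 25).
#' @return a list of class `roi_box`.
#' @export
roi_box <- function(row0, col0, height = 25L, width = 25L) {
  stopifnot(row0 >= 1, col0 >= 1, height >= 1, width >= 1)
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi_box")
}

check_roi <- function(roi, scan) {
  if (roi$row0 + roi$height - 1L > scan$rows ||
      roi$col0 + roi$width - 1L > scan$cols) {
    stop("roi extends beyond scan bounds")
  }
  invisible(roi)
}

#' Per-pixel linear elemental mapping
#'
#' With instrument parameters frozen (typically from an integrated-spectrum
#' fit), solves every pixel's spectrum by non-negative least squares
#' against the unit-amplitude component design, which is built once and
#' reused. Per-pixel backgrounds come from the plain SNIP estimator.
#'
#' @param scan an `xrf_scan`.
#' @param elements element tibble or specification string.
#' @param params frozen [xrf_params()].
#' @param config an [xrf_fit_config()] (model options).
#' @param solver passed to [linear_amplitudes()].
#' @return a tibble of class `xrf_map`: `row`, `col`, one column per term
#'   (element specs, elastic, compton) holding fitted amplitudes.
#' @export
map_amplitudes <- function(scan, elements, params,
                           config = xrf_fit_config(), solver = "nnls") {
  stopifnot(inherits(scan, "xrf_scan"))
  if (is.character(elements)) elements <- parse_element_list(elements)
  des <- amplitude_design(elements, params, scan$n_channels, config)
  rows <- scan$rows; cols <- scan$cols
  npix <- rows * cols
  res <- matrix(0, npix, length(des$terms))
  colnames(res) <- des$terms
  ix <- 0L
  for (cc in seq_len(cols)) {
    for (r in seq_len(rows)) {
      ix <- ix + 1L
      y <- scan$counts[r, cc, ]
      a <- linear_amplitudes(y, elements, params, solver = solver,
                             config = config, design = des)
      res[ix, ] <- a$amplitude
    }
  }
  grid <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  out <- tibble::as_tibble(cbind(grid, res))
  class(out) <- c("xrf_map", class(out))
  attr(out, "terms") <- des$terms
  out
}

#' Refine elemental intensities in a region of interest
#'
#' Integrates the ROI, then reruns the nonlinear AD fit starting from the
#' supplied parameters with bound intervals tightened to +/- 10% around
#' them (intersected with the global bounds), per-element amplitudes
#' re-initialized heuristically from the ROI spectrum unless provided.
#'
#' @param scan an `xrf_scan`.
#' @param roi an [roi_box()] (`NULL` fits the whole scan).
#' @param elements element tibble or specification string.
#' @param params starting parameters (typically from the integrated fit).
#' @param config an [xrf_fit_config()].
#' @param tighten half-width of the tightened bounds as a fraction of the
#'   parameter magnitude (default 0.1).
#' @return an `xrf_fit` for the ROI-integrated spectrum.
#' @export
refine_roi <- function(scan, roi, elements, params,
                       config = xrf_fit_config(), tighten = 0.1) {
  sp <- integrate_scan(scan, roi)
  # tighten against the data-capped global box (the ROI's scatter
  # amplitudes live on the ROI count scale)
  config$bounds <- tighten_bounds(params,
                                  effective_bounds(config, sp$counts),
                                  tighten)
  config$init <- "heuristic"
  fit_spectrum(sp$counts, elements, config, params = params,
               incident_energy = params$incident_energy)
}

# +/- tighten*|v| around v (with a floor of 2% of the global range for
# parameters near zero), clipped to the global bounds; log-scale parameters
# tightened on the log10 scale
tighten_bounds <- function(params, tab, tighten = 0.1) {
  lo <- up <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    v <- params[[tab$name[i]]]
    if (tab$log10[i]) v <- log10(max(v, 1e-12))
    half <- max(tighten * abs(v), 0.02 * (tab$upper[i] - tab$lower[i]))
    lo[i] <- max(tab$lower[i], v - half)
    up[i] <- min(tab$upper[i], v + half)
    if (lo[i] > up[i]) { # starting value outside the global box
      lo[i] <- min(lo[i], tab$upper[i])
      up[i] <- max(up[i], tab$lower[i])
    }
  }
  tibble::tibble(name = tab$name, lower = lo, upper = up)
}

#' Automatic ROI selection by tile intensity
#'
#' Tiles the scan with boxes of the given size, ranks tiles by total
#' counts, and returns the top `k` non-overlapping boxes.
#'
#' @param scan an `xrf_scan`.
#' @param k number of boxes.
#' @param size box edge length in pixels (clipped to the scan size).
#' @return list of [roi_box()].
#' @export
select_rois <- function(scan, k = 3L, size = 25L) {
  size <- min(size, scan$rows, scan$cols)
  r0 <- seq(1L, scan$rows - size + 1L, by = size)
  c0 <- seq(1L, scan$cols - size + 1L, by = size)
  per_pix <- apply(scan$counts, c(1, 2), sum)
  tiles <- expand.grid(r = r0, c = c0)
  tiles$total <- mapply(function(r, c) {
    sum(per_pix[r:(r + size - 1L), c:(c + size - 1L)])
  }, tiles$r, tiles$c)
  tiles <- tiles[order(-tiles$total), , drop = FALSE]
  k <- min(k, nrow(tiles))
  lapply(seq_len(k), function(i) {
    roi_box(tiles$r[i], tiles$c[i], size, size)
  })
}

#' Automated first-pass / mapping / refinement pipeline
#'
#' The no-intervention workflow: (1) fit the integrated spectrum (random
#' initialization by default), (2) per-pixel linear amplitude mapping at
#' the fitted parameters, (3) ROI selection (top-intensity tiles, or boxes
#' supplied by the caller), (4) nonlinear refinement of each ROI starting
#' from the first-pass parameters.
#'
#' @param scan an `xrf_scan`.
#' @param elements element tibble or specification string.
#' @param config an [xrf_fit_config()]; `init = "random"` reproduces a
#'   fully blind first pass.
#' @param rois optional list of [roi_box()] to bypass automatic selection.
#' @param n_rois number of automatic ROIs.
#' @param roi_size automatic ROI edge length.
#' @return an object of class `xrf_pipeline`: list with `first_pass`
#'   (`xrf_fit`), `map` (`xrf_map`), `rois`, and `roi_fits` (list of
#'   `xrf_fit`).
#' @export
run_auto_pipeline <- function(scan, elements,
                              config = xrf_fit_config(init = "random"),
                              rois = NULL, n_rois = 3L, roi_size = 25L) {
  stopifnot(inherits(scan, "xrf_scan"))
  if (is.character(elements)) elements <- parse_element_list(elements)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  integrated <- stage("integrate", integrate_scan(scan))
  first_pass <- stage("first_pass",
                      fit_spectrum(integrated$counts, elements, config))
  amap <- stage("map",
                map_amplitudes(scan, elements, first_pass$params, config))
  boxes <- rois %||% stage("roi_select", select_rois(scan, n_rois, roi_size))
  refine_cfg <- config
  refine_cfg$init <- "heuristic"
  roi_fits <- lapply(seq_along(boxes), function(i) {
    stage(paste0("refine_roi_", i),
          refine_roi(scan, boxes[[i]], elements, first_pass$params,
                     refine_cfg))
  })
  structure(list(first_pass = first_pass, map = amap, rois = boxes,
                 roi_fits = roi_fits, elements = elements,
                 config = config), class = "xrf_pipeline")
}
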