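#' Sample a ground-truth parameter set for synthetic data
#'
#' Draws instrument parameters uniformly within their bound intervals (the
#' same ranges used for random fit initialization) and element amplitudes
#' log-uniformly over `amp_range` (log10 counts). The exponential-decay
#' continuum stands in for the smooth scatter/bremsstrahlung baseline of
#' real spectra; its amplitude and decay constant are recorded in the truth
#' object so generated data always carry their own manifest.
#'
#' @param elements element tibble or specification string.
#' @param seed integer seed.
#' @param amp_range log10 amplitude range (default `c(2, 6)` counts).
#' @param continuum list with `amplitude` (counts/channel at E = 0) and
#'   `tau` (keV decay constant).
#' @param noise logical: apply Poisson counting noise when the spectrum is
#'   realized.
#' @param incident_energy beam energy (keV).
#' @return an object of class `xrf_truth`.
#' @export
sample_truth <- function(elements, seed = 1L, amp_range = c(2, 6),
                         continuum = list(amplitude = 200, tau = 4),
                         noise = TRUE, incident_energy = 12) {
  if (is.character(elements)) elements <- parse_element_list(elements)
  set.seed(seed)
  tab <- param_table()
  th <- list()
  for (i in seq_len(nrow(tab))) {
    v <- if (tab$optimizable[i]) runif(1, tab$lower[i], tab$upper[i]) else tab$default[i]
    if (tab$log10[i]) v <- 10^v
    th[[tab$name[i]]] <- v
  }
  params <- do.call(xrf_params, c(th, list(incident_energy = incident_energy)))
  la <- runif(nrow(elements), amp_range[1], amp_range[2])
  names(la) <- elements$spec
  structure(list(
    params = params, log_amplitudes = la, continuum = continuum,
    noise = noise, seed = as.integer(seed), elements = elements
  ), class = "xrf_truth")
}

# continuum counts per channel implied by a truth object
truth_continuum <- function(truth, n_channels) {
  E <- energy_axis(truth$params, n_channels)
  b <- truth$continuum$amplitude * exp(-pmax(E, 0) / truth$continuum$tau)
  b[E <= 0] <- 0
  b
}

#' Realize a synthetic spectrum from a ground truth
#'
#' Runs the forward model at the truth parameters, adds the exponential
#' continuum, optionally rescales so the noise-free total count equals
#' `target_total`, and applies Poisson noise if the truth requests it.
#'
#' @param truth an [sample_truth()] object.
#' @param n_channels number of channels (default 2048).
#' @param target_total optional total-count target; amplitudes and continuum
#'   are scaled jointly (the returned truth attribute reflects the scaling).
#' @param seed seed for the Poisson draw (defaults to the truth seed).
#' @return a tibble (`channel`, `energy`, `counts`) of class
#'   `xrf_spectrum`, with the (possibly rescaled) truth in
#'   `attr(, "truth")`; retrieve it with [ground_truth()].
#' @export
synth_spectrum <- function(truth, n_channels = 2048, target_total = NULL,
                           seed = truth$seed) {
  stopifnot(inherits(truth, "xrf_truth"))
  clean <- synth_clean_total(truth, n_channels)
  if (!is.null(target_total)) {
    s <- target_total / sum(clean)
    truth$log_amplitudes <- truth$log_amplitudes + log10(s)
    truth$continuum$amplitude <- truth$continuum$amplitude * s
    truth$params$elastic_amplitude <- truth$params$elastic_amplitude * s
    truth$params$compton_amplitude <- truth$params$compton_amplitude * s
    clean <- clean * s
  }
  counts <- clean
  if (isTRUE(truth$noise)) {
    set.seed(seed)
    counts <- rpois(n_channels, clean)
  }
  out <- tibble::tibble(
    channel = seq_len(n_channels) - 1L,
    energy = energy_axis(truth$params, n_channels),
    counts = as.numeric(counts)
  )
  class(out) <- c("xrf_spectrum", class(out))
  attr(out, "truth") <- truth
  out
}

# noise-free total spectrum (model + continuum) at the truth
synth_clean_total <- function(truth, n_channels) {
  amps <- 10^truth$log_amplitudes
  sp <- model_spectrum(truth$elements, amps, truth$params,
                       n_channels = n_channels, background = "none")
  sp$total + truth_continuum(truth, n_channels)
}

#' @rdname synth_spectrum
#' @param x an object carrying a truth manifest.
#' @export
ground_truth <- function(x) attr(x, "truth")

#' Synthetic raster scan with spatial amplitude patterns
#'
#' Generates a rows x cols scan whose per-pixel spectra share the truth's
#' instrument parameters while each element's amplitude is modulated by a
#' spatial field: Gaussian blobs (seeded random centers), a linear
#' gradient, or a constant. Fields average to 1, so the truth amplitudes
#' are per-pixel means; scatter amplitudes and the continuum are uniform
#' across pixels. Per-pixel spectra get independent Poisson noise when the
#' truth requests noise.
#'
#' @param truth an [sample_truth()] object (its amplitudes are per-pixel
#'   scale).
#' @param rows,cols scan dimensions (default 32 x 32).
#' @param n_channels spectrum length.
#' @param pattern `"blobs"`, `"gradient"` or `"constant"`.
#' @param seed seed for field placement and noise.
#' @return an object of class `xrf_scan`: list with `counts` (rows x cols x
#'   channels array), `truth`, `fields` (rows x cols x spec array of
#'   amplitude multipliers), and dimensions.
#' @export
synth_scan <- function(truth, rows = 32L, cols = 32L, n_channels = 2048,
                       pattern = c("blobs", "gradient", "constant"),
                       seed = truth$seed) {
  stopifnot(inherits(truth, "xrf_truth"), rows >= 1, cols >= 1)
  pattern <- match.arg(pattern)
  specs <- truth$elements$spec
  set.seed(seed)
  fields <- array(1, dim = c(rows, cols, length(specs)),
                  dimnames = list(NULL, NULL, specs))
  if (pattern == "blobs") {
    rg <- expand.grid(r = seq_len(rows), c = seq_len(cols))
    for (k in seq_along(specs)) {
      cr <- runif(1, 1, rows)
      cc <- runif(1, 1, cols)
      wd <- runif(1, 0.12, 0.3) * max(rows, cols)
      f <- 0.05 + exp(-((rg$r - cr)^2 + (rg$c - cc)^2) / (2 * wd^2))
      f <- f / mean(f)
      fields[, , k] <- matrix(f, rows, cols)
    }
  } else if (pattern == "gradient") {
    for (k in seq_along(specs)) {
      f <- outer(seq_len(rows) / rows, rep(1, cols))
      fields[, , k] <- f / mean(f)
    }
  }

  # unit component design at the truth parameters, then one matrix product
  cfg <- xrf_fit_config(background = "none")
  des <- amplitude_design(truth$elements, truth$params, n_channels, cfg)
  npix <- rows * cols
  amps <- 10^truth$log_amplitudes
  A <- matrix(0, length(des$terms), npix)
  rownames(A) <- des$terms
  for (k in seq_along(specs)) {
    A[specs[k], ] <- amps[specs[k]] * as.numeric(fields[, , k])
  }
  A["elastic", ] <- truth$params$elastic_amplitude
  A["compton", ] <- truth$params$compton_amplitude
  clean <- des$matrix %*% A
  clean <- clean + truth_continuum(truth, n_channels)
  counts <- if (isTRUE(truth$noise)) {
    matrix(rpois(length(clean), pmax(clean, 0)), nrow(clean), ncol(clean))
  } else {
    clean
  }
  cube <- array(0, dim = c(rows, cols, n_channels))
  for (p in seq_len(npix)) {
    r <- ((p - 1L) %% rows) + 1L
    cc <- ((p - 1L) %/% rows) + 1L
    cube[r, cc, ] <- counts[, p]
  }
  structure(list(
    counts = cube, truth = truth, fields = fields,
    rows = rows, cols = cols, n_channels = n_channels
  ), class = "xrf_scan")
}
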