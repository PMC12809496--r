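#' Energy axis from calibration coefficients
#'
#' Maps channel index `i` (0-based) to energy
#' `E_i = offset + slope * i + quad * i^2` (keV).
#'
#' @param params an [xrf_params()] set (uses `offset`, `slope`, `quad`), or a
#'   list with those fields.
#' @param n number of channels.
#' @return numeric vector of channel energies (keV).
#' @export
#' @examples
#' energy_axis(xrf_params(), 4)
energy_axis <- function(params, n) {
  stopifnot(n >= 1)
  ch <- seq_len(n) - 1
  params$offset + params$slope * ch + params$quad * ch^2
}

#' Detector resolution: Gaussian width at a given energy
#'
#' `sigma(E) = sqrt((fwhm_offset/2.3548)^2 + 0.00358 * fwhm_fano * E)`,
#' the standard Si-detector resolution model: a constant electronic-noise
#' term plus a Fano-statistics term proportional to energy, with the silicon
#' electron-hole pair-creation energy 0.00358 keV folded in (`fwhm_fano`
#' absorbs the true Fano factor).
#'
#' @param energy energy (keV), vector allowed.
#' @param params an [xrf_params()] set (uses `fwhm_offset`, `fwhm_fano`).
#' @return peak sigma in keV.
#' @export
#' @examples
#' sigma_at(6.4, xrf_params(fwhm_offset = 0.12, fwhm_fano = 0.114))
sigma_at <- function(energy, params) {
  e <- ad_clamp(energy, 0, Inf)
  sqrt((params$fwhm_offset / 2.3548)^2 + 0.00358 * params$fwhm_fano * e)
}

#' Compton-scattered energy
#'
#' Energy of an incident photon of energy `e0` after inelastic scattering
#' through `angle`: `e0 / (1 + (e0/511) * (1 - cos(angle)))` with the
#' electron rest energy 511 keV.
#'
#' @param e0 incident energy (keV).
#' @param angle scattering angle in degrees, in (0, 180].
#' @return scattered energy (keV).
#' @export
#' @examples
#' compton_energy(12, 90)
compton_energy <- function(e0, angle) {
  e0 / (1 + (e0 / 511) * (1 - cos(angle * (pi / 180))))
}

.SQRT2PI <- 2.5066282746310002
.INVSQRT2 <- 0.7071067811865475

# single Gaussian on an axis; area-normalized (sum of counts ~ area when the
# peak is interior); mu/sigma/area may be ad scalars, axis ad or numeric
gaussian_line <- function(E, mu, sigma, area, slope) {
  z <- ad_clamp((E - mu) / sigma, -30, 30)
  (area * slope / (sigma * .SQRT2PI)) * exp(-0.5 * (z * z))
}

# Gaussian + optional step + optional Hypermet tail for one peak (vector path)
peak_single <- function(E, mu, sigma, area, slope,
                        step_height = 0, tail_fraction = 0, tail_slope = 1,
                        with_step = FALSE, with_tail = FALSE,
                        with_gauss = TRUE) {
  z <- ad_clamp((E - mu) / sigma, -30, 30)
  ez <- exp(-0.5 * (z * z))
  out <- if (with_gauss) (area * slope / (sigma * .SQRT2PI)) * ez else 0
  if (with_step) {
    out <- out + (step_height * area * slope / (2 * mu)) * erfc(z * .INVSQRT2)
  }
  if (with_tail) {
    a <- 1 / (1.4142135623730951 * tail_slope)
    t <- z * .INVSQRT2 + a
    out <- out + (tail_fraction * area * slope / (2 * tail_slope * sigma)) *
      (ez * erfcx(t))
  }
  out
}

# a group of peaks with constant centers mu (numeric, length L); sigma and
# area are length-L, slope/shape parameters scalar; any of them ad or
# numeric. Evaluated by the fused compiled kernel with analytic adjoints.
peak_group <- function(E, mu, sigma, area, slope,
                       step_height = 0, tail_fraction = 0, tail_slope = 1,
                       with_step = FALSE, with_tail = FALSE,
                       with_gauss = TRUE) {
  n <- length(ad_value(E))
  if (length(mu) == 0L) return(numeric(n))
  ins <- list(E, sigma, area, slope, step_height, tail_fraction, tail_slope)
  isad <- vapply(ins, is_ad, logical(1))
  vE <- ad_value(E); vsig <- ad_value(sigma); var_ <- ad_value(area)
  vsl <- ad_value(slope); vsh <- ad_value(step_height)
  vtf <- ad_value(tail_fraction); vts <- ad_value(tail_slope)
  out <- cpp_hypermet_f(vE, mu, vsig, rep_len(var_, length(mu)), vsl, vsh,
                        vtf, vts, with_step, with_tail, with_gauss)
  if (!any(isad)) return(out)
  tape <- ins[[which(isad)[1]]]$tape
  p <- vapply(ins, function(x) if (is_ad(x)) x$id else 0L, integer(1))
  ad_node(tape, out, p, function(g) {
    b <- cpp_hypermet_b(g, vE, mu, vsig, rep_len(var_, length(mu)), vsl,
                        vsh, vtf, vts, with_step, with_tail, with_gauss)
    list(
      if (isad[1]) b$gE,
      if (isad[2]) b$gsigma,
      if (isad[3]) .red(b$garea, length(var_)),
      if (isad[4]) b$gslope,
      if (isad[5]) b$gsh,
      if (isad[6]) b$gtf,
      if (isad[7]) b$gts
    )
  })
}

#' Single peak-shape contributions on an energy axis
#'
#' Building blocks of the line-shape model, exposed for inspection and
#' testing. `gaussian_peak()` is an area-normalized Gaussian (channel counts
#' sum to `area` for interior peaks). `step_contrib()` is the flat
#' low-energy shelf `step_height * area * slope / (2 mu) * erfc(z/sqrt(2))`
#' produced by incomplete charge collection. `tail_contrib()` is the
#' Hypermet exponential low-energy tail, an exponentially modified Gaussian
#' scaled so its integrated counts equal `tail_fraction * area`.
#'
#' @param axis numeric vector of channel energies (keV).
#' @param mu peak center (keV).
#' @param sigma peak width (keV).
#' @param area integrated peak counts.
#' @param slope energy width of one channel (keV), used to convert a density
#'   to counts per channel.
#' @param step_height,tail_fraction,tail_slope dimensionless shape
#'   parameters (see [param_table()]).
#' @return numeric vector of counts per channel.
#' @export
gaussian_peak <- function(axis, mu, sigma, area, slope) {
  stopifnot(sigma > 0)
  gaussian_line(axis, mu, sigma, area, slope)
}

#' @rdname gaussian_peak
#' @export
step_contrib <- function(axis, mu, sigma, area, slope, step_height) {
  stopifnot(step_height >= 0)
  z <- ad_clamp((axis - mu) / sigma, -30, 30)
  (step_height * area * slope / (2 * mu)) * erfc(z * .INVSQRT2)
}

#' @rdname gaussian_peak
#' @export
tail_contrib <- function(axis, mu, sigma, area, slope, tail_fraction,
                         tail_slope) {
  stopifnot(tail_fraction >= 0, tail_slope > 0)
  peak_single(axis, mu, sigma, area, slope,
              tail_fraction = tail_fraction, tail_slope = tail_slope,
              with_tail = TRUE) -
    gaussian_line(axis, mu, sigma, area, slope)
}

# ---- model context ---------------------------------------------------------

#' Assemble the static context of the spectrum model
#'
#' Resolves the element list against the bundled line table at the given
#' incident energy, precomputes escape-peak centers, and records the model
#' options. The context is built once and reused across optimizer
#' iterations.
#'
#' @param elements a tibble from [parse_element_list()] (or a specification
#'   string).
#' @param n_channels number of spectrum channels.
#' @param incident_energy beam energy (keV).
#' @param escape logical: model detector escape peaks.
#' @param escape_scatter logical: also derive escape peaks from the scatter
#'   peaks (not just element lines).
#' @param material detector material for [escape_constants()].
#' @param background `"snip"`, `"none"`, or a fixed numeric background
#'   vector.
#' @param refine_background logical (default `TRUE`): run SNIP on the
#'   observed counts minus the model's current step and tail components
#'   rather than on the raw counts. The flat step shelves and exponential
#'   tails of strong peaks look like continuum to a clipping estimator;
#'   subtracting them first prevents the background and the peak model from
#'   counting those photons twice.
#' @param snip a [snip_config()].
#' @param fit_range `c(E_min, E_max)` in keV; channels outside are excluded
#'   from background estimation and the fit loss. Default
#'   `c(0.25, incident_energy + 1)`.
#' @return an internal context object (class `xrf_ctx`).
#' @export
xrf_model_context <- function(elements, n_channels = 2048,
                              incident_energy = 12,
                              escape = TRUE, escape_scatter = TRUE,
                              material = "Si",
                              background = "snip",
                              refine_background = TRUE,
                              snip = snip_config(),
                              fit_range = NULL) {
  if (is.character(elements)) elements <- parse_element_list(elements)
  mat <- escape_constants(material)
  specs <- vector("list", nrow(elements))
  for (i in seq_len(nrow(elements))) {
    row <- elements[i, ]
    if (row$is_pileup) {
      l1 <- lines_for(row$element, "K", incident_energy)
      l2 <- lines_for(row$partner, "K", incident_energy)
      center <- if (nrow(l1) && nrow(l2)) {
        l1$energy_kev[which.max(l1$ratio)] + l2$energy_kev[which.max(l2$ratio)]
      } else {
        NA_real_
      }
      specs[[i]] <- list(spec = row$spec, is_pileup = TRUE, center = center)
    } else {
      ln <- lines_for(row$element, row$family, incident_energy)
      esc_keep <- ln$energy_kev > mat$edge_energy &
        (ln$energy_kev - mat$escape_line_energy) > 0
      specs[[i]] <- list(
        spec = row$spec, is_pileup = FALSE,
        mu = ln$energy_kev, br = ln$ratio,
        esc_mu = ln$energy_kev[esc_keep] - mat$escape_line_energy,
        esc_br = ln$ratio[esc_keep]
      )
    }
  }
  names(specs) <- elements$spec
  structure(list(
    elements = elements, specs = specs, n_channels = n_channels,
    incident_energy = incident_energy, escape = escape,
    escape_scatter = escape_scatter, material = mat,
    background = background, refine_background = refine_background,
    snip = snip,
    fit_range = fit_range %||% c(0.25, incident_energy + 1)
  ), class = "xrf_ctx")
}

# ---- full forward evaluation -----------------------------------------------
# th: named list of model parameters (ad scalars or numerics)
# log_amps: named list/vector of log10 amplitudes per element spec
# observed: numeric counts (needed when background == "snip")
# returns list of components; each is a length-n vector (ad or numeric)
eval_model <- function(ctx, th, log_amps, observed = NULL) {
  n <- ctx$n_channels
  ch <- seq_len(n) - 1
  E <- th$offset + th$slope * ch + th$quad * (ch * ch)
  e0 <- ctx$incident_energy

  refine <- isTRUE(ctx$refine_background) &&
    !identical(ctx$background, "none") && !is.numeric(ctx$background)
  artifacts <- numeric(n)

  element <- vector("list", length(ctx$specs))
  names(element) <- names(ctx$specs)
  esc_parts <- list()
  for (s in ctx$specs) {
    A <- 10^log_amps[[s$spec]]
    if (s$is_pileup) {
      element[[s$spec]] <- if (is.na(s$center)) numeric(n) else {
        gaussian_line(E, s$center, sigma_at(s$center, th), A, th$slope)
      }
      next
    }
    if (length(s$mu) == 0L) {
      element[[s$spec]] <- numeric(n)
      next
    }
    sig <- sigma_at(s$mu, th)
    area <- A * s$br
    element[[s$spec]] <- peak_group(
      E, s$mu, sig, area, th$slope,
      step_height = th$step_height, tail_fraction = th$tail_fraction,
      tail_slope = th$tail_slope, with_step = TRUE, with_tail = TRUE
    )
    if (refine) {
      artifacts <- artifacts + peak_group(
        E, s$mu, sig, area, th$slope,
        step_height = th$step_height, tail_fraction = th$tail_fraction,
        tail_slope = th$tail_slope, with_step = TRUE, with_tail = TRUE,
        with_gauss = FALSE
      )
    }
    if (ctx$escape && length(s$esc_mu)) {
      esc_parts[[length(esc_parts) + 1L]] <- peak_group(
        E, s$esc_mu, sigma_at(s$esc_mu, th),
        (th$escape_fraction * A) * s$esc_br, th$slope
      )
    }
  }

  elastic <- gaussian_line(E, e0, sigma_at(e0, th), th$elastic_amplitude,
                           th$slope)
  mu_c <- compton_energy(e0, th$compton_angle)
  sig_c <- th$compton_fwhm_corr * sigma_at(mu_c, th)
  compton <- peak_single(
    E, mu_c, sig_c, th$compton_amplitude, th$slope,
    step_height = th$compton_step, tail_fraction = th$compton_tail_fraction,
    tail_slope = th$compton_tail_slope, with_step = TRUE, with_tail = TRUE
  )
  if (refine) {
    artifacts <- artifacts + peak_single(
      E, mu_c, sig_c, th$compton_amplitude, th$slope,
      step_height = th$compton_step,
      tail_fraction = th$compton_tail_fraction,
      tail_slope = th$compton_tail_slope, with_step = TRUE,
      with_tail = TRUE, with_gauss = FALSE
    )
  }

  if (ctx$escape && ctx$escape_scatter) {
    mat <- ctx$material
    if (e0 > mat$edge_energy) {
      esc_parts[[length(esc_parts) + 1L]] <- gaussian_line(
        E, e0 - mat$escape_line_energy,
        sigma_at(e0 - mat$escape_line_energy, th),
        th$escape_fraction * th$elastic_amplitude, th$slope
      )
    }
    if (ad_value(mu_c) > mat$edge_energy) {
      mu_ce <- mu_c - mat$escape_line_energy
      esc_parts[[length(esc_parts) + 1L]] <- gaussian_line(
        E, mu_ce, sigma_at(mu_ce, th),
        th$escape_fraction * th$compton_amplitude, th$slope
      )
    }
  }
  escape <- numeric(n)
  for (p in esc_parts) escape <- escape + p

  bg <- if (identical(ctx$background, "none")) {
    numeric(n)
  } else if (is.numeric(ctx$background)) {
    stopifnot(length(ctx$background) == n)
    ctx$background
  } else {
    stopifnot(!is.null(observed))
    # the channel window is frozen (ctx$snip_idx, from the reference
    # calibration) during optimization so the loss stays continuous in the
    # calibration parameters; widths inside remain differentiable
    bg_in <- if (refine) ad_clamp(observed - artifacts, 0, Inf) else observed
    snip_core(bg_in, E, th, ctx$snip, ctx$fit_range, idx = ctx$snip_idx)
  }

  total <- bg + elastic + compton + escape
  for (v in element) total <- total + v

  list(energy = E, element = element, elastic = elastic, compton = compton,
       escape = escape, background = bg, total = total)
}

#' Evaluate the full model spectrum and its components
#'
#' Runs the forward model at fixed parameters and amplitudes: characteristic
#' line peaks (Gaussian + step + tail) per element specification, Rayleigh
#' (elastic) and Compton scatter peaks, detector escape peaks, optional
#' pileup sum peaks, plus the background. The total is the channel-wise sum
#' of all components.
#'
#' @param elements element specification string or tibble
#'   (see [parse_element_list()]).
#' @param amplitudes named vector of element amplitudes in counts (names are
#'   canonical spec labels, e.g. `c(Fe = 1e5, Pt_L = 2e4)`).
#' @param params an [xrf_params()] set.
#' @param n_channels number of channels.
#' @param observed optional observed counts vector, required when
#'   `background = "snip"`.
#' @param background `"none"` (default), `"snip"`, or a numeric vector.
#' @param ... further options passed to [xrf_model_context()].
#' @return a tibble with one row per channel: `channel`, `energy`,
#'   `background`, `elastic`, `compton`, `escape`, one column per element
#'   spec, and `total`.
#' @export
#' @examples
#' sp <- model_spectrum("Fe,Cu", c(Fe = 1e4, Cu = 5e3), xrf_params(),
#'                      n_channels = 1024)
#' head(sp)
model_spectrum <- function(elements, amplitudes, params,
                           n_channels = 2048, observed = NULL,
                           background = "none", ...) {
  ctx <- xrf_model_context(elements, n_channels = n_channels,
                           incident_energy = params$incident_energy,
                           background = background, ...)
  la <- as.list(log10(pmax(amplitudes, 1e-300)))
  missing_specs <- setdiff(names(ctx$specs), names(la))
  if (length(missing_specs)) {
    stop("missing amplitude for: ", paste(missing_specs, collapse = ", "))
  }
  comp <- eval_model(ctx, params, la, observed = observed)
  out <- tibble::tibble(
    channel = seq_len(n_channels) - 1L,
    energy = comp$energy,
    background = comp$background,
    elastic = comp$elastic,
    compton = comp$compton,
    escape = comp$escape
  )
  for (nm in names(comp$element)) out[[nm]] <- comp$element[[nm]]
  out$total <- comp$total
  out
}

#' Spectrum of a single element specification
#'
#' Sum over the excitable lines of the (element, family) group of
#' area-normalized Gaussians with step and tail contributions; each line's
#' area is `amplitude * branching_ratio`, so the family's integrated counts
#' approximately equal `amplitude`.
#'
#' @param element chemical symbol (or pileup spec like `"Si_Si"`).
#' @param family line family, default `"K"`.
#' @param amplitude total family counts.
#' @param params an [xrf_params()] set.
#' @param n_channels number of channels.
#' @return numeric vector of counts per channel.
#' @export
element_spectrum <- function(element, family = "K", amplitude, params,
                             n_channels = 2048) {
  stopifnot(amplitude >= 0)
  spec <- if (family == "K") element else paste(element, family, sep = "_")
  el <- parse_element_list(spec)
  ctx <- xrf_model_context(el, n_channels = n_channels,
                           incident_energy = params$incident_energy,
                           escape = FALSE, background = "none")
  la <- stats::setNames(list(log10(max(amplitude, 1e-300))), el$spec)
  v <- eval_model(ctx, params, la)$element[[el$spec]]
  pmax(v, 0)
}

#' Scatter peaks
#'
#' `elastic_peak()` places a Gaussian of area `elastic_amplitude` at the
#' incident energy; `compton_peak()` places a Gaussian + step + tail of area
#' `compton_amplitude` at the Compton-shifted energy, widened by
#' `compton_fwhm_corr`.
#'
#' @param params an [xrf_params()] set.
#' @param n_channels number of channels.
#' @return numeric counts per channel.
#' @export
elastic_peak <- function(params, n_channels = 2048) {
  E <- energy_axis(params, n_channels)
  gaussian_line(E, params$incident_energy,
                sigma_at(params$incident_energy, params),
                params$elastic_amplitude, params$slope)
}

#' @rdname elastic_peak
#' @export
compton_peak <- function(params, n_channels = 2048) {
  E <- energy_axis(params, n_channels)
  mu <- compton_energy(params$incident_energy, params$compton_angle)
  peak_single(E, mu, params$compton_fwhm_corr * sigma_at(mu, params),
              params$compton_amplitude, params$slope,
              step_height = params$compton_step,
              tail_fraction = params$compton_tail_fraction,
              tail_slope = params$compton_tail_slope,
              with_step = TRUE, with_tail = TRUE)
}

#' Escape peaks for a set of parent Gaussian peaks
#'
#' For every parent peak above the detector material's absorption edge, adds
#' a Gaussian at `parent energy - escape line energy` with area
#' `escape_fraction * parent area`. Parents whose shifted center falls at or
#' below zero energy are dropped.
#'
#' @param parents a data frame with columns `mu` (keV) and `area` (counts).
#' @param params an [xrf_params()] set.
#' @param n_channels number of channels.
#' @param material detector material name.
#' @return numeric counts per channel.
#' @export
escape_peaks <- function(parents, params, n_channels = 2048,
                         material = "Si") {
  mat <- escape_constants(material)
  E <- energy_axis(params, n_channels)
  keep <- parents$mu > mat$edge_energy &
    (parents$mu - mat$escape_line_energy) > 0
  mu <- parents$mu[keep] - mat$escape_line_energy
  peak_group(E, mu, sigma_at(mu, params),
             params$escape_fraction * parents$area[keep], params$slope)
}

#' Pileup sum peak for a pair of element specifications
#'
#' A single Gaussian at the sum of the two partners' strongest excitable
#' line energies, with its own free amplitude. Returns zeros when either
#' partner has no excitable line.
#'
#' @param spec pileup specification string, e.g. `"Si_Si"`.
#' @param amplitude peak area in counts.
#' @param params an [xrf_params()] set.
#' @param n_channels number of channels.
#' @return numeric counts per channel.
#' @export
pileup_peak <- function(spec, amplitude, params, n_channels = 2048) {
  el <- parse_element_list(spec)
  stopifnot(el$is_pileup)
  ctx <- xrf_model_context(el, n_channels = n_channels,
                           incident_energy = params$incident_energy,
                           escape = FALSE, background = "none")
  center <- ctx$specs[[1]]$center
  if (is.na(center)) return(numeric(n_channels))
  E <- energy_axis(params, n_channels)
  gaussian_line(E, center, sigma_at(center, params), amplitude, params$slope)
}
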