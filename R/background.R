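#' SNIP background configuration
#'
#' Parameters of the iterative peak-clipping continuum estimator. Each
#' channel is repeatedly replaced by the minimum of itself and the mean of
#' two neighbours offset by a clipping half-width; the half-width tracks the
#' detector resolution (`base_width` FWHM units converted to channels) and
#' shrinks geometrically by `width_decay` until it falls below `min_width`.
#' Counts are first boxcar-smoothed and moved to the log-log-sqrt (LLS)
#' scale, which compresses the dynamic range so tall peaks are clipped in
#' few passes.
#'
#' @param base_width clipping half-width in units of the local FWHM
#'   (default 2: the largest clipping window spans about two FWHM, wide
#'   enough that an isolated Gaussian peak is fully clipped away).
#' @param boxcar_width odd boxcar width in channels for pre-smoothing.
#' @param initial_reps clipping passes at the full width before decay.
#' @param width_decay multiplicative width decay per pass, in (0, 1).
#' @param min_width stop once the maximal half-width (channels) drops below
#'   this.
#' @return a list of class `snip_config`.
#' @export
snip_config <- function(base_width = 2, boxcar_width = 5L,
                        initial_reps = 16L, width_decay = 1 / sqrt(2),
                        min_width = 0.5) {
  stopifnot(base_width > 0, boxcar_width >= 1, boxcar_width %% 2 == 1,
            initial_reps >= 1, width_decay > 0, width_decay < 1,
            min_width >= 0)
  structure(list(base_width = base_width, boxcar_width = boxcar_width,
                 initial_reps = initial_reps, width_decay = width_decay,
                 min_width = min_width), class = "snip_config")
}

# differentiable SNIP on the computation graph; observed is plain numeric,
# E/th may be tape variables. Fractional clipping half-widths use linear
# interpolation between neighbouring channels so the background stays
# differentiable in the calibration and resolution parameters (integer
# widths reduce to exact indexing). Returns a full-length background, zero
# outside the fit range.
snip_core <- function(observed, E, th, cfg, fit_range, idx = NULL) {
  n <- length(observed)
  if (is.null(idx)) {
    Ev <- ad_value(E)
    idx <- which(Ev >= fit_range[1] & Ev <= fit_range[2] & Ev > 0)
    if (length(idx) < 2L) stop("fit range selects fewer than 2 channels")
    idx <- seq.int(min(idx), max(idx))
  }
  m <- length(idx)

  y <- boxcar_smooth(observed[idx], cfg$boxcar_width)
  v <- log(log(sqrt(y + 1) + 1) + 1)

  Esub <- if (is_ad(E)) E[idx] else E[idx]
  w <- cfg$base_width * (2.3548 * sigma_at(Esub, th)) / th$slope

  clip1 <- function(v, w) snip_clip_pass(v, w)
  for (r in seq_len(cfg$initial_reps)) v <- clip1(v, w)
  wcur <- w
  while (max(ad_value(wcur)) > cfg$min_width) {
    v <- clip1(v, wcur)
    wcur <- wcur * cfg$width_decay
  }
  b <- (exp(exp(v) - 1) - 1)^2 - 1
  b <- clean_nonneg(b)
  scatter_into(n, idx, b)
}

# one clipping pass v_i <- min(v_i, (v[i-w] + v[i+w])/2), fused in the
# compiled kernel; v and/or w may be tape variables
snip_clip_pass <- function(v, w) {
  av <- is_ad(v); aw <- is_ad(w)
  vv <- ad_value(v); wv <- ad_value(w)
  out <- cpp_snip_clip_f(vv, wv)
  if (!av && !aw) return(out)
  tape <- if (av) v$tape else w$tape
  p <- c(if (av) v$id else 0L, if (aw) w$id else 0L)
  ad_node(tape, out, p, function(g) {
    b <- cpp_snip_clip_b(g, vv, wv)
    list(if (av) b$gv, if (aw) b$gw)
  })
}

#' SNIP continuum estimate of a spectrum
#'
#' Runs the peak-clipping background estimator at fixed parameters and
#' returns the per-channel continuum. This is the same routine embedded in
#' the fitting computation graph (there it stays differentiable with
#' respect to the calibration and resolution parameters); here it is
#' evaluated numerically.
#'
#' @param counts numeric counts per channel (or a spectrum tibble with a
#'   `counts` column).
#' @param params an [xrf_params()] set.
#' @param config a [snip_config()].
#' @param fit_range `c(E_min, E_max)` keV; default
#'   `c(0.25, incident_energy + 1)`. Channels outside get background 0.
#' @return a tibble with `channel`, `energy`, `counts`, `background`.
#' @export
snip_background <- function(counts, params, config = snip_config(),
                            fit_range = NULL) {
  if (is.data.frame(counts)) counts <- counts$counts
  stopifnot(all(counts >= 0))
  n <- length(counts)
  E <- energy_axis(params, n)
  fr <- fit_range %||% c(0.25, params$incident_energy + 1)
  bg <- snip_core(counts, E, params, config, fr)
  tibble::tibble(channel = seq_len(n) - 1L, energy = E, counts = counts,
                 background = bg)
}

#' Plain reference SNIP implementation
#'
#' A straightforward, non-graph reimplementation of the same clipping
#' schedule, written with explicit loops and its own interpolation code.
#' It exists as an independent cross-check of the differentiable version:
#' the two must agree channel for channel.
#'
#' @inheritParams snip_background
#' @return numeric background vector (full length, zero outside the range).
#' @export
snip_background_reference <- function(counts, params,
                                      config = snip_config(),
                                      fit_range = NULL) {
  if (is.data.frame(counts)) counts <- counts$counts
  n <- length(counts)
  ch <- seq_len(n) - 1
  en <- params$offset + params$slope * ch + params$quad * ch^2
  fr <- fit_range %||% c(0.25, params$incident_energy + 1)
  sel <- which(en >= fr[1] & en <= fr[2] & en > 0)
  if (length(sel) < 2L) stop("fit range selects fewer than 2 channels")
  sel <- seq.int(min(sel), max(sel))
  m <- length(sel)

  # boxcar with replicated edges
  bw <- config$boxcar_width
  h <- (bw - 1L) %/% 2L
  yy <- counts[sel]
  if (bw > 1L) {
    yp <- c(rep(yy[1], h), yy, rep(yy[m], h))
    sm <- numeric(m)
    for (i in seq_len(m)) sm[i] <- mean(yp[i:(i + bw - 1L)])
    yy <- sm
  }
  v <- log(log(sqrt(yy + 1) + 1) + 1)

  fw <- 2.3548 * sqrt((params$fwhm_offset / 2.3548)^2 +
                        0.00358 * params$fwhm_fano * pmax(en[sel], 0))
  w <- config$base_width * fw / params$slope

  read_at <- function(v, p) {
    p <- pmin(pmax(p, 1), m)
    f <- pmin(floor(p), m - 1)
    t <- p - f
    v[f] * (1 - t) + v[f + 1] * t
  }
  clip_pass <- function(v, w) {
    i <- seq_len(m)
    avg <- (read_at(v, i - w) + read_at(v, i + w)) / 2
    out <- pmin(v, avg)
    # both neighbours must be in range, else the channel is left unclipped
    off <- (i - w) < 1 | (i + w) > m
    out[off] <- v[off]
    out
  }
  for (r in seq_len(config$initial_reps)) v <- clip_pass(v, w)
  wcur <- w
  while (max(wcur) > config$min_width) {
    v <- clip_pass(v, wcur)
    wcur <- wcur * config$width_decay
  }
  b <- (exp(exp(v) - 1) - 1)^2 - 1
  b[!is.finite(b) | b < 0] <- 0
  out <- numeric(n)
  out[sel] <- b
  out
}
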