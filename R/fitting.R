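#' Mean-squared-error fitting loss
#'
#' Mean over the masked channels of the squared residual between observed
#' and model counts — the objective minimized during fitting.
#'
#' @param observed,model equal-length count vectors.
#' @param mask integer channel indices (1-based) or logical vector; default
#'   all channels.
#' @return scalar MSE.
#' @export
#' @examples
#' mse_loss(c(1, 2, 3), c(1, 2, 5)) # 4/3
mse_loss <- function(observed, model, mask = NULL) {
  n <- length(ad_value(observed))
  stopifnot(length(ad_value(model)) == n)
  idx <- if (is.null(mask)) seq_len(n) else if (is.logical(mask)) which(mask) else as.integer(mask)
  if (length(idx) == 0L) stop("empty channel mask")
  r <- (observed - model)[idx]
  mean(r * r)
}

#' Coefficient of determination of a fit
#'
#' `R^2 = 1 - RSS/TSS`, with the residual sum of squares equal to the MSE
#' times the number of masked channels. 1 is a perfect fit; 0 means the
#' model does no better than the mean of the observations; negative values
#' mean worse than the mean.
#'
#' @inheritParams mse_loss
#' @return scalar, at most 1.
#' @export
r_squared <- function(observed, model, mask = NULL) {
  n <- length(observed)
  idx <- if (is.null(mask)) seq_len(n) else if (is.logical(mask)) which(mask) else as.integer(mask)
  if (length(idx) == 0L) stop("empty channel mask")
  y <- observed[idx]
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("observed spectrum is constant on the mask; R^2 undefined")
  1 - sum((y - model[idx])^2) / tss
}

#' Fitting configuration
#'
#' @param n_iterations optimizer iterations (default 500).
#' @param learning_rate base step size of the adaptive optimizer (default
#'   0.02); parameters are optimized on a unit-interval scale over their
#'   bound ranges (and amplitudes on log10 scale), so one step moves a
#'   parameter by at most about 2% of its range.
#' @param optimizer `"adam"` (adaptive moments, default) or `"sgd"` (plain
#'   gradient descent).
#' @param warmup_set names of the parameters co-optimized with the
#'   amplitudes during warmup (default: the calibration coefficients).
#' @param warmup_smooth odd boxcar width (channels) applied to both the
#'   observed and the model spectrum in the warmup loss (default 31,
#'   roughly two line widths; 1 disables). Smoothing widens each peak's
#'   basin of attraction so a several-percent calibration error, which
#'   displaces peaks by many line widths, still produces a useful
#'   gradient; the joint phase always uses the exact loss.
#' @param n_restarts number of cosine-annealing cycles in the joint phase
#'   (default 2). Re-warming the learning rate lets the optimizer leave
#'   shallow attraction basins and settle again; the reported fit is still
#'   the lowest-loss iterate across the whole run.
#' @param warmup_fraction fraction of the iterations spent warming up
#'   amplitudes and energy calibration before the full joint fit (default
#'   0.2). Randomly initialized amplitudes can be orders of magnitude off
#'   and a few-percent calibration error misplaces peaks by many line
#'   widths; fitting amplitudes and calibration first, with the peak-shape
#'   and scatter parameters held, is a far better-conditioned subproblem
#'   and keeps one huge mis-scaled or mis-placed peak from dragging the
#'   shape parameters into a broad-peak local minimum. Set to 0 for a
#'   plain joint loop.
#' @param lr_decay `"cosine"` (anneal to 0 across the run, default) or
#'   `"none"`.
#' @param init `"heuristic"` (window-sum amplitude estimates, default
#'   parameters), `"random"` (uniform within bounds, seeded), or
#'   `"provided"` (use the `params`/`amplitudes` arguments as given).
#' @param seed integer seed for random initialization.
#' @param optimize character vector of parameter names to optimize; default
#'   is every parameter flagged optimizable in [param_table()]. Element
#'   amplitudes are always optimized.
#' @param bounds optional tibble like [param_table()] (columns `name`,
#'   `lower`, `upper`) overriding bound intervals.
#' @param amp_init_range log10 range for random amplitude initialization.
#' @param background `"snip"` (estimated each iteration inside the
#'   computation graph), `"none"`, or a fixed numeric vector.
#' @param snip a [snip_config()].
#' @param refine_background see [xrf_model_context()]; the linear solver
#'   applies the same refinement by fixed-point iteration
#'   (`n_bg_refine` rounds).
#' @param n_bg_refine background-refinement rounds in
#'   [linear_amplitudes()].
#' @param escape,escape_scatter,fit_range see [xrf_model_context()].
#' @return a list of class `xrf_fit_config`.
#' @export
xrf_fit_config <- function(n_iterations = 500L, learning_rate = 0.02,
                           optimizer = c("adam", "sgd"),
                           warmup_fraction = 0.2, n_restarts = 2L,
                           warmup_set = c("offset", "slope", "quad"),
                           warmup_smooth = 31L,
                           lr_decay = c("cosine", "none"),
                           init = c("heuristic", "random", "provided"),
                           seed = 1L, optimize = NULL, bounds = NULL,
                           amp_init_range = c(2, 6),
                           background = "snip", snip = snip_config(),
                           refine_background = TRUE, n_bg_refine = 3L,
                           escape = TRUE, escape_scatter = TRUE,
                           fit_range = NULL) {
  structure(list(
    n_iterations = as.integer(n_iterations),
    learning_rate = learning_rate,
    optimizer = match.arg(optimizer),
    warmup_fraction = warmup_fraction,
    warmup_set = warmup_set,
    warmup_smooth = as.integer(warmup_smooth),
    n_restarts = max(1L, as.integer(n_restarts)),
    lr_decay = match.arg(lr_decay),
    init = match.arg(init),
    seed = as.integer(seed), optimize = optimize, bounds = bounds,
    amp_init_range = amp_init_range,
    background = background, snip = snip,
    refine_background = refine_background,
    n_bg_refine = as.integer(n_bg_refine),
    escape = escape, escape_scatter = escape_scatter,
    fit_range = fit_range
  ), class = "xrf_fit_config")
}

# bound table with per-fit overrides applied; the log-scale scatter
# amplitudes get a data-driven upper bound (a peak area cannot exceed the
# total counts, and integrated scan spectra far exceed the per-pixel scale
# the static table describes)
effective_bounds <- function(config, counts = NULL) {
  tab <- param_table()
  if (!is.null(counts)) {
    cap <- log10(sum(counts) + 10)
    j <- which(tab$log10)
    tab$upper[j] <- pmax(tab$upper[j], cap)
  }
  if (!is.null(config$bounds)) {
    for (i in seq_len(nrow(config$bounds))) {
      j <- match(config$bounds$name[i], tab$name)
      if (is.na(j)) stop("unknown parameter in bounds: ", config$bounds$name[i])
      tab$lower[j] <- config$bounds$lower[i]
      tab$upper[j] <- config$bounds$upper[i]
    }
  }
  if (!is.null(config$optimize)) {
    bad <- setdiff(config$optimize, tab$name)
    if (length(bad)) stop("unknown parameter(s) in optimize: ",
                          paste(bad, collapse = ", "))
    tab$optimizable <- tab$name %in% config$optimize
  }
  tab
}

ctx_from_config <- function(elements, n_channels, incident_energy, config) {
  xrf_model_context(
    elements, n_channels = n_channels, incident_energy = incident_energy,
    escape = config$escape, escape_scatter = config$escape_scatter,
    background = config$background,
    refine_background = isTRUE(config$refine_background),
    snip = config$snip,
    fit_range = config$fit_range
  )
}

# freeze the fit-window channel indices from a reference calibration so the
# loss is continuous in the calibration parameters during optimization
freeze_ctx_window <- function(ctx, params) {
  E <- energy_axis(params, ctx$n_channels)
  idx <- which(E >= ctx$fit_range[1] & E <= ctx$fit_range[2] & E > 0)
  if (length(idx) < 2L) stop("fit range selects fewer than 2 channels")
  ctx$snip_idx <- seq.int(min(idx), max(idx))
  ctx$mask_idx <- ctx$snip_idx
  ctx
}

#' Initialize parameters and amplitudes for a fit
#'
#' Heuristic mode starts from the default parameter set and estimates each
#' element amplitude from the background-subtracted counts in a +/- 2 sigma
#' window around its strongest excitable line (scaled by that line's
#' branching ratio, floored at 1 count). Random mode draws every optimizable
#' parameter uniformly within its bounds and amplitudes log-uniformly in
#' `amp_init_range`, using the configuration seed.
#'
#' @param counts numeric observed counts (or spectrum tibble).
#' @param elements element tibble or specification string.
#' @param config an [xrf_fit_config()].
#' @param params starting [xrf_params()] for `init = "provided"` (also the
#'   base set for `"heuristic"`).
#' @param amplitudes named amplitude vector (counts) for
#'   `init = "provided"`.
#' @param incident_energy beam energy (keV).
#' @return list with `params` (class `xrf_params`) and `log_amplitudes`
#'   (named log10 amplitudes).
#' @export
init_fit <- function(counts, elements, config = xrf_fit_config(),
                     params = NULL, amplitudes = NULL,
                     incident_energy = if (!is.null(params)) params$incident_energy else 12) {
  if (is.data.frame(counts)) counts <- counts$counts
  if (is.character(elements)) elements <- parse_element_list(elements)
  tab <- effective_bounds(config, counts)
  base <- params %||% xrf_params(incident_energy = incident_energy)

  if (config$init == "random") {
    set.seed(config$seed)
    th <- as.list(base)
    for (i in seq_len(nrow(tab))) {
      if (!tab$optimizable[i]) next
      v <- runif(1, tab$lower[i], tab$upper[i])
      if (tab$log10[i]) v <- 10^v
      th[[tab$name[i]]] <- v
    }
    th <- do.call(xrf_params, c(th[tab$name],
                                list(incident_energy = incident_energy)))
    la <- runif(nrow(elements), config$amp_init_range[1],
                config$amp_init_range[2])
    names(la) <- elements$spec
    return(list(params = th, log_amplitudes = la))
  }

  if (config$init == "provided") {
    stopifnot(!is.null(params), !is.null(amplitudes))
    la <- log10(pmax(amplitudes[elements$spec], 1))
    return(list(params = params, log_amplitudes = la))
  }

  # heuristic: window sums around strongest lines over SNIP-subtracted counts
  fr <- config$fit_range %||% c(0.25, incident_energy + 1)
  bg <- snip_background_reference(counts, base, config$snip, fr)
  resid <- pmax(counts - bg, 0)
  E <- energy_axis(base, length(counts))
  # scatter amplitudes from the same window-sum heuristic; data scales
  # (e.g. integrated scans) can be far from the table defaults
  base <- as.list(base)
  s_el <- sigma_at(incident_energy, base)
  base$elastic_amplitude <-
    max(sum(resid[abs(E - incident_energy) <= 2 * s_el]), 100)
  mu_c <- compton_energy(incident_energy, base$compton_angle)
  s_c <- base$compton_fwhm_corr * sigma_at(mu_c, base)
  base$compton_amplitude <-
    max(sum(resid[abs(E - mu_c) <= 2 * s_c]), 100)
  base <- do.call(xrf_params, c(base[param_table()$name],
                                list(incident_energy = incident_energy)))
  la <- numeric(nrow(elements))
  names(la) <- elements$spec
  for (i in seq_len(nrow(elements))) {
    row <- elements[i, ]
    if (row$is_pileup) {
      la[i] <- 0 # 1 count
      next
    }
    ln <- lines_for(row$element, row$family, incident_energy)
    if (nrow(ln) == 0L) {
      la[i] <- 0
      next
    }
    k <- which.max(ln$ratio)
    mu <- ln$energy_kev[k]
    s <- sigma_at(mu, base)
    win <- which(abs(E - mu) <= 2 * s)
    amp <- sum(resid[win]) / ln$ratio[k]
    la[i] <- log10(max(amp, 1))
  }
  list(params = base, log_amplitudes = la)
}

# Adam / SGD update on a flat parameter vector
make_optimizer <- function(kind, n_par) {
  m <- numeric(n_par)
  v <- numeric(n_par)
  t <- 0L
  b1 <- 0.9; b2 <- 0.99; eps <- 1e-8
  function(x, g, lr) {
    t <<- t + 1L
    if (kind == "adam") {
      m <<- b1 * m + (1 - b1) * g
      v <<- b2 * v + (1 - b2) * g * g
      mh <- m / (1 - b1^t)
      vh <- v / (1 - b2^t)
      x - lr * mh / (sqrt(vh) + eps)
    } else {
      x - lr * g
    }
  }
}

# one forward+backward pass; returns loss value and gradient vector over
# c(z-scaled optimizable theta, log10 amplitudes). smooth > 1 evaluates the
# loss between boxcar-smoothed observed and model spectra (warmup phase)
fit_step_grad <- function(ctx, observed, tab, opt_idx, z_frozen, x,
                          smooth = 1L) {
  n_opt <- length(opt_idx)
  tape <- ad_tape()
  zvars <- vector("list", n_opt)
  zl <- as.list(z_frozen)
  for (j in seq_len(n_opt)) {
    zvars[[j]] <- ad_var(tape, x[j])
    zl[[opt_idx[j]]] <- zvars[[j]]
  }
  th <- z_to_theta(zl, tab, ctx$incident_energy)
  nspec <- length(ctx$specs)
  lavars <- vector("list", nspec)
  la <- vector("list", nspec)
  names(la) <- names(ctx$specs)
  for (j in seq_len(nspec)) {
    lavars[[j]] <- ad_var(tape, x[n_opt + j])
    la[[j]] <- lavars[[j]]
  }
  comp <- eval_model(ctx, th, la, observed = observed)
  loss <- if (smooth > 1L) {
    mse_loss(boxcar_smooth(observed, smooth),
             boxcar_smooth(comp$total, smooth), ctx$mask_idx)
  } else {
    mse_loss(observed, comp$total, ctx$mask_idx)
  }
  grads <- ad_backward(loss)
  g <- numeric(length(x))
  for (j in seq_len(n_opt)) g[j] <- ad_grad_of(grads, zvars[[j]])
  for (j in seq_len(nspec)) g[n_opt + j] <- ad_grad_of(grads, lavars[[j]])
  list(loss = loss$v, grad = g)
}

#' Fit a spectrum by AD-based joint optimization
#'
#' Runs the gradient-descent fitting loop: each iteration recomputes the
#' SNIP background inside the computation graph, evaluates the model
#' spectrum, measures the MSE loss against the observed counts, obtains
#' exact gradients for every optimizable parameter and amplitude by
#' reverse-mode automatic differentiation, and takes an adaptive (Adam)
#' step. Parameters are box-constrained to their bound intervals after each
#' update. The returned fit is the iterate with the lowest recorded loss.
#'
#' @param counts observed spectrum: numeric counts per channel or a tibble
#'   with a `counts` column.
#' @param elements element tibble or specification string.
#' @param config an [xrf_fit_config()].
#' @param params,amplitudes optional starting values (see [init_fit()]).
#' @param incident_energy beam energy (keV).
#' @return an object of class `xrf_fit`: fitted parameters (`params`),
#'   `amplitudes` (counts), the per-channel `spectrum` tibble (observed,
#'   model, background, residual), per-component model columns
#'   (`components`), `loss_trace`, `r_squared`, and bookkeeping fields.
#'   Works with [tidy()], [glance()] and [autoplot()].
#' @export
fit_spectrum <- function(counts, elements, config = xrf_fit_config(),
                         params = NULL, amplitudes = NULL,
                         incident_energy = if (!is.null(params)) params$incident_energy else 12) {
  if (is.data.frame(counts)) counts <- counts$counts
  if (is.character(elements)) elements <- parse_element_list(elements)
  n <- length(counts)
  tab <- effective_bounds(config, counts)
  ini <- init_fit(counts, elements, config, params, amplitudes,
                  incident_energy)

  ctx <- ctx_from_config(elements, n, incident_energy, config)
  ctx <- freeze_ctx_window(ctx, ini$params)

  z_all <- theta_to_z(ini$params, tab)
  opt_idx <- which(tab$optimizable)
  x <- c(z_all[opt_idx], ini$log_amplitudes[names(ctx$specs)])
  n_opt <- length(opt_idx)
  n_amp <- length(ctx$specs)

  n_iter <- config$n_iterations
  n_warm <- min(round((config$warmup_fraction %||% 0) * n_iter), n_iter)
  n_joint <- n_iter - n_warm
  n_cycles <- if (n_joint > 0) min(config$n_restarts %||% 1L, n_joint) else 1L
  cycle_len <- if (n_joint > 0) ceiling(n_joint / n_cycles) else 0L
  amp_slots <- n_opt + seq_len(n_amp)
  warm_slots <- c(which(tab$name[opt_idx] %in% (config$warmup_set %||%
                                                  character(0))),
                  amp_slots)
  loss_trace <- numeric(n_iter)
  best_x <- x
  best_loss <- Inf
  best_it <- 0L
  step_warm <- make_optimizer(config$optimizer, length(warm_slots))
  step <- NULL
  sm <- max(1L, config$warmup_smooth %||% 1L)
  if (sm %% 2L == 0L) sm <- sm + 1L
  for (it in seq_len(n_iter)) {
    fg <- fit_step_grad(ctx, counts, tab, opt_idx, z_all, x,
                        smooth = if (it <= n_warm) sm else 1L)
    if (!is.finite(fg$loss)) {
      bad <- which(!is.finite(fg$grad))
      nm <- c(tab$name[opt_idx], names(ctx$specs))
      stop("non-finite loss at iteration ", it,
           if (length(bad)) paste0(" (suspect: ",
                                   paste(nm[head(bad, 3)], collapse = ", "),
                                   ")") else "")
    }
    loss_trace[it] <- fg$loss
    if (fg$loss < best_loss) {
      best_loss <- fg$loss
      best_x <- x
      best_it <- it
    }
    if (it <= n_warm) {
      x[warm_slots] <- step_warm(x[warm_slots], fg$grad[warm_slots],
                                 config$learning_rate)
      x[seq_len(n_opt)] <- pmin(pmax(x[seq_len(n_opt)], 0), 1)
      if (it == n_warm) best_loss <- Inf # phases use different losses
    } else {
      pos <- (it - n_warm - 1L) %% cycle_len # position within this cycle
      if (pos == 0L) step <- make_optimizer(config$optimizer, length(x))
      lr <- config$learning_rate
      if (config$lr_decay == "cosine" && cycle_len > 1L) {
        lr <- lr * 0.5 * (1 + cos(pi * pos / (cycle_len - 1)))
      }
      x <- step(x, fg$grad, lr)
      x[seq_len(n_opt)] <- pmin(pmax(x[seq_len(n_opt)], 0), 1)
    }
  }

  # evaluate at the best iterate (or the initialization when n_iterations=0)
  if (n_iter == 0L) best_x <- x
  z_best <- z_all
  z_best[opt_idx] <- best_x[seq_len(n_opt)]
  th_list <- z_to_theta(as.list(z_best), tab, incident_energy)
  th_best <- do.call(xrf_params, c(th_list[tab$name],
                                   list(incident_energy = incident_energy)))
  la_best <- best_x[n_opt + seq_len(n_amp)]
  names(la_best) <- names(ctx$specs)
  comp <- eval_model(ctx, th_best, as.list(la_best), observed = counts)
  final_loss <- mse_loss(counts, comp$total, ctx$mask_idx)

  sp <- tibble::tibble(
    channel = seq_len(n) - 1L, energy = comp$energy, observed = counts,
    model = comp$total, background = comp$background,
    residual = counts - comp$total
  )
  components <- tibble::as_tibble(
    c(list(channel = sp$channel, energy = sp$energy,
           background = comp$background, elastic = comp$elastic,
           compton = comp$compton, escape = comp$escape), comp$element)
  )
  structure(list(
    params = th_best,
    amplitudes = setNames(10^la_best, names(la_best)),
    log_amplitudes = la_best,
    elements = elements,
    spectrum = sp,
    components = components,
    loss_trace = loss_trace,
    loss = final_loss,
    r_squared = r_squared(counts, ad_value(comp$total), ctx$mask_idx),
    mask = ctx$mask_idx,
    best_iteration = best_it,
    config = config,
    init = ini
  ), class = "xrf_fit")
}

#' Fixed-parameter linear amplitude solve
#'
#' With the instrument parameters frozen, the model is linear in the
#' amplitudes: the spectrum is a non-negative combination of unit-amplitude
#' component spectra (one per element spec plus the elastic and Compton
#' peaks, each including its escape peaks). This solves the
#' background-subtracted counts by non-negative least squares
#' (Lawson-Hanson; `solver = "svd"` gives the unconstrained least-squares
#' solution instead).
#'
#' @param counts observed counts vector or spectrum tibble.
#' @param elements element tibble or specification string.
#' @param params frozen [xrf_params()].
#' @param solver `"nnls"` (default) or `"svd"`.
#' @param config an [xrf_fit_config()] (model options and fit range).
#' @param design optional precomputed design from [amplitude_design()].
#' @return tibble with columns `term` and `amplitude` (counts); element
#'   terms first, then `elastic` and `compton`.
#' @export
linear_amplitudes <- function(counts, elements, params,
                              solver = c("nnls", "svd"),
                              config = xrf_fit_config(), design = NULL) {
  solver <- match.arg(solver)
  if (is.data.frame(counts)) counts <- counts$counts
  if (is.null(design)) {
    design <- amplitude_design(elements, params, length(counts), config)
  }
  A <- design$matrix[design$mask, , drop = FALSE]
  solve1 <- function(bg) {
    if (all(counts == 0)) return(numeric(ncol(A)))
    y <- (counts - bg)[design$mask]
    if (solver == "nnls") {
      pracma::lsqnonneg(A, y)$x
    } else {
      qrA <- qr(A)
      if (qrA$rank < ncol(A)) {
        warning("rank-deficient design; returning smallest-norm solution")
        sv <- svd(A)
        keep <- sv$d > max(sv$d) * 1e-10
        as.numeric(sv$v[, keep, drop = FALSE] %*%
                     ((crossprod(sv$u[, keep, drop = FALSE], y)) /
                        sv$d[keep]))
      } else {
        as.numeric(qr.coef(qrA, y))
      }
    }
  }
  use_snip <- identical(config$background, "snip")
  bg <- if (use_snip) {
    snip_background_reference(counts, params, config$snip, design$fit_range)
  } else if (is.numeric(config$background)) {
    config$background
  } else {
    numeric(length(counts))
  }
  a <- solve1(bg)
  if (use_snip && isTRUE(config$refine_background) && any(counts > 0)) {
    # same artifact-aware background as the nonlinear fit, reached by
    # fixed-point iteration: subtract the step/tail components implied by
    # the current amplitudes, re-estimate, re-solve
    for (k in seq_len(config$n_bg_refine)) {
      art <- as.numeric(design$st_matrix %*% a)
      bg <- snip_background_reference(pmax(counts - art, 0), params,
                                      config$snip, design$fit_range)
      a <- solve1(bg)
    }
  }
  tibble::tibble(term = design$terms, amplitude = as.numeric(a))
}

#' Unit-amplitude component design matrix
#'
#' Columns are the model spectra of each element spec, the elastic peak and
#' the Compton peak, all at unit amplitude and the given frozen parameters
#' (escape peaks included with their parents). Built once and reused for
#' per-pixel mapping.
#'
#' @inheritParams linear_amplitudes
#' @param n_channels channel count.
#' @return list with `matrix`, `terms`, `mask`, `fit_range`.
#' @export
amplitude_design <- function(elements, params, n_channels,
                             config = xrf_fit_config()) {
  if (is.character(elements)) elements <- parse_element_list(elements)
  config$background <- "none"
  ctx <- ctx_from_config(elements, n_channels, params$incident_energy,
                         config)
  ctx <- freeze_ctx_window(ctx, params)
  th <- as.list(params)
  th$elastic_amplitude <- 1
  th$compton_amplitude <- 1
  la <- as.list(setNames(numeric(length(ctx$specs)), names(ctx$specs)))
  comp <- eval_model(ctx, th, la)
  # per-element columns must carry their own escape peaks; recompute escape
  # per spec by evaluating specs one at a time is wasteful, so distribute
  # escape by rebuilding it per element from the context
  cols <- list()
  st_cols <- list()
  for (s in ctx$specs) {
    v <- comp$element[[s$spec]]
    stv <- numeric(ctx$n_channels)
    if (!s$is_pileup && length(s$mu)) {
      stv <- peak_group(comp$energy, s$mu, sigma_at(s$mu, th), s$br,
                        th$slope, step_height = th$step_height,
                        tail_fraction = th$tail_fraction,
                        tail_slope = th$tail_slope, with_step = TRUE,
                        with_tail = TRUE, with_gauss = FALSE)
    }
    if (ctx$escape && !s$is_pileup && length(s$esc_mu)) {
      E <- comp$energy
      v <- v + peak_group(E, s$esc_mu, sigma_at(s$esc_mu, th),
                          th$escape_fraction * s$esc_br, th$slope)
    }
    cols[[s$spec]] <- v
    st_cols[[s$spec]] <- stv
  }
  el <- comp$elastic
  co <- comp$compton
  if (ctx$escape && ctx$escape_scatter) {
    mat <- ctx$material
    E <- comp$energy
    e0 <- ctx$incident_energy
    if (e0 > mat$edge_energy) {
      mu <- e0 - mat$escape_line_energy
      el <- el + gaussian_line(E, mu, sigma_at(mu, th),
                               th$escape_fraction, th$slope)
    }
    mu_c <- compton_energy(e0, th$compton_angle)
    if (mu_c > mat$edge_energy) {
      mu <- mu_c - mat$escape_line_energy
      co <- co + gaussian_line(E, mu, sigma_at(mu, th),
                               th$escape_fraction, th$slope)
    }
  }
  cols$elastic <- el
  cols$compton <- co
  st_cols$elastic <- numeric(ctx$n_channels)
  mu_c <- compton_energy(ctx$incident_energy, th$compton_angle)
  st_cols$compton <- peak_single(
    comp$energy, mu_c, th$compton_fwhm_corr * sigma_at(mu_c, th), 1,
    th$slope, step_height = th$compton_step,
    tail_fraction = th$compton_tail_fraction,
    tail_slope = th$compton_tail_slope, with_step = TRUE, with_tail = TRUE,
    with_gauss = FALSE)
  list(matrix = do.call(cbind, cols), terms = names(cols),
       st_matrix = do.call(cbind, st_cols),
       mask = ctx$mask_idx, fit_range = ctx$fit_range)
}

#' Compare AD gradients against central finite differences
#'
#' For every optimizable scalar — the instrument parameters on their
#' natural scales and the per-element log10 amplitudes — computes the
#' reverse-mode gradient of the MSE loss and a central finite-difference
#' estimate (relative step 1e-4, floored at 1e-4 of 1% of the bound
#' range for near-zero parameters), and reports the per-parameter
#' relative error `|ad - fd| / max(|ad|, |fd|, floor)` with a floor of
#' 1e-6 times the largest gradient magnitude.
#'
#' @inheritParams fit_spectrum
#' @return tibble with `term`, `grad_ad`, `grad_fd`, `rel_error`; frozen
#'   parameters are omitted (reported via the `skipped` attribute).
#' @export
gradient_check <- function(counts, elements, config = xrf_fit_config(),
                           params = NULL, amplitudes = NULL,
                           incident_energy = if (!is.null(params)) params$incident_energy else 12) {
  if (is.data.frame(counts)) counts <- counts$counts
  if (is.character(elements)) elements <- parse_element_list(elements)
  tab <- effective_bounds(config, counts)
  ini <- init_fit(counts, elements, config, params, amplitudes,
                  incident_energy)
  ctx <- ctx_from_config(elements, length(counts), incident_energy, config)
  ctx <- freeze_ctx_window(ctx, ini$params)
  opt_names <- tab$name[tab$optimizable]
  th0 <- as.list(ini$params)
  la0 <- ini$log_amplitudes[names(ctx$specs)]
  nm <- c(opt_names, names(ctx$specs))
  x0 <- c(vapply(opt_names, function(n) th0[[n]], numeric(1)), la0)

  loss_at <- function(x) {
    th <- th0
    for (j in seq_along(opt_names)) th[[opt_names[j]]] <- x[j]
    la <- as.list(x[length(opt_names) + seq_along(ctx$specs)])
    names(la) <- names(ctx$specs)
    comp <- eval_model(ctx, th, la, observed = counts)
    mse_loss(counts, comp$total, ctx$mask_idx)
  }

  # AD gradient with tape variables on the natural scales
  tape <- ad_tape()
  th <- th0
  thvars <- vector("list", length(opt_names))
  for (j in seq_along(opt_names)) {
    thvars[[j]] <- ad_var(tape, th0[[opt_names[j]]])
    th[[opt_names[j]]] <- thvars[[j]]
  }
  lavars <- vector("list", length(ctx$specs))
  la <- vector("list", length(ctx$specs))
  names(la) <- names(ctx$specs)
  for (j in seq_along(ctx$specs)) {
    lavars[[j]] <- ad_var(tape, la0[[j]])
    la[[j]] <- lavars[[j]]
  }
  comp <- eval_model(ctx, th, la, observed = counts)
  grads <- ad_backward(mse_loss(counts, comp$total, ctx$mask_idx))
  gad <- c(
    vapply(thvars, function(v) ad_grad_of(grads, v), numeric(1)),
    vapply(lavars, function(v) ad_grad_of(grads, v), numeric(1))
  )

  # parameter-relative central differences
  rng <- setNames(tab$upper - tab$lower, tab$name)
  gfd <- numeric(length(x0))
  for (j in seq_along(x0)) {
    scale_j <- if (j <= length(opt_names)) {
      max(abs(x0[j]), 0.01 * rng[[opt_names[j]]])
    } else {
      max(abs(x0[j]), 0.01)
    }
    h <- 1e-4 * scale_j
    xp <- x0; xp[j] <- x0[j] + h
    xm <- x0; xm[j] <- x0[j] - h
    gfd[j] <- (loss_at(xp) - loss_at(xm)) / (2 * h)
  }
  floor_ <- 1e-6 * max(abs(gad), abs(gfd))
  out <- tibble::tibble(
    term = nm, grad_ad = gad, grad_fd = gfd,
    rel_error = abs(gad - gfd) / pmax(abs(gad), abs(gfd), floor_)
  )
  attr(out, "skipped") <- tab$name[!tab$optimizable]
  out
}
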