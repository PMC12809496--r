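# small in-code fixtures shared across tests

FIVE_ELEMENTS <- "Fe,Cu,Ca,Zn,K"

# deterministic noise-free synthetic spectrum and its truth
fixture_spectrum <- function(seed = 11, n = 2048, noise = FALSE,
                             elements = FIVE_ELEMENTS, ...) {
  tr <- sample_truth(elements, seed = seed, noise = noise)
  synth_spectrum(tr, n_channels = n, ...)
}

# theta perturbed by a fraction of each bound interval, amplitudes random
perturbed_start <- function(truth, seed, frac = 0.1,
                            amp_range = c(2, 6)) {
  tab <- param_table()
  z <- adxrf:::theta_to_z(truth$params)
  set.seed(seed + 1000)
  zp <- pmin(pmax(z + runif(length(z), -frac, frac), 0), 1)
  thp <- adxrf:::z_to_theta(as.list(zp), tab, truth$params$incident_energy)
  params <- do.call(xrf_params, c(
    thp[tab$name],
    list(incident_energy = truth$params$incident_energy)
  ))
  set.seed(seed + 2000)
  amps <- 10^runif(nrow(truth$elements), amp_range[1], amp_range[2])
  names(amps) <- truth$elements$spec
  list(params = params, amplitudes = amps)
}

# numeric central finite difference of f at x
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}
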