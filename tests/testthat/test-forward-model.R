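test_that("energy axis evaluates the quadratic calibration", {
  expect_equal(energy_axis(list(offset = 0, slope = 0.01, quad = 0), 3),
               c(0, 0.01, 0.02))
  ax <- energy_axis(list(offset = -0.05, slope = 0.01, quad = 0), 101)
  expect_equal(ax[101], 0.95)
  ax2 <- energy_axis(list(offset = 0, slope = 0.01, quad = 1e-7), 1001)
  expect_equal(ax2[1001], 10.1)
  expect_true(all(diff(ax2) > 0))
})

test_that("detector resolution model evaluates and is monotone", {
  ps <- xrf_params(fwhm_offset = 0.12, fwhm_fano = 0.114)
  expect_equal(sigma_at(6.4, ps), 0.0722, tolerance = 1e-3)
  # fano = 0 collapses to the electronic-noise floor at every energy
  ps0 <- xrf_params(fwhm_fano = 1e-12)
  expect_equal(sigma_at(c(1, 5, 10), ps0), rep(0.12 / 2.3548, 3),
               tolerance = 1e-6)
  e <- seq(0.5, 12, by = 0.5)
  expect_true(all(diff(sigma_at(e, ps)) > 0))
})

test_that("Compton shift follows the closed form", {
  expect_equal(compton_energy(12, 90), 11.7247, tolerance = 1e-4)
  expect_equal(compton_energy(12, 180), 11.4617, tolerance = 1e-4)
  expect_equal(compton_energy(12, 1e-9), 12)
  expect_lt(compton_energy(12, 120), compton_energy(12, 90))
})

test_that("gaussian peak is area-normalized, unimodal and symmetric", {
  th <- xrf_params()
  ax <- energy_axis(th, 2048)
  g <- gaussian_peak(ax, 6, 0.08, 1e4, th$slope)
  expect_equal(sum(g), 1e4, tolerance = 1e-3)
  pk <- which.max(g)
  expect_equal(ax[pk], 6, tolerance = th$slope)
  # symmetry about the center
  expect_equal(g[pk + 1:20], g[pk - 1:20], tolerance = 1e-6)
})

test_that("step contribution is a half-height shelf rolling off above mu", {
  th <- xrf_params()
  ax <- energy_axis(th, 2048)
  s0 <- step_contrib(ax, 6, 0.08, 1e4, th$slope, 0)
  expect_equal(s0, numeric(2048))
  s <- step_contrib(ax, 6, 0.08, 1e4, th$slope, 0.05)
  plateau <- s[ax > 1 & ax < 5]
  expect_equal(diff(range(plateau)), 0, tolerance = 1e-6)
  i_mu <- which.min(abs(ax - 6))
  expect_equal(s[i_mu], plateau[1] / 2, tolerance = 1e-3)
  expect_lt(s[ax > 7][1] / plateau[1], 1e-10)
})

test_that("tail mass equals tail_fraction times area (quadrature oracle)", {
  th <- xrf_params()
  ax <- energy_axis(th, 2048)
  t0 <- tail_contrib(ax, 6, 0.08, 1e4, th$slope, 0, 1)
  expect_equal(t0, numeric(2048), tolerance = 1e-12)
  for (gam in c(0.5, 1, 2)) {
    tl <- tail_contrib(ax, 6, 0.08, 1e4, th$slope, 0.1, gam)
    # independent quadrature of the closed-form tail density
    dens <- function(e) {
      z <- (e - 6) / 0.08
      0.1 * 1e4 / (2 * gam * 0.08) *
        exp(z / gam + 1 / (2 * gam^2)) *
        pracma::erfc(z / sqrt(2) + 1 / (sqrt(2) * gam))
    }
    mass <- stats::integrate(dens, 0, 12, rel.tol = 1e-8)$value
    expect_equal(sum(tl), 0.1 * 1e4, tolerance = 0.02)
    expect_equal(sum(tl), mass, tolerance = 0.01)
    # one-sided: more counts below the center than above
    expect_gt(sum(tl[ax < 6]), sum(tl[ax > 6]))
  }
})

test_that("element spectrum respects branching ratios and conservation", {
  th <- xrf_params(step_height = 1e-12, tail_fraction = 1e-12,
                   escape_fraction = 0)
  v <- element_spectrum("Fe", "K", 5e4, th, 2048)
  expect_equal(sum(v), 5e4, tolerance = 5e-3)
  ax <- energy_axis(th, 2048)
  ka_win <- abs(ax - 6.40) < 0.25
  kb_win <- abs(ax - 7.06) < 0.25
  ln <- lines_for("Fe", "K", 12)
  ka_br <- sum(ln$ratio[startsWith(ln$label, "Ka")])
  kb_br <- sum(ln$ratio[startsWith(ln$label, "Kb")])
  expect_equal(sum(v[kb_win]) / sum(v[ka_win]), kb_br / ka_br,
               tolerance = 0.01)
  # element with all edges above the incident energy contributes nothing
  thl <- xrf_params(incident_energy = 5)
  expect_equal(element_spectrum("Pt", "L", 1e4, thl, 1024), numeric(1024))
})

test_that("scatter peaks sit at the expected energies with unit areas", {
  th <- xrf_params(compton_step = 1e-12, compton_tail_fraction = 1e-12,
                   compton_angle = 120)
  el <- elastic_peak(th, 2048)
  co <- compton_peak(th, 2048)
  ax <- energy_axis(th, 2048)
  expect_equal(ax[which.max(el)], 12, tolerance = 2 * th$slope)
  expect_equal(ax[which.max(co)], compton_energy(12, 120),
               tolerance = 2 * th$slope)
  expect_lt(ax[which.max(co)], ax[which.max(el)])
  expect_equal(sum(el), th$elastic_amplitude, tolerance = 1e-2)
  expect_equal(sum(co), th$compton_amplitude, tolerance = 1e-2)
  th0 <- xrf_params(elastic_amplitude = 1e-300, compton_amplitude = 1e-300)
  expect_equal(max(elastic_peak(th0, 1024)), 0, tolerance = 1e-290)
})

test_that("escape peaks appear shifted by the Si K-alpha energy", {
  th <- xrf_params(escape_fraction = 0.02)
  ax <- energy_axis(th, 2048)
  parents <- data.frame(mu = c(7.00, 1.50), area = c(1e4, 1e4))
  esc <- escape_peaks(parents, th, 2048)
  # parent above the Si edge produces a peak at 7.00 - 1.740 = 5.260
  expect_equal(ax[which.max(esc)], 5.260, tolerance = 2 * th$slope)
  # parent below the Si edge produces nothing: total is one escape peak
  expect_equal(sum(esc), 0.02 * 1e4, tolerance = 1e-2)
  th0 <- xrf_params(escape_fraction = 0)
  expect_equal(escape_peaks(parents, th0, 2048), numeric(2048))
})

test_that("pileup peak sits at the sum of the strongest line energies", {
  th <- xrf_params()
  ax <- energy_axis(th, 2048)
  v <- pileup_peak("Si_Si", 1e3, th, 2048)
  expect_equal(ax[which.max(v)], 2 * 1.7400, tolerance = 2 * th$slope)
  expect_equal(sum(v), 1e3, tolerance = 1e-2)
  expect_equal(pileup_peak("Si_Si", 0, th, 2048), numeric(2048),
               tolerance = 1e-12)
  # wider than either parent line: sigma grows with energy
  expect_gt(sigma_at(3.48, th), sigma_at(1.74, th))
})

test_that("model spectrum equals the brute-force component sum", {
  th <- xrf_params(step_height = 0.02, tail_fraction = 0.05,
                   tail_slope = 1.2, escape_fraction = 0.01)
  amps <- c(Fe = 1e5, Ca = 2e4)
  sp <- model_spectrum("Fe,Ca", amps, th, n_channels = 1500,
                       escape_scatter = FALSE)
  ax <- energy_axis(th, 1500)
  si <- escape_constants("Si")

  # independent brute-force loop over every line, written from the formulas
  brute <- numeric(1500)
  for (el in c("Fe", "Ca")) {
    ln <- lines_for(el, "K", th$incident_energy)
    for (i in seq_len(nrow(ln))) {
      mu <- ln$energy_kev[i]
      area <- amps[el] * ln$ratio[i]
      s <- sqrt((th$fwhm_offset / 2.3548)^2 + 0.00358 * th$fwhm_fano * mu)
      z <- pmin(pmax((ax - mu) / s, -30), 30)
      brute <- brute + area * th$slope * exp(-z^2 / 2) / (s * sqrt(2 * pi))
      brute <- brute + th$step_height * area * th$slope / (2 * mu) *
        pracma::erfc(z / sqrt(2))
      gam <- th$tail_slope
      brute <- brute + th$tail_fraction * area * th$slope / (2 * gam * s) *
        exp(-z^2 / 2) * pracma::erfcx(z / sqrt(2) + 1 / (sqrt(2) * gam))
      if (mu > si$edge_energy) {
        mue <- mu - si$escape_line_energy
        se <- sqrt((th$fwhm_offset / 2.3548)^2 + 0.00358 * th$fwhm_fano * mue)
        ze <- pmin(pmax((ax - mue) / se, -30), 30)
        brute <- brute + th$escape_fraction * area * th$slope *
          exp(-ze^2 / 2) / (se * sqrt(2 * pi))
      }
    }
  }
  elements_only <- sp$Fe + sp$Ca + sp$escape
  expect_equal(elements_only, brute, tolerance = 1e-7)
  # total is the channel-wise sum of all components
  comp_sum <- sp$background + sp$elastic + sp$compton + sp$escape +
    sp$Fe + sp$Ca
  expect_equal(sp$total, comp_sum, tolerance = 1e-12)
})

test_that("model is additive and permutation invariant over elements", {
  th <- xrf_params(escape_fraction = 0.01)
  a <- c(Fe = 2e4, Cu = 5e3, Ca = 1e4)
  s_abc <- model_spectrum("Fe,Cu,Ca", a, th, n_channels = 1024,
                          escape_scatter = FALSE)
  s_cab <- model_spectrum("Ca,Fe,Cu", a, th, n_channels = 1024,
                          escape_scatter = FALSE)
  expect_equal(s_abc$total, s_cab$total, tolerance = 1e-12)

  s_a <- model_spectrum("Fe", a["Fe"], th, n_channels = 1024,
                        escape_scatter = FALSE)
  s_bc <- model_spectrum("Cu,Ca", a[c("Cu", "Ca")], th, n_channels = 1024,
                         escape_scatter = FALSE)
  # elements superpose; scatter is counted once
  expect_equal(s_abc$total - s_abc$elastic - s_abc$compton,
               (s_a$total - s_a$elastic - s_a$compton) +
                 (s_bc$total - s_bc$elastic - s_bc$compton),
               tolerance = 1e-9)
})

test_that("all model components are non-negative", {
  tr <- sample_truth(FIVE_ELEMENTS, seed = 3, noise = FALSE)
  sp <- model_spectrum(tr$elements, 10^tr$log_amplitudes, tr$params,
                       n_channels = 2048)
  for (col in setdiff(names(sp), c("channel", "energy"))) {
    expect_true(all(sp[[col]] >= 0), info = col)
  }
})

test_that("zero amplitudes leave only the background", {
  th <- xrf_params(elastic_amplitude = 1e-300, compton_amplitude = 1e-300)
  bgv <- rep(7, 1024)
  sp <- model_spectrum("Fe", c(Fe = 1e-300), th, n_channels = 1024,
                       background = bgv)
  expect_equal(sp$total, bgv, tolerance = 1e-250)
})
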