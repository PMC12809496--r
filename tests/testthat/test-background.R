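test_that("constant spectra are their own background", {
  th <- xrf_params()
  obs <- rep(100, 2048)
  bg <- snip_background(obs, th)
  inside <- bg$energy >= 0.25 & bg$energy <= 13
  expect_equal(bg$background[inside], rep(100, sum(inside)),
               tolerance = 1e-6)
  expect_equal(bg$background[!inside], rep(0, sum(!inside)))
})

test_that("differentiable SNIP equals the plain reference channel for channel", {
  th <- xrf_params()
  set.seed(4)
  E <- energy_axis(th, 2048)
  obs <- 60 + 40 * exp(-E / 3) +
    gaussian_peak(E, 4, 0.07, 2e4, th$slope) +
    gaussian_peak(E, 8, 0.09, 5e3, th$slope)
  obs <- rpois(2048, pmax(obs, 0))

  # general (fractional-width) configuration
  ours <- snip_background(obs, th)$background
  ref <- snip_background_reference(obs, th)
  expect_equal(ours, ref, tolerance = 1e-9)

  # integer-width configuration: fano = 0 makes the width constant;
  # base_width chosen so the half-width is exactly 10 channels
  thi <- xrf_params(fwhm_fano = 1e-30)
  wconst <- 10 * thi$slope / 0.12 # base_width giving w = 10 channels
  cfg <- snip_config(base_width = wconst)
  expect_equal(cfg$base_width * 0.12 / thi$slope, 10, tolerance = 1e-12)
  ours_i <- snip_background(obs, thi, cfg)$background
  ref_i <- snip_background_reference(obs, thi, cfg)
  expect_lt(max(abs(ours_i - ref_i)) / max(ref_i), 1e-6)
})

test_that("background under an isolated peak recovers the flat continuum", {
  th <- xrf_params()
  E <- energy_axis(th, 2048)
  obs <- 50 + gaussian_peak(E, 6, 5 * sigma_at(6, th) / 5, 1e4, th$slope)
  bg <- snip_background(obs, th)$background
  under <- abs(E - 6) < 2 * sigma_at(6, th)
  expect_true(all(abs(bg[under] - 50) / 50 < 0.15))
})

test_that("background never exceeds the smoothed spectrum", {
  th <- xrf_params()
  set.seed(9)
  E <- energy_axis(th, 2048)
  obs <- rpois(2048, 80 + gaussian_peak(E, 5, 0.08, 1e4, th$slope))
  bg <- snip_background(obs, th)$background
  # smoothing acts on the fit-range subvector with replicated edges,
  # exactly as inside the estimator
  idx <- which(E >= 0.25 & E <= 13)
  idx <- seq.int(min(idx), max(idx))
  sm <- boxcar_smooth(obs[idx], 5)
  expect_true(all(bg[idx] <= sm + 1e-6))
})

test_that("SNIP is nearly idempotent on its own output", {
  th <- xrf_params()
  set.seed(10)
  E <- energy_axis(th, 2048)
  obs <- 70 + 30 * exp(-E / 4) + gaussian_peak(E, 6, 0.08, 3e4, th$slope)
  b1 <- snip_background(obs, th)$background
  b2 <- snip_background(b1, th)$background
  inside <- which(E >= 0.3 & E <= 12.4 & b1 > 1)
  expect_true(all(abs(b2[inside] - b1[inside]) / b1[inside] < 0.01))
})

test_that("gradients flow through the background to the calibration", {
  th <- xrf_params()
  set.seed(11)
  E0 <- energy_axis(th, 1024)
  obs <- rpois(1024, 50 + 50 * exp(-E0 / 4) +
                 gaussian_peak(E0, 6, 0.08, 2e4, th$slope))
  fr <- c(0.25, 10)
  idx <- which(E0 >= fr[1] & E0 <= fr[2])
  idx <- seq.int(min(idx), max(idx))
  loss_of <- function(slope) {
    thl <- as.list(th)
    thl$slope <- slope
    ch <- 0:1023
    E <- thl$offset + thl$slope * ch + thl$quad * ch^2
    bg <- adxrf:::snip_core(obs, E, thl, snip_config(), fr, idx = idx)
    r <- (obs - bg)[idx]
    mean(r * r)
  }
  tp <- ad_tape()
  sl <- ad_var(tp, th$slope)
  L <- loss_of(sl)
  g_ad <- ad_grad_of(ad_backward(L), sl)
  expect_true(is.finite(g_ad))
  expect_true(abs(g_ad) > 0)
  h <- 1e-7
  g_fd <- (loss_of(th$slope + h) - loss_of(th$slope - h)) / (2 * h)
  expect_equal(g_ad, g_fd, tolerance = 1e-3)
})

test_that("degenerate fit ranges are rejected", {
  th <- xrf_params()
  expect_error(snip_background(rep(10, 1024), th, fit_range = c(50, 60)),
               "fewer than 2")
})
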