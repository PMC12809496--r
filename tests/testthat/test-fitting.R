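test_that("MSE loss matches hand arithmetic and scales quadratically", {
  expect_equal(mse_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse_loss(c(1, 2, 3), c(1, 2, 5)), 4 / 3)
  y <- c(2, 4, 9); m <- c(1, 5, 7)
  expect_equal(mse_loss(3 * y, 3 * m), 9 * mse_loss(y, m))
  expect_equal(mse_loss(y, m, mask = c(1, 2)), mean(c(1, 1)))
  expect_error(mse_loss(y, m, mask = integer(0)), "empty")
})

test_that("R^2 identities hold exactly", {
  set.seed(2)
  y <- rpois(200, 50)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 200)), 0)
  m <- y + rnorm(200)
  # residual sum of squares equals MSE times the channel count
  rss <- sum((y - m)^2)
  expect_equal(mse_loss(y, m) * 200, rss)
  expect_equal(r_squared(y, m), 1 - rss / sum((y - mean(y))^2))
  expect_error(r_squared(rep(5, 10), rnorm(10)), "constant")
})

test_that("random initialization is seeded and respects bounds", {
  sp <- fixture_spectrum(seed = 21)
  el <- parse_element_list(FIVE_ELEMENTS)
  cfg <- xrf_fit_config(init = "random", seed = 33)
  i1 <- init_fit(sp$counts, el, cfg)
  i2 <- init_fit(sp$counts, el, cfg)
  expect_identical(i1, i2)
  tab <- param_table()
  for (i in seq_len(nrow(tab))) {
    v <- i1$params[[tab$name[i]]]
    if (tab$log10[i]) v <- log10(v)
    expect_gte(v, tab$lower[i])
    expect_lte(v, tab$upper[i])
  }
  i3 <- init_fit(sp$counts, el, xrf_fit_config(init = "random", seed = 34))
  expect_false(identical(i1$log_amplitudes, i3$log_amplitudes))
})

test_that("heuristic amplitudes land near the truth for dominant peaks", {
  tr <- sample_truth("Fe,Ca", seed = 40, noise = FALSE,
                     amp_range = c(5, 5.5))
  sp <- synth_spectrum(tr, n_channels = 2048)
  ini <- init_fit(sp$counts, tr$elements, xrf_fit_config(),
                  params = tr$params)
  truth_la <- tr$log_amplitudes
  # within a factor of 3 on noise-free data (windows at the true
  # calibration, so only background subtraction and branching approximate)
  expect_true(all(abs(ini$log_amplitudes - truth_la) < log10(3)))
  # an element with no excitable line gets the floor of 1 count
  el2 <- parse_element_list("Fe,Pt_L")
  ini2 <- init_fit(sp$counts, el2,
                   xrf_fit_config(),
                   params = xrf_params(incident_energy = 5),
                   incident_energy = 5)
  expect_equal(unname(ini2$log_amplitudes["Pt_L"]), 0)
})

test_that("zero iterations return the initialization unchanged", {
  sp <- fixture_spectrum(seed = 22)
  tr <- ground_truth(sp)
  cfg <- xrf_fit_config(n_iterations = 0, init = "provided")
  f <- fit_spectrum(sp$counts, FIVE_ELEMENTS, cfg, params = tr$params,
                    amplitudes = 10^tr$log_amplitudes)
  expect_equal(length(f$loss_trace), 0)
  expect_equal(f$best_iteration, 0)
  expect_equal(unname(f$log_amplitudes), unname(tr$log_amplitudes),
               tolerance = 1e-12)
  expect_equal(f$params$slope, tr$params$slope, tolerance = 1e-12)
  expect_gt(f$r_squared, 0.99)
})

test_that("amplitude-only AD fit recovers truth on noise-free data", {
  tr <- sample_truth(FIVE_ELEMENTS, seed = 23, noise = FALSE)
  sp <- synth_spectrum(tr, n_channels = 2048)
  set.seed(5)
  a0 <- 10^runif(5, 3, 5)
  names(a0) <- tr$elements$spec
  cfg <- xrf_fit_config(n_iterations = 500, init = "provided",
                        optimize = character(0), warmup_fraction = 0,
                        seed = 23)
  f <- fit_spectrum(sp$counts, FIVE_ELEMENTS, cfg, params = tr$params,
                    amplitudes = a0)
  expect_gte(f$r_squared, 0.999)
  truth_a <- 10^tr$log_amplitudes
  contrib <- truth_a / sum(sp$counts)
  big <- contrib >= 0.01
  expect_true(all(abs(f$amplitudes[names(truth_a)][big] /
                        truth_a[big] - 1) < 0.02))
})

test_that("best-iterate loss never exceeds any joint-phase loss", {
  sp <- fixture_spectrum(seed = 25)
  cfg <- xrf_fit_config(n_iterations = 40, init = "heuristic", seed = 1)
  f <- fit_spectrum(sp$counts, FIVE_ELEMENTS, cfg)
  expect_length(f$loss_trace, 40)
  # warmup entries use the smoothed loss; the best iterate is selected over
  # the exact-loss joint phase
  joint <- f$loss_trace[(round(0.2 * 40) + 1):40]
  expect_lte(f$loss, min(joint) * (1 + 1e-8))
})

test_that("seeded fits are reproducible", {
  sp <- fixture_spectrum(seed = 26, noise = TRUE)
  cfg <- xrf_fit_config(n_iterations = 25, init = "random", seed = 7)
  f1 <- fit_spectrum(sp$counts, FIVE_ELEMENTS, cfg)
  f2 <- fit_spectrum(sp$counts, FIVE_ELEMENTS, cfg)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$amplitudes, f2$amplitudes)
})

test_that("linear solver recovers exact amplitudes on clean data at true parameters", {
  tr <- sample_truth(FIVE_ELEMENTS, seed = 27, noise = FALSE)
  sp <- synth_spectrum(tr, n_channels = 2048)
  la <- linear_amplitudes(sp$counts, FIVE_ELEMENTS, tr$params)
  truth_a <- 10^tr$log_amplitudes
  got <- la$amplitude[match(names(truth_a), la$term)]
  contrib <- truth_a / sum(sp$counts)
  big <- contrib >= 0.005
  expect_true(all(abs(got[big] / truth_a[big] - 1) < 0.005))
  # all-zero spectrum gives all-zero amplitudes
  la0 <- linear_amplitudes(numeric(2048), FIVE_ELEMENTS, tr$params)
  expect_equal(la0$amplitude, rep(0, nrow(la0)))
})

test_that("svd solver agrees with nnls on well-posed clean data", {
  tr <- sample_truth("Fe,Ca", seed = 28, noise = FALSE, amp_range = c(4, 5))
  sp <- synth_spectrum(tr, n_channels = 1024)
  a1 <- linear_amplitudes(sp$counts, "Fe,Ca", tr$params, solver = "nnls")
  a2 <- linear_amplitudes(sp$counts, "Fe,Ca", tr$params, solver = "svd")
  expect_equal(a1$amplitude[1:2], a2$amplitude[1:2], tolerance = 0.01)
})

test_that("AD gradients match finite differences for every optimizable scalar", {
  sp <- fixture_spectrum(seed = 29, noise = TRUE, target_total = 1e6)
  rep1 <- gradient_check(sp$counts, FIVE_ELEMENTS,
                         config = xrf_fit_config(init = "random", seed = 3))
  expect_lte(max(rep1$rel_error), 1e-3)
  # every optimizable parameter plus one amplitude per element is reported
  expect_equal(nrow(rep1), sum(param_table()$optimizable) + 5)
  # frozen parameters are reported as skipped
  cfg2 <- xrf_fit_config(init = "random", seed = 3,
                         optimize = c("slope", "fwhm_offset"))
  rep2 <- gradient_check(sp$counts, FIVE_ELEMENTS, config = cfg2)
  expect_equal(nrow(rep2), 2 + 5)
  expect_true("quad" %in% attr(rep2, "skipped"))
})

test_that("non-finite losses abort with a diagnostic", {
  sp <- fixture_spectrum(seed = 30)
  cfg <- xrf_fit_config(n_iterations = 5, init = "provided")
  bad <- 10^sample_truth(FIVE_ELEMENTS, seed = 30)$log_amplitudes
  bad[1] <- 1e300 # overflows the squared residual
  expect_error(
    fit_spectrum(sp$counts, FIVE_ELEMENTS, cfg,
                 params = xrf_params(), amplitudes = bad),
    "non-finite loss"
  )
})
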