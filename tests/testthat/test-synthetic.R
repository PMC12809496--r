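test_that("truth sampling is seeded and stays within the stated ranges", {
  t1 <- sample_truth(FIVE_ELEMENTS, seed = 5)
  t2 <- sample_truth(FIVE_ELEMENTS, seed = 5)
  expect_identical(t1$log_amplitudes, t2$log_amplitudes)
  expect_identical(unclass(t1$params), unclass(t2$params))
  t3 <- sample_truth(FIVE_ELEMENTS, seed = 6)
  expect_false(identical(t1$log_amplitudes, t3$log_amplitudes))

  tab <- param_table()
  for (i in seq_len(nrow(tab))) {
    v <- t1$params[[tab$name[i]]]
    if (tab$log10[i]) v <- log10(v)
    expect_gte(v, tab$lower[i]); expect_lte(v, tab$upper[i])
  }
  expect_true(all(t1$log_amplitudes >= 2 & t1$log_amplitudes <= 6))
})

test_that("noise-free realization equals forward model plus continuum", {
  tr <- sample_truth("Fe,Ca", seed = 7, noise = FALSE)
  sp <- synth_spectrum(tr, n_channels = 1024)
  manual <- model_spectrum(tr$elements, 10^tr$log_amplitudes, tr$params,
                           n_channels = 1024)$total
  E <- energy_axis(tr$params, 1024)
  cont <- tr$continuum$amplitude * exp(-pmax(E, 0) / tr$continuum$tau)
  cont[E <= 0] <- 0
  expect_equal(sp$counts, manual + cont, tolerance = 1e-12)
  # truth manifest travels with the data
  expect_s3_class(ground_truth(sp), "xrf_truth")
})

test_that("Poisson noise is seeded and unbiased", {
  tr <- sample_truth("Fe,Ca", seed = 8, noise = TRUE)
  s1 <- synth_spectrum(tr, n_channels = 512)
  s2 <- synth_spectrum(tr, n_channels = 512)
  expect_identical(s1$counts, s2$counts)
  expect_true(all(s1$counts == round(s1$counts)))

  clean <- adxrf:::synth_clean_total(tr, 512)
  reps <- vapply(1:200, function(k) {
    synth_spectrum(tr, n_channels = 512, seed = 1000 + k)$counts
  }, numeric(512))
  mu <- rowMeans(reps)
  se <- sqrt(pmax(clean, 1e-9) / 200)
  frac_in <- mean(abs(mu - clean) <= 3 * se)
  expect_gt(frac_in, 0.99)
})

test_that("count-target rescaling hits the requested total", {
  tr <- sample_truth(FIVE_ELEMENTS, seed = 9, noise = FALSE)
  sp <- synth_spectrum(tr, n_channels = 2048, target_total = 1e6)
  expect_equal(sum(sp$counts), 1e6, tolerance = 1e-6)
  # the attached truth reflects the rescaled amplitudes
  tr2 <- ground_truth(sp)
  again <- synth_spectrum(tr2, n_channels = 2048)
  expect_equal(sum(again$counts), 1e6, tolerance = 1e-6)
})

test_that("scan cubes honour patterns and integrate linearly", {
  tr <- sample_truth("Fe,Ca", seed = 12, noise = FALSE)
  sc <- synth_scan(tr, rows = 4, cols = 5, n_channels = 256,
                   pattern = "constant")
  expect_equal(dim(sc$counts), c(4, 5, 256))
  # constant pattern: every pixel identical
  base <- sc$counts[1, 1, ]
  for (r in 1:4) for (cc in 1:5) {
    expect_equal(sc$counts[r, cc, ], base, tolerance = 1e-9)
  }
  # integration equals the sum of pixels
  int <- integrate_scan(sc)
  expect_equal(int$counts, 20 * base, tolerance = 1e-9)

  # blob pattern: the generated cube reflects the stored truth fields
  # (nominal calibration so the element lines sit on the shorter axis)
  trb <- tr
  trb$params <- xrf_params()
  sb <- synth_scan(trb, rows = 8, cols = 8, n_channels = 1024,
                   pattern = "blobs")
  f <- sb$fields[, , "Fe"]
  expect_equal(mean(f), 1, tolerance = 1e-9)
  expect_gt(max(f) / min(f), 2)
  amps <- 10^trb$log_amplitudes
  w <- amps["Fe"] * as.numeric(f) +
    amps["Ca"] * as.numeric(sb$fields[, , "Ca"])
  per_pix <- as.numeric(apply(sb$counts, c(1, 2), sum))
  expect_gt(cor(per_pix, w), 0.999)
})

test_that("round trip: fitting a noise-free realization at the truth leaves R^2 at 1", {
  tr <- sample_truth(FIVE_ELEMENTS, seed = 13, noise = FALSE)
  sp <- synth_spectrum(tr, n_channels = 2048)
  cfg <- xrf_fit_config(n_iterations = 0, init = "provided")
  f <- fit_spectrum(sp$counts, FIVE_ELEMENTS, cfg, params = tr$params,
                    amplitudes = 10^tr$log_amplitudes)
  expect_gte(f$r_squared, 0.99999)
})
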