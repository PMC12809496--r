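test_that("spectrum CSV round trips and rejects bad input", {
  d <- withr::local_tempdir()
  p <- file.path(d, "sp.csv")
  x <- tibble::tibble(channel = 0:9, counts = c(5, 7, 0, 1:7))
  write_spectrum(x, p)
  back <- read_spectrum(p)
  expect_equal(back$counts, x$counts)
  expect_equal(back$channel, x$channel)

  # headerless two-column CSV is accepted
  writeLines(c("0,5", "1,7", "2,0"), p)
  expect_equal(read_spectrum(p)$counts, c(5, 7, 0))

  writeLines(c("0,5", "1,-3"), p)
  expect_error(read_spectrum(p), "invalid counts")
  expect_error(read_spectrum(file.path(d, "nope.csv")), "no such file")
})

test_that("scan CSV + manifest round trips including the ground truth", {
  d <- withr::local_tempdir()
  tr <- sample_truth("Fe,Ca", seed = 61, noise = TRUE,
                     amp_range = c(3, 4))
  sc <- synth_scan(tr, rows = 3, cols = 4, n_channels = 128)
  p <- file.path(d, "scan.csv")
  write_scan(sc, p)
  back <- read_scan(p)
  expect_equal(back$counts, sc$counts)
  expect_equal(back$rows, 3)
  expect_equal(back$truth$log_amplitudes, tr$log_amplitudes,
               tolerance = 1e-9)
  expect_equal(back$truth$params$slope, tr$params$slope, tolerance = 1e-12)
})

test_that("run configuration layers defaults, file and overrides", {
  d <- withr::local_tempdir()
  f <- file.path(d, "cfg.yaml")
  yaml::write_yaml(list(elements = "Fe,Ca",
                        fit = list(iterations = 77)), f)
  rc <- run_config(f, overrides = list(seed = 42,
                                       fit = list(learning_rate = 0.5)))
  expect_equal(rc$elements, "Fe,Ca")     # from file
  expect_equal(rc$fit$iterations, 77)    # from file
  expect_equal(rc$fit$learning_rate, 0.5) # override wins
  expect_equal(rc$seed, 42)
  expect_equal(rc$n_channels, 2048L)      # default survives
  expect_error(run_config("no-such.yaml"), "no such config")
})

test_that("fit reports are written as JSON plus CSV curves", {
  d <- withr::local_tempdir()
  sp <- fixture_spectrum(seed = 62, elements = "Fe,Ca")
  f <- fit_spectrum(sp$counts, "Fe,Ca",
                    xrf_fit_config(n_iterations = 10, seed = 1))
  write_fit_report(f, d, "report")
  j <- jsonlite::read_json(file.path(d, "report.json"))
  expect_equal(j$r_squared, f$r_squared, tolerance = 1e-9)
  expect_named(j$amplitudes, c("Fe", "Ca"))
  curves <- readr::read_csv(file.path(d, "report_curves.csv"),
                            show_col_types = FALSE)
  expect_equal(nrow(curves), 2048)
  expect_true(all(c("observed", "model", "background", "residual") %in%
                    names(curves)))
})

test_that("cli simulate/fit/gradcheck produce their outputs", {
  d <- withr::local_tempdir()
  out1 <- file.path(d, "sim")
  st <- xrf_cli(c("simulate", "--seed", "7", "--elements", "Fe,Ca",
                  "--output", out1))
  expect_equal(st, 0L)
  expect_true(file.exists(file.path(out1, "spectrum.csv")))
  expect_true(file.exists(file.path(out1, "scan.csv")))
  expect_true(file.exists(file.path(out1, "scan.csv.manifest.json")))
  expect_true(file.exists(file.path(out1, "config.yaml")))

  # identical seeds give identical files
  out2 <- file.path(d, "sim2")
  xrf_cli(c("simulate", "--seed", "7", "--elements", "Fe,Ca",
            "--output", out2))
  expect_identical(readLines(file.path(out1, "spectrum.csv")),
                   readLines(file.path(out2, "spectrum.csv")))

  out3 <- file.path(d, "fit")
  st3 <- xrf_cli(c("fit", "--input", file.path(out1, "spectrum.csv"),
                   "--elements", "Fe,Ca", "--iters", "10",
                   "--seed", "1", "--output", out3))
  expect_equal(st3, 0L)
  expect_true(file.exists(file.path(out3, "fit.json")))

  # unknown flags exit non-zero with a usage message
  expect_message(st4 <- xrf_cli(c("fit", "--bogus")), "usage")
  expect_equal(st4, 1L)
  expect_message(st5 <- xrf_cli(character(0)), "usage")
  expect_equal(st5, 1L)
})

test_that("tidy, glance and autoplot work on fits and maps", {
  sp <- fixture_spectrum(seed = 63, elements = "Fe,Ca")
  f <- fit_spectrum(sp$counts, "Fe,Ca",
                    xrf_fit_config(n_iterations = 8, seed = 1))
  td <- tidy(f)
  expect_true(all(c("term", "type", "estimate") %in% names(td)))
  expect_true(all(c("Fe", "Ca") %in% td$term))
  gl <- glance(f)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$r_squared, f$r_squared)
  p1 <- autoplot(f)
  expect_s3_class(p1, "ggplot")

  tr <- sample_truth("Fe,Ca", seed = 64, noise = FALSE,
                     amp_range = c(4, 4.5))
  sc <- synth_scan(tr, rows = 3, cols = 3, n_channels = 256)
  amap <- map_amplitudes(sc, "Fe,Ca", tr$params)
  p2 <- autoplot(amap)
  expect_s3_class(p2, "ggplot")
})
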