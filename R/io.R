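#' Read and write single spectra as two-column CSV
#'
#' The on-disk format is `channel,counts` (header optional on read, written
#' on write). Counts must be non-negative and finite.
#'
#' @param path file path.
#' @return `read_spectrum()` returns a tibble (`channel`, `counts`).
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  df <- tryCatch(
    utils::read.csv(path, header = has_header,
                    col.names = c("channel", "counts")),
    error = function(e) {
      stop("malformed spectrum CSV '", path, "': ", conditionMessage(e))
    }
  )
  if (ncol(df) != 2L || !is.numeric(df$counts) || !is.numeric(df$channel)) {
    stop("malformed spectrum CSV '", path,
         "': expected two numeric columns channel,counts")
  }
  bad <- which(!is.finite(df$counts) | df$counts < 0)
  if (length(bad)) {
    stop("invalid counts in '", path, "' at line ",
         bad[1] + has_header, ": ", df$counts[bad[1]])
  }
  out <- tibble::as_tibble(df)
  class(out) <- c("xrf_spectrum", class(out))
  out
}

#' @rdname read_spectrum
#' @param x spectrum tibble (or numeric counts vector).
#' @export
write_spectrum <- function(x, path) {
  if (is.numeric(x)) {
    x <- tibble::tibble(channel = seq_along(x) - 1L, counts = x)
  }
  utils::write.csv(x[, c("channel", "counts")], path, row.names = FALSE)
  invisible(path)
}

#' Read and write raster scans as long CSV plus JSON manifest
#'
#' A scan cube (rows x cols x channels) is stored as a long CSV with
#' columns `row,col,channel,counts` next to a JSON manifest
#' (`<path>.manifest.json`) holding the dimensions and, for synthetic
#' scans, the serialized ground truth.
#'
#' @param path CSV file path.
#' @return `read_scan()` returns an `xrf_scan`.
#' @export
read_scan <- function(path) {
  mpath <- paste0(path, ".manifest.json")
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(mpath)) stop("missing scan manifest: ", mpath)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cube <- array(0, dim = c(man$rows, man$cols, man$n_channels))
  cube[cbind(df$row, df$col, df$channel + 1L)] <- df$counts
  truth <- if (!is.null(man$truth)) truth_from_manifest(man$truth) else NULL
  structure(list(counts = cube, truth = truth, fields = NULL,
                 rows = man$rows, cols = man$cols,
                 n_channels = man$n_channels), class = "xrf_scan")
}

#' @rdname read_scan
#' @param scan an `xrf_scan`.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "xrf_scan"))
  idx <- which(scan$counts != 0, arr.ind = TRUE)
  df <- tibble::tibble(
    row = idx[, 1], col = idx[, 2], channel = idx[, 3] - 1L,
    counts = scan$counts[idx]
  )
  readr::write_csv(df, path, progress = FALSE)
  man <- list(rows = scan$rows, cols = scan$cols,
              n_channels = scan$n_channels)
  if (!is.null(scan$truth)) man$truth <- truth_to_manifest(scan$truth)
  jsonlite::write_json(man, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

truth_to_manifest <- function(truth) {
  list(
    params = unclass(truth$params),
    log_amplitudes = as.list(truth$log_amplitudes),
    continuum = truth$continuum,
    noise = truth$noise,
    seed = truth$seed,
    elements = paste(truth$elements$spec, collapse = ",")
  )
}

truth_from_manifest <- function(m) {
  p <- m$params
  ie <- p$incident_energy
  p$incident_energy <- NULL
  structure(list(
    params = do.call(xrf_params, c(p, list(incident_energy = ie))),
    log_amplitudes = unlist(m$log_amplitudes),
    continuum = m$continuum,
    noise = m$noise,
    seed = m$seed,
    elements = parse_element_list(m$elements)
  ), class = "xrf_truth")
}

#' Write a fit report: JSON summary plus per-channel CSV
#'
#' @param fit an `xrf_fit`.
#' @param dir output directory (created if needed).
#' @param name basename for the report files.
#' @return the directory, invisibly.
#' @export
write_fit_report <- function(fit, dir, name = "fit") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summ <- list(
    r_squared = fit$r_squared,
    loss = fit$loss,
    best_iteration = fit$best_iteration,
    n_iterations = fit$config$n_iterations,
    params = unclass(fit$params),
    amplitudes = as.list(fit$amplitudes)
  )
  jsonlite::write_json(summ, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(fit$spectrum, file.path(dir, paste0(name, "_curves.csv")),
                   progress = FALSE)
  invisible(dir)
}
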