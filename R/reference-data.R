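# package-level cache for the bundled line table
the <- new.env(parent = emptyenv())

#' Bundled characteristic emission lines
#'
#' Returns the table of characteristic X-ray emission lines shipped with the
#' package: one row per line with its element, family (K/L/M), label, energy
#' (keV), relative intensity within the (element, family) group (normalized
#' to sum to 1), and the binding (absorption-edge) energy of the originating
#' shell. Lines of one family closer than 1 eV are merged on load, with their
#' intensities summed. A user-supplied table in the same CSV layout can
#' replace the bundled one via `path`.
#'
#' @param path optional path to a replacement CSV
#'   (`element,z,family,label,energy_kev,ratio,edge_kev`).
#' @return a tibble of emission lines.
#' @export
#' @examples
#' dplyr::filter(xray_lines(), element == "Fe")
xray_lines <- function(path = NULL) {
  if (is.null(path) && !is.null(the$lines)) {
    return(the$lines)
  }
  p <- path %||% system.file("extdata", "xray_lines.csv", package = "adxrf")
  raw <- utils::read.csv(p, comment.char = "#", stringsAsFactors = FALSE)
  tab <- tibble::as_tibble(raw)
  # merge lines of one family closer than 1 eV (e.g. unresolved Ka1/Ka2 in
  # light elements); keep the strongest label, sum intensities
  tab <- tab |>
    dplyr::group_by(.data$element, .data$family) |>
    dplyr::arrange(.data$energy_kev, .by_group = TRUE) |>
    dplyr::mutate(.grp = cumsum(c(1, diff(.data$energy_kev) >= 1e-3))) |>
    dplyr::group_by(.data$element, .data$z, .data$family, .data$.grp) |>
    dplyr::summarise(
      label = .data$label[which.max(.data$ratio)],
      energy_kev = .data$energy_kev[which.max(.data$ratio)],
      ratio = sum(.data$ratio),
      edge_kev = .data$edge_kev[which.max(.data$ratio)],
      .groups = "drop"
    ) |>
    dplyr::select(-".grp")
  # renormalize intensities exactly within each (element, family)
  tab <- tab |>
    dplyr::group_by(.data$element, .data$family) |>
    dplyr::mutate(ratio = .data$ratio / sum(.data$ratio)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$z, .data$family, dplyr::desc(.data$ratio))
  validate_line_table(tab)
  if (is.null(path)) the$lines <- tab
  tab
}

validate_line_table <- function(tab) {
  stopifnot(
    all(tab$energy_kev > 0),
    all(tab$ratio > 0), all(tab$ratio <= 1),
    all(tab$edge_kev > 0),
    all(tab$energy_kev < tab$edge_kev + 5)
  )
  sums <- tab |>
    dplyr::group_by(.data$element, .data$family) |>
    dplyr::summarise(s = sum(.data$ratio), .groups = "drop")
  if (any(abs(sums$s - 1) > 1e-8)) {
    stop("line-table intensity groups must each sum to 1")
  }
  invisible(tab)
}

#' Parse a comma-separated target-element list
#'
#' Element specifications name an element with an optional line-family
#' suffix: `"Fe"` means the K lines of iron (K is the default family),
#' `"Pt_L"` the L lines of platinum, `"Pb_M"` the M lines of lead. A pileup
#' (sum) peak of two K-line elements is written by joining two bare symbols,
#' e.g. `"Si_Si"`.
#'
#' @param text comma-separated specifications, e.g. `"Fe,Cu,Zn,Pt_L"`.
#' @return a tibble with columns `spec` (canonical label), `element`,
#'   `family`, `is_pileup`, and (for pileups) `partner`.
#' @export
#' @examples
#' parse_element_list("Fe,Cu,Pt_L")
parse_element_list <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(trimws(text)))
  tokens <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) stop("empty element list")
  known <- unique(xray_lines()$element)
  parse1 <- function(tok) {
    parts <- strsplit(tok, "_", fixed = TRUE)[[1]]
    if (length(parts) == 1L) {
      el <- parts[1]
      if (!el %in% known) stop("unknown element symbol: ", el)
      tibble::tibble(
        spec = el, element = el, family = "K",
        is_pileup = FALSE, partner = NA_character_
      )
    } else if (length(parts) == 2L && parts[2] %in% c("K", "L", "M")) {
      el <- parts[1]
      if (!el %in% known) stop("unknown element symbol: ", el)
      fam <- parts[2]
      if (!any(xray_lines()$element == el & xray_lines()$family == fam)) {
        stop("no bundled ", fam, " lines for element: ", el)
      }
      tibble::tibble(
        spec = paste(el, fam, sep = "_"), element = el, family = fam,
        is_pileup = FALSE, partner = NA_character_
      )
    } else if (length(parts) == 2L) {
      for (el in parts) {
        if (!el %in% known) stop("unknown element symbol: ", el)
      }
      tibble::tibble(
        spec = paste(parts, collapse = "_"), element = parts[1], family = "K",
        is_pileup = TRUE, partner = parts[2]
      )
    } else {
      stop("malformed element specification: ", tok)
    }
  }
  out <- dplyr::bind_rows(lapply(tokens, parse1))
  if (anyDuplicated(out$spec)) {
    stop("duplicate element specification: ",
         paste(out$spec[duplicated(out$spec)], collapse = ", "))
  }
  out
}

#' Emission lines of one element specification excitable at a given energy
#'
#' Looks up the bundled lines of `(element, family)` and keeps those whose
#' originating-shell binding energy lies below the incident beam energy (a
#' shell can only be ionized by photons above its edge). The result can be
#' empty.
#'
#' @param element chemical symbol.
#' @param family `"K"`, `"L"` or `"M"`.
#' @param incident_energy beam energy in keV.
#' @return tibble of lines (possibly zero rows).
#' @export
#' @examples
#' lines_for("Fe", "K", 10)  # Fe K edge 7.112 keV < 10 keV: excitable
#' lines_for("Pb", "L", 10)  # only lines with edges below 10 keV (none)
lines_for <- function(element, family = "K", incident_energy) {
  stopifnot(incident_energy > 0)
  tab <- xray_lines()
  tab[tab$element == element & tab$family == family &
        tab$edge_kev < incident_energy, ]
}

# detector escape constants, keV
.detector_materials <- list(
  Si = list(name = "Si", escape_line_energy = 1.7400, edge_energy = 1.8389)
)

#' Detector-material escape constants
#'
#' Escape peaks appear at a parent peak's energy minus the detector
#' material's own characteristic line energy (Si K-alpha for silicon
#' detectors), and only for parents above the material's absorption edge.
#'
#' @param material detector material name; currently `"Si"`.
#' @return a list with `name`, `escape_line_energy` (keV) and `edge_energy`
#'   (keV).
#' @export
escape_constants <- function(material = "Si") {
  m <- .detector_materials[[material]]
  if (is.null(m)) stop("unknown detector material: ", material)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
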