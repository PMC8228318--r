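#' Molar masses of the analytes and reference compounds
#'
#' Computed from the molecular formulas: CBD, Delta9-THC and Delta8-THC are
#' isomers (C21H30O2), CBN is C21H26O2, the external-standard components are
#' tetrachloronitrobenzene (TCNB, C6HCl4NO2) and ethylbenzene (EB, C8H10).
#'
#' @return Named numeric vector, g/mol.
#' @export
#' @examples
#' molar_masses()[["cbd"]]
molar_masses <- function() {
  c(
    cbd = 314.47, delta9_thc = 314.47, delta8_thc = 314.47, cbn = 310.44,
    cbg = 316.48, cbda = 358.48, thca = 358.48,
    tcnb = 260.89, eb = 106.17
  )
}

#' Build the cannabinoid signal library
#'
#' Returns the per-signal quantification table: for each analyte the chemical
#' shift, multiplicity, coupling constant, proton count, integration mode
#' (fixed-window trapezoidal integration or constrained line fit), the
#' matrix-specific integration/search window, and the published detection and
#' quantification limits used for censoring.
#'
#' Quantification signals are the three CBD multiplets at 3.88 ("CBD 1"),
#' 4.52 ("CBD 2") and 4.63 ppm ("CBD 3"), the Delta9-THC doublet at 6.15 ppm,
#' the Delta8-THC doublet at 6.12 ppm, and the CBN signals at 7.05, 7.13 and
#' 8.21 ppm (one proton each). CBD 2 is integrated for QC but excluded from
#' the aggregated CBD value because it is matrix-biased (`qc_only = TRUE`).
#' Non-quantified interferent rows (the CBD singlet at 5.56 ppm, the broad CBD
#' aromatic hump near 6.2 ppm, the Delta9-THC quintet at 6.33 ppm and the
#' CBG/CBDA/THCA/CBN signals between 6.2 and 6.45 ppm) are carried so the
#' simulator reproduces the crowded region on top of the hump.
#'
#' The line-fit signals overlapped by the CBD hump (CBD 4.63, Delta9-THC 6.15,
#' Delta8-THC 6.12) carry a wider search window; for MCT-oil matrices the
#' Delta8/Delta9 search windows are narrowed to prevent the two doublets from
#' being interchanged by the fit.
#'
#' @param matrix_kind `"hemp"` or `"MCT"` carrier-oil matrix.
#' @param window_half_ppm Half width of fixed integration windows (ppm).
#' @param search_half_ppm Half width of line-fit search windows, hemp (ppm).
#' @param mct_thc_half_ppm Narrowed Delta8/Delta9 search half width for MCT.
#' @return A tibble, one row per signal.
#' @export
#' @examples
#' dplyr::filter(signal_library("hemp"), quantified)
signal_library <- function(matrix_kind = c("hemp", "MCT"),
                           window_half_ppm = 0.04,
                           search_half_ppm = 0.06,
                           mct_thc_half_ppm = 0.02) {
  if (length(matrix_kind) != 1 || !matrix_kind %in% c("hemp", "MCT")) {
    matrix_kind <- tryCatch(match.arg(matrix_kind),
      error = function(e) {
        stop("unknown matrix_kind: must be \"hemp\" or \"MCT\"", call. = FALSE)
      }
    )
  }
  mm <- molar_masses()
  lib <- tibble::tribble(
    ~analyte, ~label, ~center_ppm, ~multiplicity, ~j_hz, ~n_protons, ~mode,
    ~quantified, ~qc_only, ~lod_mg_kg, ~loq_mg_kg,
    # quantification signals (Table of limits: published mg/kg values)
    "cbd", "CBD 1", 3.88, "m", 4.0, 1L, "window", TRUE, FALSE, 346, 1092,
    "cbd", "CBD 2", 4.52, "m", 1.5, 1L, "window", TRUE, TRUE, 134, 445,
    "cbd", "CBD 3", 4.63, "m", 1.5, 1L, "linefit", TRUE, FALSE, 307, 979,
    "delta9_thc", "D9-THC H-3'", 6.15, "d", 1.7, 1L, "linefit", TRUE, FALSE, 608, 1858,
    "delta8_thc", "D8-THC H-3'", 6.12, "d", 1.7, 1L, "linefit", TRUE, FALSE, 250, 816,
    "cbn", "CBN H-2", 7.05, "d", 8.0, 1L, "window", TRUE, FALSE, 517, 1604,
    "cbn", "CBN H-5", 7.13, "d", 8.0, 1L, "window", TRUE, FALSE, 623, 1897,
    "cbn", "CBN H-4", 8.21, "s", 0.0, 1L, "window", TRUE, FALSE, 504, 1568,
    # interferents: simulated but never quantified
    "cbd", "CBD H-2", 5.56, "s", 0.0, 1L, "none", FALSE, FALSE, NA, NA,
    "cbd", "CBD hump", 6.20, "hump", 0.0, 2L, "none", FALSE, FALSE, NA, NA,
    "delta9_thc", "D9-THC H-1", 6.33, "quint", 1.7, 1L, "none", FALSE, FALSE, NA, NA,
    "cbg", "CBG ArH", 6.24, "s", 0.0, 2L, "none", FALSE, FALSE, NA, NA,
    "cbda", "CBDA ArH", 6.23, "s", 0.0, 1L, "none", FALSE, FALSE, NA, NA,
    "thca", "THCA ArH", 6.228, "s", 0.0, 1L, "none", FALSE, FALSE, NA, NA,
    "cbn", "CBN H-8", 6.31, "d", 8.0, 1L, "none", FALSE, FALSE, NA, NA,
    "cbn", "CBN H-10", 6.41, "d", 8.0, 1L, "none", FALSE, FALSE, NA, NA
  )
  half <- ifelse(lib$mode == "linefit", search_half_ppm, window_half_ppm)
  if (matrix_kind == "MCT") {
    thc <- lib$analyte %in% c("delta9_thc", "delta8_thc") & lib$mode == "linefit"
    half[thc] <- mct_thc_half_ppm
  }
  lib$window_high <- lib$center_ppm + half
  lib$window_low <- lib$center_ppm - half
  lib$molar_mass <- unname(mm[lib$analyte])
  lib$matrix_kind <- matrix_kind
  lib
}

#' The TCNB/EB external quantification-reference (QR) standard
#'
#' The QR solution contains tetrachloronitrobenzene (4662 mg/L; aromatic
#' singlet integrated over 7.64-7.83 ppm, 1 proton) and ethylbenzene
#' (3506 mg/L; aromatic multiplet over 7.0162-7.2341 ppm, 3 protons) in
#' deuterochloroform. Both have long longitudinal relaxation times (T1 of
#' 10.9 s and 8.8 s), so at the short repetition time of the screening
#' experiment their signals are partially saturated; the empirical correction
#' factors kappa (1.30 for TCNB, 1.22 for EB) restore the fully relaxed
#' intensity in the ERETIC-factor equation.
#'
#' @return A tibble with one row per component.
#' @export
#' @examples
#' qr_standard()
qr_standard <- function() {
  tibble::tibble(
    component = c("tcnb", "eb"),
    mass_mg_l = c(4662, 3506),
    molar_mass = c(260.89, 106.17),
    n_protons = c(1L, 3L),
    range_high_ppm = c(7.83, 7.2341),
    range_low_ppm = c(7.64, 7.0162),
    center_ppm = c(7.735, 7.125),
    multiplicity = c("s", "t"),
    j_hz = c(0, 7.6),
    kappa = c(1.30, 1.22),
    t1_s = c(10.9, 8.8)
  )
}

check_qr <- function(qr) {
  need <- c(
    "component", "mass_mg_l", "molar_mass", "n_protons", "range_high_ppm",
    "range_low_ppm", "kappa", "t1_s"
  )
  missing <- setdiff(need, names(qr))
  if (length(missing)) {
    stop("QR standard is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(!is.finite(qr$kappa)) || any(!is.finite(qr$t1_s))) {
    stop("QR standard needs finite kappa and T1 for every component", call. = FALSE)
  }
  stopifnot(all(qr$kappa >= 1), all(qr$mass_mg_l > 0))
  invisible(qr)
}

#' Write / read a signal library as a YAML config
#'
#' The library is serialized as a human-editable list of signal entries
#' (keys: analyte, label, center_ppm, multiplicity, j_hz, n_protons, mode,
#' window, molar_mass, limits) so windows and couplings can be adjusted
#' without touching code. Shifts and windows are in ppm.
#'
#' @param library A tibble as returned by [signal_library()].
#' @param path File path.
#' @return `read_signal_library()` returns the tibble; `write_signal_library()`
#'   returns `path` invisibly.
#' @export
write_signal_library <- function(library, path) {
  entries <- purrr::pmap(library, function(...) {
    row <- list(...)
    row
  })
  yaml::write_yaml(list(matrix_kind = library$matrix_kind[1], signals = entries), path)
  invisible(path)
}

#' @rdname write_signal_library
#' @export
read_signal_library <- function(path) {
  cfg <- yaml::read_yaml(path)
  lib <- purrr::map_dfr(cfg$signals, function(row) {
    row$lod_mg_kg <- if (is.null(row$lod_mg_kg)) NA_real_ else row$lod_mg_kg
    row$loq_mg_kg <- if (is.null(row$loq_mg_kg)) NA_real_ else row$loq_mg_kg
    tibble::as_tibble(row)
  })
  lib$n_protons <- as.integer(lib$n_protons)
  lib
}
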