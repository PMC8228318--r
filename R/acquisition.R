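#' Acquisition parameters for a 1D 1H experiment
#'
#' Bundles the per-experiment metadata that travels with an FID from
#' acquisition (or simulation) to the final report. The defaults are the
#' parameters of the multiple-suppression quantification experiment:
#' TD = 131072 time-domain points zero-filled to SI = 262144, spectral width
#' 20.5617 ppm, 64 scans at receiver gain 16, a 6 s relaxation delay and
#' 0.30 Hz exponential line broadening, all at 300.0 K.
#'
#' `td` and `si` count *real* points (the Bruker convention: an FID holds
#' `td/2` complex samples), so the acquisition time satisfies
#' `aq_s ~ td / (2 * sw_ppm * sf_mhz)`.
#'
#' @param sf_mhz Spectrometer frequency in MHz. The nominal 400.0 MHz makes
#'   the published Hz/ppm band conversions exact (2156 Hz -> 5.39 ppm).
#' @param td Time-domain size in real points (must be even).
#' @param si Processed (zero-filled) size in real points, `si >= td`.
#' @param sw_ppm Spectral width in ppm.
#' @param o1_ppm Carrier position (centre of the spectral window) in ppm.
#' @param ns,ds Number of scans and dummy scans.
#' @param rg Receiver gain.
#' @param p1_us 90 degree pulse length in microseconds.
#' @param d1_s Relaxation delay in seconds.
#' @param aq_s Acquisition time in seconds; derived from `td`, `sw_ppm` and
#'   `sf_mhz` when `NULL`.
#' @param lb_hz Exponential line broadening in Hz.
#' @param temperature_k Sample temperature in K.
#'
#' @return An object of class `acq_params` (a named list).
#' @export
#' @examples
#' acq <- acq_params()
#' acq$aq_s
acq_params <- function(sf_mhz = 400.0,
                       td = 131072L,
                       si = 262144L,
                       sw_ppm = 20.5617,
                       o1_ppm = 6.0,
                       ns = 64L,
                       ds = 4L,
                       rg = 16,
                       p1_us = 8.0,
                       d1_s = 6,
                       aq_s = NULL,
                       lb_hz = 0.30,
                       temperature_k = 300.0) {
  td <- as.integer(td)
  si <- as.integer(si)
  stopifnot(
    sf_mhz > 0, td > 0, td %% 2L == 0L, si %% 2L == 0L,
    sw_ppm > 0, ns > 0, rg > 0, p1_us > 0, d1_s > 0, lb_hz >= 0,
    temperature_k > 0
  )
  if (si < td) {
    stop("`si` must be at least `td` (zero filling cannot truncate)", call. = FALSE)
  }
  sw_hz <- sw_ppm * sf_mhz
  aq_derived <- td / (2 * sw_hz)
  if (is.null(aq_s)) {
    aq_s <- aq_derived
  } else if (abs(aq_s - aq_derived) / aq_derived > 0.02) {
    stop(sprintf(
      "aq_s = %.6f s is inconsistent with td/(2 * sw_hz) = %.6f s",
      aq_s, aq_derived
    ), call. = FALSE)
  }
  structure(
    list(
      sf_mhz = sf_mhz, td = td, si = si, sw_ppm = sw_ppm, sw_hz = sw_hz,
      o1_ppm = o1_ppm, ns = as.integer(ns), ds = as.integer(ds), rg = rg,
      p1_us = p1_us, d1_s = d1_s, aq_s = aq_s, lb_hz = lb_hz,
      temperature_k = temperature_k
    ),
    class = "acq_params"
  )
}

#' @export
print.acq_params <- function(x, ...) {
  cat("<acq_params> ", x$sf_mhz, " MHz, TD ", x$td, " -> SI ", x$si,
    ", SW ", x$sw_ppm, " ppm, NS ", x$ns, ", RG ", x$rg,
    ", P1 ", x$p1_us, " us, D1 ", x$d1_s, " s, ", x$temperature_k, " K\n",
    sep = ""
  )
  invisible(x)
}

#' Default triglyceride suppression bands
#'
#' The seven frequency bands (relative to TMS at 0 ppm) in which the intense
#' lipid resonances of the oil matrix are selectively saturated during
#' acquisition so the receiver gain can be raised for the minor cannabinoid
#' signals: 347-357, 504-524, 640-650, 803-823, 919-929, 1102-1112 and
#' 2116-2156 Hz (0.87-0.89 up to 5.29-5.39 ppm at the nominal 400 MHz).
#'
#' @param residual_fraction Fraction of the in-band signal that survives
#'   suppression, in `[0, 1]`.
#' @return A tibble with columns `lo_hz`, `hi_hz`, `residual_fraction`.
#' @export
#' @examples
#' suppression_bands()
suppression_bands <- function(residual_fraction = 0.01) {
  stopifnot(residual_fraction >= 0, residual_fraction <= 1)
  tibble::tibble(
    lo_hz = c(347, 504, 640, 803, 919, 1102, 2116),
    hi_hz = c(357, 524, 650, 823, 929, 1112, 2156),
    residual_fraction = residual_fraction
  )
}

#' Convert a frequency offset in Hz to ppm (and back)
#'
#' Offsets are relative to the 0 ppm reference, so the conversion is a plain
#' division by the spectrometer frequency: 2156 Hz is 5.39 ppm at 400 MHz.
#'
#' @param value_hz,value_ppm Numeric vector of offsets.
#' @param sf_mhz Spectrometer frequency in MHz.
#' @return Numeric vector in the target unit.
#' @export
#' @examples
#' hz_to_ppm(2156, 400) # 5.39
hz_to_ppm <- function(value_hz, sf_mhz) {
  stopifnot(sf_mhz > 0)
  value_hz / sf_mhz
}

#' @rdname hz_to_ppm
#' @export
ppm_to_hz <- function(value_ppm, sf_mhz) {
  stopifnot(sf_mhz > 0)
  value_ppm * sf_mhz
}
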