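#' Construct an FID object
#'
#' An FID is the complex time-domain signal together with its acquisition
#' metadata. `data` holds `td/2` complex samples (TD counts real points).
#'
#' @param data Complex vector of time-domain samples.
#' @param acq An [acq_params()] object.
#' @param provenance List of processing steps already applied.
#' @return An object of class `nmr_fid`.
#' @export
new_fid <- function(data, acq, provenance = list()) {
  stopifnot(is.complex(data), inherits(acq, "acq_params"))
  structure(list(data = data, acq = acq, provenance = provenance),
    class = "nmr_fid"
  )
}

#' @export
print.nmr_fid <- function(x, ...) {
  cat("<nmr_fid> ", length(x$data), " complex points (",
    2L * length(x$data), " real), dwell ", signif(1 / x$acq$sw_hz, 4), " s",
    if (length(x$provenance)) paste0(
      ", steps: ",
      paste(vapply(x$provenance, `[[`, "", "step"), collapse = " > ")
    ),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Construct a 1D spectrum object
#'
#' Frequency-domain counterpart of an FID: complex intensities on a strictly
#' decreasing ppm axis (the NMR plotting convention, high field to the right),
#' plus the acquisition metadata and a provenance trail of applied processing
#' steps and their parameters.
#'
#' @param real,imag Numeric vectors of equal length.
#' @param ppm Strictly decreasing ppm axis of the same length.
#' @param acq An [acq_params()] object.
#' @param provenance List of processing steps applied so far.
#' @param flags Character vector of quality flags.
#' @return An object of class `nmr_spectrum`.
#' @export
new_spectrum <- function(real, imag, ppm, acq, provenance = list(),
                         flags = character()) {
  stopifnot(
    length(real) == length(imag), length(real) == length(ppm),
    inherits(acq, "acq_params"), all(diff(ppm) < 0)
  )
  structure(
    list(
      real = real, imag = imag, ppm = ppm, acq = acq,
      provenance = provenance, flags = flags
    ),
    class = "nmr_spectrum"
  )
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat("<nmr_spectrum> ", length(x$real), " points, ",
    signif(max(x$ppm), 6), " .. ", signif(min(x$ppm), 6), " ppm @ ",
    x$acq$sf_mhz, " MHz",
    if (length(x$flags)) paste0(" [flags: ", paste(x$flags, collapse = ", "), "]"),
    "\n",
    sep = ""
  )
  if (length(x$provenance)) {
    cat("  steps: ", paste(vapply(x$provenance, `[[`, "", "step"),
      collapse = " > "
    ), "\n", sep = "")
  }
  invisible(x)
}

#' Convert a spectrum to a tibble
#'
#' @param x An `nmr_spectrum`.
#' @param ... Unused.
#' @return A tibble with columns `ppm`, `real`, `imag`.
#' @method as_tibble nmr_spectrum
#' @export
as_tibble.nmr_spectrum <- function(x, ...) {
  tibble::tibble(ppm = x$ppm, real = x$real, imag = x$imag)
}

# indices of axis points inside a (high_ppm, low_ppm) closed window
spec_window_idx <- function(spec, high_ppm, low_ppm) {
  if (high_ppm < low_ppm) {
    tmp <- high_ppm
    high_ppm <- low_ppm
    low_ppm <- tmp
  }
  if (high_ppm > max(spec$ppm) || low_ppm < min(spec$ppm)) {
    stop(sprintf(
      "window [%.3f, %.3f] ppm lies outside the spectral axis [%.3f, %.3f]",
      low_ppm, high_ppm, min(spec$ppm), max(spec$ppm)
    ), call. = FALSE)
  }
  which(spec$ppm <= high_ppm & spec$ppm >= low_ppm)
}

# formals are dot-prefixed so `...` entries (e.g. `p`) cannot partially
# match them
add_step <- function(.prov, .step, ...) {
  c(.prov, list(c(list(step = .step), list(...))))
}

#' Plot a 1D spectrum
#'
#' @param object An `nmr_spectrum`.
#' @param xlim Optional `c(high_ppm, low_ppm)` zoom range.
#' @param ... Unused.
#' @return A ggplot object (ppm axis reversed, as spectra are drawn).
#' @method autoplot nmr_spectrum
#' @export
autoplot.nmr_spectrum <- function(object, xlim = NULL, ...) {
  df <- tibble::tibble(ppm = object$ppm, intensity = object$real)
  if (!is.null(xlim)) {
    df <- dplyr::filter(df, .data$ppm <= max(xlim), .data$ppm >= min(xlim))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ppm, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
}
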