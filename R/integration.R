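# Per-signal area extraction: fixed-window trapezoidal integration for
# well-separated signals, and constrained doublet line fitting on a local
# linear baseline for the signals overlapped by the broad CBD aromatic hump.

trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Integrate a signal window
#'
#' Trapezoidal integral of the absorption (real) part over the signal's
#' `(high_ppm, low_ppm)` window. The integration variable is the frequency in
#' Hz, so areas are directly comparable between experiments at the same
#' spectrometer frequency (the unit the PULCON relation assumes).
#'
#' With `local_baseline = TRUE` a per-signal linear baseline estimated from
#' the flanking strips just outside the window is subtracted first: the oil
#' matrix leaves slowly varying offsets under some windows that a global
#' baseline correction cannot fully remove, and the per-signal correction is
#' what keeps a blank matrix integrating to (censorable) noise.
#'
#' @param spec A processed [new_spectrum()] object.
#' @param signal One row of [signal_library()] (or anything with
#'   `window_high`/`window_low`), or `NULL` when `high_ppm`/`low_ppm` given.
#' @param high_ppm,low_ppm Explicit window bounds (override `signal`).
#' @param local_baseline Subtract the local linear baseline from the flanks.
#' @param flank_frac Width of each flanking strip as a fraction of the
#'   window width.
#' @return The area (arbitrary units, Hz-scaled).
#' @export
integrate_window <- function(spec, signal = NULL, high_ppm = NULL, low_ppm = NULL,
                             local_baseline = TRUE, flank_frac = 0.35) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  if (is.null(high_ppm)) {
    high_ppm <- signal$window_high
    low_ppm <- signal$window_low
  }
  if (high_ppm < low_ppm) {
    tmp <- high_ppm
    high_ppm <- low_ppm
    low_ppm <- tmp
  }
  idx <- spec_window_idx(spec, high_ppm, low_ppm)
  hz <- spec$ppm[idx] * spec$acq$sf_mhz
  y <- spec$real[idx]
  if (local_baseline) {
    w <- (high_ppm - low_ppm) * flank_frac
    flank <- function(hi, lo) {
      ids <- tryCatch(spec_window_idx(spec, hi, lo), error = function(e) integer())
      if (length(ids) < 3) {
        return(NULL)
      }
      c(level = stats::median(spec$real[ids]), at = mean(spec$ppm[ids]) * spec$acq$sf_mhz)
    }
    up <- flank(high_ppm + w, high_ppm)
    dn <- flank(low_ppm, low_ppm - w)
    if (!is.null(up) && !is.null(dn)) {
      slope <- (up["level"] - dn["level"]) / (up["at"] - dn["at"])
      y <- y - (dn["level"] + slope * (hz - dn["at"]))
    } else if (!is.null(up) || !is.null(dn)) {
      lvl <- if (is.null(up)) dn["level"] else up["level"]
      y <- y - lvl
    }
  }
  -trapz(hz, y) # axis is descending, flip the sign
}

unit_lorentzian <- function(x, center, fwhm) {
  (2 / (pi * fwhm)) / (1 + (2 * (x - center) / fwhm)^2)
}

#' Fit a multiplet on a local baseline
#'
#' Models the signal as equal-width Lorentzians at the positions and relative
#' intensities of its coupling pattern (for a doublet: two equal-area lines
#' separated by `j_hz`), riding on a local low-order polynomial baseline, and
#' returns the multiplet area with the baseline excluded. The centre is free
#' within the search window. This is the overlap-robust integration used for
#' the signals sitting on the broad CBD hump (CBD 4.63, Delta9-THC 6.15,
#' Delta8-THC 6.12): the local baseline (quadratic by default, so the
#' curvature of the hump under the narrow multiplet is absorbed) separates
#' the overlap. Non-convergence, a centre pinned at the window edge, a
#' negative amplitude, or a fitted peak indistinguishable from the local
#' residual noise all yield `converged = FALSE` and area 0.
#'
#' @param spec A processed [new_spectrum()] object.
#' @param signal One row of [signal_library()]; `j_hz` = 0 fits a singlet.
#' @param search_window Optional `c(high_ppm, low_ppm)` override.
#' @param height_snr_min Minimum fitted peak height over the point-noise
#'   estimate for the fit to count as a detection.
#' @param baseline_order Polynomial order of the local baseline (0, 1 or 2).
#' @param fit_half_hz After the multiplet is located inside the search
#'   window, the least-squares fit itself uses only points within this many
#'   Hz of the located centre (a local fit keeps the polynomial baseline a
#'   good model of the hump underneath).
#' @param fwhm_max_hz,fwhm_min_hz Bounds of the fitted line width; a fit
#'   pinned at either bound has locked onto a broad background feature (or a
#'   single-point residual artifact) and is rejected.
#' @return A one-row tibble (class fields of a fit result): `area`,
#'   `center_ppm`, `fwhm_hz`, `baseline_b0`, `baseline_b1`, `converged`,
#'   `residual_rms`, `flags`.
#' @export
fit_doublet_on_baseline <- function(spec, signal, search_window = NULL,
                                    height_snr_min = 4, baseline_order = 2,
                                    fit_half_hz = 16, fwhm_max_hz = 8,
                                    fwhm_min_hz = 0.5) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  if (is.null(search_window)) {
    search_window <- c(signal$window_high, signal$window_low)
  }
  hi <- max(search_window)
  lo <- min(search_window)
  idx <- spec_window_idx(spec, hi, lo)
  sf <- spec$acq$sf_mhz
  x <- spec$ppm[idx] * sf # Hz
  y <- spec$real[idx]
  j <- signal$j_hz
  mult <- if (!is.null(signal$multiplicity)) signal$multiplicity else "d"
  if (mult == "hump") mult <- "s"
  pat <- multiplet_pattern(mult, j)
  no_fit <- function(flag) {
    tibble::tibble(
      label = signal$label, area = 0, center_ppm = NA_real_,
      fwhm_hz = NA_real_, baseline_b0 = NA_real_, baseline_b1 = NA_real_,
      converged = FALSE, residual_rms = NA_real_, flags = flag
    )
  }
  if (length(x) < 8) {
    return(no_fit("window_too_small"))
  }
  # starting values: the narrow multiplet is located on a running-median
  # high-passed copy of the window, so a strong sloping hump underneath does
  # not drag the start to the window edge
  dx <- abs(stats::median(diff(x)))
  k_med <- as.integer(round(10 / dx)) # ~10 Hz median window
  if (k_med %% 2L == 0L) k_med <- k_med + 1L
  k_med <- max(3L, min(k_med, length(y) - 2L + (length(y) %% 2L)))
  y_hp <- y - stats::runmed(y, k_med)
  c0 <- x[which.max(y_hp)]
  hp <- max(y_hp)
  fw0 <- 1.5
  # local fit region around the located centre
  local <- abs(x - c0) <= max(fit_half_hz, 4 * dx)
  if (sum(local) >= 8) {
    x <- x[local]
    y <- y[local]
  }
  base0 <- stats::median(y)
  a0 <- max(hp * pi * fw0, .Machine$double.eps)
  dat <- data.frame(x = x, y = y)
  xm <- mean(x)
  xs <- max(x) - xm
  shape <- function(x, c, fw) {
    out <- 0
    for (i in seq_along(pat$offset)) {
      out <- out + pat$weight[i] * unit_lorentzian(x, c + pat$offset[i], fw)
    }
    out
  }
  baseline_order <- max(0L, min(2L, as.integer(baseline_order)))
  model <- function(A, c, fw, b0, b1 = 0, b2 = 0, x) {
    u <- (x - xm) / xs
    A * shape(x, c, fw) + b0 + b1 * u + b2 * u^2
  }
  forms <- list(
    y ~ model(A, c, fw, b0, x = x),
    y ~ model(A, c, fw, b0, b1, x = x),
    y ~ model(A, c, fw, b0, b1, b2, x = x)
  )
  start <- list(A = a0, c = c0, fw = fw0, b0 = base0, b1 = 0, b2 = 0)
  np <- 4L + baseline_order
  fit <- tryCatch(
    minpack.lm::nlsLM(
      forms[[baseline_order + 1L]],
      data = dat,
      start = start[seq_len(np)],
      lower = c(0, min(x), fwhm_min_hz, rep(-Inf, np - 3L)),
      upper = c(Inf, max(x), fwhm_max_hz, rep(Inf, np - 3L)),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(no_fit("fit_failed"))
  }
  p <- stats::coef(fit)
  res <- stats::resid(fit)
  resid_rms <- sqrt(mean(res^2))
  # point-noise estimate from first differences: insensitive to the smooth
  # residual a low-order baseline leaves under a strong hump
  noise_pt <- stats::sd(diff(res)) / sqrt(2)
  height <- p[["A"]] * max(shape(p[["c"]] + c(0, pat$offset), p[["c"]], p[["fw"]]))
  edge_tol <- 0.002 * sf # 0.002 ppm in Hz
  flags <- character()
  converged <- TRUE
  if (p[["c"]] <= min(x) + edge_tol || p[["c"]] >= max(x) - edge_tol) {
    converged <- FALSE
    flags <- c(flags, "center_at_edge")
  }
  if (p[["A"]] <= 0) {
    converged <- FALSE
    flags <- c(flags, "non_positive_area")
  }
  if (p[["fw"]] >= 0.99 * fwhm_max_hz || p[["fw"]] <= 1.01 * fwhm_min_hz) {
    converged <- FALSE
    flags <- c(flags, "width_at_bound")
  }
  if (is.finite(noise_pt) && noise_pt > 0 && height < height_snr_min * noise_pt) {
    converged <- FALSE
    flags <- c(flags, "below_noise")
  }
  tibble::tibble(
    label = signal$label,
    area = if (converged) unname(p[["A"]]) else 0,
    center_ppm = unname(p[["c"]]) / sf,
    fwhm_hz = unname(p[["fw"]]),
    baseline_b0 = unname(p[["b0"]]),
    baseline_b1 = if ("b1" %in% names(p)) unname(p[["b1"]]) else 0,
    converged = converged,
    residual_rms = resid_rms,
    flags = if (length(flags)) paste(flags, collapse = ";") else ""
  )
}


#' Find the candidate THC doublets near 6.1-6.2 ppm
#'
#' Sequential peeling over the union of the (drift-corrected) Delta9 and
#' Delta8 search windows: the strongest doublet is fitted first, its fitted
#' multiplet (baseline excluded) is subtracted from the spectrum, and a
#' second fit runs on the residual. This yields up to two distinct candidate
#' doublets even when one is much stronger than the other, which the
#' assignment step ([assign_delta_thc()]) then maps to Delta9/Delta8.
#'
#' @param spec A processed [new_spectrum()] object.
#' @param library A [signal_library()] tibble (supplies windows and J).
#' @param drift_offset_ppm Drift correction from [estimate_hump_offset()].
#' @return A tibble of up to two fit-result rows.
#' @export
find_thc_doublets <- function(spec, library = signal_library("hemp"),
                              drift_offset_ppm = 0) {
  thc <- library[library$analyte %in% c("delta9_thc", "delta8_thc") &
    library$mode == "linefit", ]
  if (!nrow(thc)) {
    return(tibble::tibble())
  }
  hi <- max(thc$window_high) + drift_offset_ppm
  lo <- min(thc$window_low) + drift_offset_ppm
  sig <- thc[which.max(thc$center_ppm), ] # doublet template (J, label unused)
  fit1 <- fit_doublet_on_baseline(spec, sig, search_window = c(hi, lo))
  if (!fit1$converged) {
    return(fit1)
  }
  # subtract the fitted multiplet and fit the residual
  peeled <- spec
  sf <- spec$acq$sf_mhz
  idx <- spec_window_idx(spec, hi + 0.05, lo - 0.05)
  x_hz <- spec$ppm[idx] * sf
  pat <- multiplet_pattern(sig$multiplicity, sig$j_hz)
  mdl <- 0
  for (i in seq_along(pat$offset)) {
    mdl <- mdl + pat$weight[i] *
      unit_lorentzian(x_hz, fit1$center_ppm * sf + pat$offset[i], fit1$fwhm_hz)
  }
  peeled$real[idx] <- peeled$real[idx] - fit1$area * mdl
  fit2 <- fit_doublet_on_baseline(peeled, sig, search_window = c(hi, lo))
  dplyr::bind_rows(fit1, fit2)
}

#' Estimate the CBD-hump drift offset
#'
#' The Delta8/Delta9-THC doublets and the broad CBD aromatic hump drift
#' together as a function of the CBD content. The hump centre is found by
#' wide moving-average smoothing of the 5.9-6.5 ppm region; its offset from
#' the nominal 6.2 ppm estimates the drift and is used to anchor the THC
#' target positions before assignment. Returns 0 when no hump is evident.
#'
#' @param spec A processed [new_spectrum()] object.
#' @param nominal_ppm Nominal hump position.
#' @param smooth_hz Width of the smoothing kernel in Hz.
#' @return Offset in ppm (observed - nominal).
#' @export
estimate_hump_offset <- function(spec, nominal_ppm = 6.20, smooth_hz = 20) {
  idx <- tryCatch(spec_window_idx(spec, 6.5, 5.9), error = function(e) integer())
  if (length(idx) < 16) {
    return(0)
  }
  y <- spec$real[idx]
  dppm <- abs(stats::median(diff(spec$ppm[idx])))
  bins_per_hz <- 1 / (spec$acq$sf_mhz * dppm)
  # wide running median first: removes the narrow multiplets (including the
  # Delta9 + Delta8 doublet pair, which together span ~15 Hz) while the
  # ~40 Hz hump passes through, so a sample without CBD cannot fake a hump
  # out of its sharp lines
  k_med <- as.integer(round(40 * bins_per_hz))
  if (k_med %% 2L == 0L) k_med <- k_med + 1L
  k_med <- max(3L, min(k_med, length(y) - 2L + (length(y) %% 2L)))
  y_med <- stats::runmed(y, k_med)
  k <- max(3L, as.integer(round(smooth_hz * bins_per_hz)))
  if (k %% 2L == 0L) k <- k + 1L
  ys <- stats::filter(y_med, rep(1 / k, k), sides = 2)
  ok <- !is.na(ys)
  if (!any(ok)) {
    return(0)
  }
  floor_level <- stats::median(abs(spec$real))
  if (max(ys[ok]) < 20 * floor_level) {
    return(0)
  }
  # intensity centroid of the top of the smoothed hump; a feature much
  # narrower than the hump (a surviving multiplet remnant) is not a hump
  ppm_ok <- spec$ppm[idx][ok]
  ys_ok <- as.numeric(ys[ok])
  top <- ys_ok >= 0.6 * max(ys_ok)
  top_width_hz <- sum(top) * dppm * spec$acq$sf_mhz
  if (top_width_hz < 15) {
    return(0)
  }
  sum(ppm_ok[top] * ys_ok[top]) / sum(ys_ok[top]) - nominal_ppm
}

#' Assign candidate doublet fits to Delta9- and Delta8-THC
#'
#' Each converged candidate fit near 6.1-6.2 ppm is assigned to the Delta9
#' (target 6.15 ppm) or Delta8 (target 6.12 ppm) doublet by minimal distance
#' between the fitted centre and the drift-corrected target, within
#' matrix-specific assignment windows. Duplicate fits of the same underlying
#' peak are collapsed first. When two fits land in the same target window the
#' higher-shift fit goes to Delta9 (deterministic tie-break); an unassigned
#' target reports area 0 with a flag; fits equidistant from both targets
#' beyond tolerance are flagged ambiguous.
#'
#' @param fits A tibble of fit results ([fit_doublet_on_baseline()] rows).
#' @param matrix_kind `"hemp"` or `"MCT"`.
#' @param drift_offset_ppm Drift correction added to both targets (e.g. from
#'   [estimate_hump_offset()]).
#' @param ambig_tol_ppm Distance difference below which a fit sitting between
#'   the two targets is flagged ambiguous rather than assigned.
#' @return A tibble with one row per target (`delta9_thc`, `delta8_thc`):
#'   `area`, `center_ppm`, `converged`, `flags`.
#' @export
assign_delta_thc <- function(fits, matrix_kind = c("hemp", "MCT"),
                             drift_offset_ppm = 0, ambig_tol_ppm = 1e-4) {
  matrix_kind <- match.arg(matrix_kind)
  half <- if (matrix_kind == "MCT") 0.02 else 0.03
  targets <- c(delta9_thc = 6.15, delta8_thc = 6.12) + drift_offset_ppm
  out <- tibble::tibble(
    analyte = names(targets), target_ppm = unname(targets),
    area = 0, center_ppm = NA_real_, converged = FALSE, flags = "unassigned"
  )
  cand <- fits[fits$converged & fits$area > 0 & is.finite(fits$center_ppm), ]
  if (!nrow(cand)) {
    return(out)
  }
  # collapse duplicate captures of the same peak (keep the larger area)
  cand <- cand[order(-cand$area), ]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    dup <- keep & seq_len(nrow(cand)) > i &
      abs(cand$center_ppm - cand$center_ppm[i]) < 0.004
    keep[dup] <- FALSE
  }
  cand <- cand[keep, ]
  d9 <- abs(cand$center_ppm - targets["delta9_thc"])
  d8 <- abs(cand$center_ppm - targets["delta8_thc"])
  ambiguous <- abs(d9 - d8) < ambig_tol_ppm
  fill <- function(target, sel) {
    row <- which(out$analyte == target)
    out$area[row] <<- cand$area[sel]
    out$center_ppm[row] <<- cand$center_ppm[sel]
    out$converged[row] <<- TRUE
    out$flags[row] <<- ""
  }
  if (nrow(cand) == 1) {
    # single candidate: nearest target, unless exactly between the two
    if (!ambiguous[1]) {
      target <- if (d9[1] <= d8[1]) "delta9_thc" else "delta8_thc"
      if (min(d9[1], d8[1]) <= half) fill(target, 1L)
    }
  } else {
    # two or more candidates: keep the two strongest, then the higher-shift
    # one is Delta9 and the lower Delta8 (deterministic, order-independent),
    # each only if it falls inside its own assignment window
    keep2 <- order(-cand$area)[1:2]
    hi_c <- keep2[which.max(cand$center_ppm[keep2])]
    lo_c <- keep2[which.min(cand$center_ppm[keep2])]
    if (abs(cand$center_ppm[hi_c] - targets["delta9_thc"]) <= half) {
      fill("delta9_thc", hi_c)
    }
    if (abs(cand$center_ppm[lo_c] - targets["delta8_thc"]) <= half) {
      fill("delta8_thc", lo_c)
    }
  }
  if (any(ambiguous)) {
    out$flags <- vapply(out$flags, function(f) {
      paste(c(if (nzchar(f)) f, "ambiguous_candidate"), collapse = ";")
    }, "")
  }
  out
}

#' Signal-to-noise ratio of a signal window
#'
#' Peak maximum of the signal window over twice the standard deviation of a
#' signal-free noise window; values below the qNMR quality guideline of 250
#' are flagged. The two windows must be disjoint.
#'
#' @param spec A processed [new_spectrum()] object.
#' @param signal_window,noise_window `(high_ppm, low_ppm)` pairs.
#' @param snr_min Quality threshold (default 250).
#' @return A list with `snr`, `flag` (`""`, `"below_250"` or `"degenerate"`).
#' @export
estimate_snr <- function(spec, signal_window, noise_window, snr_min = 250) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  s_hi <- max(signal_window)
  s_lo <- min(signal_window)
  n_hi <- max(noise_window)
  n_lo <- min(noise_window)
  if (s_hi > n_lo && n_hi > s_lo) {
    stop("signal and noise windows must be disjoint", call. = FALSE)
  }
  sig <- spec$real[spec_window_idx(spec, s_hi, s_lo)]
  noi <- spec$real[spec_window_idx(spec, n_hi, n_lo)]
  noise_sd <- stats::sd(noi)
  if (!is.finite(noise_sd) || noise_sd == 0) {
    return(list(snr = Inf, flag = "degenerate"))
  }
  snr <- max(sig) / (2 * noise_sd)
  list(snr = snr, flag = if (snr < snr_min) "below_250" else "")
}
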