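# FID -> spectrum processing chain: exponential apodization, zero filling,
# Fourier transform, automatic phase correction, asymmetric-least-squares
# baseline correction and TMS referencing, with a provenance trail.

#' Zero-fill an FID
#'
#' Appends complex zeros so the processed spectrum holds `si` real points
#' (`si/2` complex samples). The original samples are bit-preserved.
#'
#' @param fid An [new_fid()] object.
#' @param si Target size in real points, `si >= td`.
#' @return The extended FID.
#' @export
zero_fill <- function(fid, si = fid$acq$si) {
  stopifnot(inherits(fid, "nmr_fid"))
  si <- as.integer(si)
  n_target <- si %/% 2L
  n <- length(fid$data)
  if (n_target < n) {
    stop("si smaller than the recorded time domain: zero filling cannot truncate",
      call. = FALSE
    )
  }
  x <- c(fid$data, complex(real = numeric(n_target - n), imaginary = numeric(n_target - n)))
  acq <- fid$acq
  acq$si <- si
  new_fid(x, acq, add_step(fid$provenance, "zero_fill", si = si))
}

#' Exponential apodization
#'
#' Multiplies sample `k` by `exp(-pi * lb_hz * t_k)` (`t_k = k * dwell`,
#' first point unchanged), which broadens every line by `lb_hz` and trades
#' resolution for signal-to-noise.
#'
#' @param fid An [new_fid()] object.
#' @param lb_hz Line broadening in Hz (>= 0; 0 is the identity).
#' @return The apodized FID.
#' @export
apodize_exponential <- function(fid, lb_hz = fid$acq$lb_hz) {
  stopifnot(inherits(fid, "nmr_fid"))
  if (lb_hz < 0) stop("line broadening must be non-negative", call. = FALSE)
  if (lb_hz == 0) {
    return(fid)
  }
  t <- (seq_along(fid$data) - 1) / fid$acq$sw_hz
  new_fid(
    fid$data * exp(-pi * lb_hz * t), fid$acq,
    add_step(fid$provenance, "apodize", lb_hz = lb_hz)
  )
}

#' Fourier transform an FID into a spectrum
#'
#' Complex FFT with the frequency axis mapped to ppm (descending, anchored to
#' the carrier position). The first FID point is halved by default, the
#' standard discrete-FT correction that removes the constant baseline offset.
#'
#' @param fid An [new_fid()] object (non-empty).
#' @param first_point_half Halve the first time-domain sample.
#' @return An [new_spectrum()] object.
#' @export
fourier_transform <- function(fid, first_point_half = TRUE) {
  stopifnot(inherits(fid, "nmr_fid"))
  n <- length(fid$data)
  if (n == 0) stop("empty FID", call. = FALSE)
  x <- fid$data
  if (first_point_half) x[1] <- x[1] * 0.5
  X <- stats::fft(x)
  # reorder so the axis runs from +sw/2 down to -sw/2 around the carrier
  half <- n %/% 2L
  X <- c(X[(half + 1L):n], X[1:half]) # fftshift: f in [-sw/2, sw/2)
  acq <- fid$acq
  df <- acq$sw_hz / n
  f_hz <- (seq_len(n) - 1L - half) * df
  ppm <- acq$o1_ppm + f_hz / acq$sf_mhz
  ord <- rev(seq_len(n)) # descending ppm
  new_spectrum(Re(X)[ord], Im(X)[ord], ppm[ord], acq,
    provenance = add_step(fid$provenance, "fourier_transform", n = n)
  )
}

# rotate a complex spectrum by zeroth/first order phase (degrees);
# the first-order term is linear across the axis around a pivot index
phase_rotate <- function(real, imag, phi0_deg, phi1_deg, pivot_frac = 0.5) {
  n <- length(real)
  frac <- (seq_len(n) - 1) / (n - 1) - pivot_frac
  phi <- (phi0_deg + phi1_deg * frac) * pi / 180
  s <- complex(real = real, imaginary = imag) * exp(complex(imaginary = phi))
  list(real = Re(s), imag = Im(s))
}

#' Apply a manual phase correction
#'
#' @param spec An [new_spectrum()] object.
#' @param phi0_deg,phi1_deg Zeroth- and first-order phase in degrees; the
#'   first-order ramp pivots at the centre of the axis.
#' @return The rotated spectrum.
#' @export
phase_correct <- function(spec, phi0_deg, phi1_deg = 0) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  r <- phase_rotate(spec$real, spec$imag, phi0_deg, phi1_deg)
  new_spectrum(r$real, r$imag, spec$ppm, spec$acq,
    add_step(spec$provenance, "phase", phi0_deg = phi0_deg, phi1_deg = phi1_deg),
    flags = spec$flags
  )
}

#' Automatic phase correction
#'
#' Two-stage automatic phasing. First, the phase error is read directly off
#' the peaks: at the centre of a Lorentzian line the complex intensity has
#' exactly the phase error of the spectrum, so the arguments of the detected
#' peak maxima are fitted (intensity-weighted, phase-unwrapped) against axis
#' position, giving closed-form zeroth- and first-order estimates. Second,
#' the estimate is refined by Nelder-Mead minimization of a penalized
#' objective (negative-intensity penalty plus the entropy of the derivative
#' of the real part) evaluated on the strongest spectral regions. Applied
#' angles are recorded in the provenance; non-convergence flags the result
#' rather than failing silently.
#'
#' @param spec An [new_spectrum()] object.
#' @param peak_snr_min Peak detection threshold as a multiple of the median
#'   absolute magnitude.
#' @param refine Run the Nelder-Mead refinement stage.
#' @return The phased spectrum, with `phi0_deg`/`phi1_deg` in provenance.
#' @export
auto_phase <- function(spec, peak_snr_min = 10, refine = TRUE) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  mag <- sqrt(spec$real^2 + spec$imag^2)
  thr <- peak_snr_min * stats::median(mag[mag > 0])
  n <- length(mag)
  is_peak <- c(FALSE, mag[2:(n - 1)] > mag[1:(n - 2)] &
    mag[2:(n - 1)] >= mag[3:n], FALSE) & mag > thr
  idx <- which(is_peak)
  flags <- spec$flags
  if (!length(idx)) {
    flags <- c(flags, "auto_phase_no_peaks")
    out <- spec
    out$flags <- flags
    out$provenance <- add_step(out$provenance, "auto_phase",
      phi0_deg = 0, phi1_deg = 0, converged = FALSE
    )
    return(out)
  }
  ang <- atan2(spec$imag[idx], spec$real[idx]) # phase error at each peak
  w <- mag[idx]
  frac <- (idx - 1) / (n - 1) - 0.5
  # unwrap against the strongest peak
  ref <- ang[which.max(w)]
  ang <- ref + atan2(sin(ang - ref), cos(ang - ref))
  if (length(idx) >= 2 && stats::sd(frac) > 0) {
    fit <- stats::lm.wfit(cbind(1, frac), ang, w)
    phi0 <- unname(-fit$coefficients[1] * 180 / pi)
    phi1 <- unname(-fit$coefficients[2] * 180 / pi)
  } else {
    phi0 <- -stats::weighted.mean(ang, w) * 180 / pi
    phi1 <- 0
  }
  # robust alternative start: unweighted median angle, no first-order term
  # (the weighted regression can be poisoned by distorted peaks, e.g. the
  # cut Lorentzian shoulders that survive at suppression-band edges)
  phi0_med <- -stats::median(ang) * 180 / pi
  converged <- TRUE
  if (refine) {
    # evaluation points: the strongest bins plus a uniform thinning of the
    # whole axis, so every spectral region constrains the first-order term
    keep <- union(
      order(mag, decreasing = TRUE)[seq_len(min(3000L, n))],
      seq(1L, n, by = max(1L, n %/% 2000L))
    )
    keep <- sort(keep)
    re <- spec$real[keep]
    im <- spec$imag[keep]
    fr <- (keep - 1) / (n - 1) - 0.5
    objective <- function(p) {
      phi <- (p[1] + p[2] * fr) * pi / 180
      r <- re * cos(phi) - im * sin(phi)
      h <- abs(diff(r))
      tot <- sum(h)
      ent <- if (tot > 0) {
        hn <- h[h > 0] / tot
        -sum(hn * log(hn))
      } else {
        0
      }
      neg <- r[r < 0]
      # negativity dominates (absorption spectra are non-negative up to
      # noise); the entropy term only breaks near-ties
      0.01 * ent + 1e5 * sum(neg^2) / (sum(r^2) + .Machine$double.eps)
    }
    starts <- list(c(phi0, phi1), c(phi0_med, 0), c(0, 0))
    best <- starts[[which.min(vapply(starts, objective, numeric(1)))]]
    opt <- stats::optim(best, objective,
      method = "Nelder-Mead",
      control = list(maxit = 500, reltol = 1e-10)
    )
    if (opt$convergence == 0 && opt$value <= objective(best)) {
      phi0 <- opt$par[1]
      phi1 <- opt$par[2]
    } else if (opt$convergence != 0) {
      converged <- FALSE
      flags <- c(flags, "auto_phase_not_converged")
    }
  }
  # normalize phi0 into (-180, 180]
  phi0 <- atan2(sin(phi0 * pi / 180), cos(phi0 * pi / 180)) * 180 / pi
  r <- phase_rotate(spec$real, spec$imag, phi0, phi1)
  new_spectrum(r$real, r$imag, spec$ppm, spec$acq,
    add_step(spec$provenance, "auto_phase",
      phi0_deg = unname(phi0), phi1_deg = unname(phi1), converged = converged
    ),
    flags = flags
  )
}

# asymmetric least squares (Eilers) baseline on a decimated grid:
# minimize sum w_i (y_i - z_i)^2 + lambda * sum (d2 z)^2 with w small above
# the baseline; exclusion windows get weight 0.
als_baseline <- function(y, lambda, p, n_iter = 10, w0 = NULL) {
  m <- length(y)
  D <- Matrix::bandSparse(m - 2, m,
    k = 0:2,
    diagonals = list(rep(1, m - 2), rep(-2, m - 2), rep(1, m - 2))
  )
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  keep <- if (is.null(w0)) rep(TRUE, m) else w0 > 0
  z <- y
  for (i in seq_len(n_iter)) {
    wk <- w * as.numeric(keep)
    W <- Matrix::Diagonal(m, wk)
    z <- as.numeric(Matrix::solve(W + DtD, wk * y))
    w <- ifelse(y > z, p, 1 - p)
  }
  z
}

#' Baseline correction
#'
#' Subtracts a smooth baseline estimated by asymmetric least squares on a
#' decimated (block-averaged) copy of the real part, then interpolated back
#' to the full axis. Signal windows can be excluded from the baseline
#' estimate; after correction the median of the signal-free regions is
#' approximately zero. The spectrum must be phased first.
#'
#' @param spec An [new_spectrum()] object.
#' @param exclude Optional two-column matrix/data frame of
#'   `(high_ppm, low_ppm)` signal windows excluded from the baseline fit.
#' @param lambda Smoothness penalty of the asymmetric least squares (grid
#'   units of the decimated axis).
#' @param p Asymmetry parameter (weight of points above the baseline).
#' @param grid_max Maximum decimated grid size.
#' @return The baseline-corrected spectrum.
#' @export
baseline_correct <- function(spec, exclude = NULL, lambda = 1e6, p = 1e-4,
                             grid_max = 8192L) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  n <- length(spec$real)
  m <- as.integer(min(grid_max, n))
  block <- n %/% m
  m <- n %/% block
  used <- m * block
  y <- colMeans(matrix(spec$real[seq_len(used)], nrow = block))
  ppm_g <- colMeans(matrix(spec$ppm[seq_len(used)], nrow = block))
  w0 <- rep(1, m)
  if (!is.null(exclude)) {
    exclude <- as.matrix(exclude)
    for (k in seq_len(nrow(exclude))) {
      hi <- max(exclude[k, ])
      lo <- min(exclude[k, ])
      w0[ppm_g <= hi & ppm_g >= lo] <- 0
    }
    if (!any(w0 > 0)) {
      stop("no signal-free region left for baseline estimation", call. = FALSE)
    }
  }
  z <- als_baseline(y, lambda = lambda, p = p, w0 = w0)
  base_full <- stats::approx(ppm_g, z, xout = spec$ppm, rule = 2)$y
  new_spectrum(spec$real - base_full, spec$imag, spec$ppm, spec$acq,
    add_step(spec$provenance, "baseline", lambda = lambda, p = p),
    flags = spec$flags
  )
}

#' Reference the axis to TMS
#'
#' Shifts the ppm axis so the TMS maximum (searched within +/- 0.2 ppm of 0)
#' sits at exactly 0 ppm. If no peak rises above the detection threshold the
#' axis is left unchanged and the spectrum is flagged (with a warning).
#'
#' @param spec An [new_spectrum()] object.
#' @param search_ppm Half width of the search window around 0 ppm.
#' @param snr_min Detection threshold as a multiple of the median absolute
#'   intensity of the search window's surroundings.
#' @return The referenced spectrum.
#' @export
reference_to_tms <- function(spec, search_ppm = 0.2, snr_min = 20) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  idx <- which(spec$ppm <= search_ppm & spec$ppm >= -search_ppm)
  if (!length(idx)) {
    warning("axis does not cover the TMS region; left unreferenced")
    spec$flags <- c(spec$flags, "tms_not_found")
    return(spec)
  }
  y <- spec$real[idx]
  floor_level <- stats::median(abs(spec$real))
  i_max <- idx[which.max(y)]
  if (max(y) < snr_min * floor_level) {
    warning("no TMS peak found near 0 ppm; axis left unchanged")
    spec$flags <- c(spec$flags, "tms_not_found")
    spec$provenance <- add_step(spec$provenance, "tms_reference",
      shift_ppm = 0, found = FALSE
    )
    return(spec)
  }
  shift <- spec$ppm[i_max]
  new_spectrum(spec$real, spec$imag, spec$ppm - shift, spec$acq,
    add_step(spec$provenance, "tms_reference", shift_ppm = -shift, found = TRUE),
    flags = spec$flags
  )
}

#' Full processing chain
#'
#' Applies, in order: exponential apodization, zero filling to SI, Fourier
#' transform, automatic phase correction, baseline correction, and TMS
#' referencing. Each step and its parameters are recorded in the provenance.
#'
#' @param fid An [new_fid()] object.
#' @param lb_hz Line broadening (default from the acquisition parameters).
#' @param si Zero-fill target in real points (default from acquisition).
#' @param baseline_exclude Optional exclusion windows for the baseline fit.
#' @param reference Run TMS referencing.
#' @param phase Run automatic phasing.
#' @param baseline Run baseline correction.
#' @return A processed [new_spectrum()] object.
#' @export
#' @examples
#' acq <- acq_params(td = 8192L, si = 16384L)
#' fid <- synthesize_fid(
#'   sample_composition(cbd = 5000, matrix_kind = "none"),
#'   acq, lineshape_params(noise_sigma = 0)
#' )
#' spec <- process_fid(fid)
process_fid <- function(fid, lb_hz = fid$acq$lb_hz, si = fid$acq$si,
                        baseline_exclude = NULL, reference = TRUE,
                        phase = TRUE, baseline = TRUE) {
  spec <- fid |>
    apodize_exponential(lb_hz) |>
    zero_fill(si) |>
    fourier_transform()
  if (phase) spec <- auto_phase(spec)
  if (baseline) spec <- baseline_correct(spec, exclude = baseline_exclude)
  if (reference) spec <- reference_to_tms(spec)
  spec
}
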