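# Synthetic CBD-oil spectra: analyte multiplets and the broad CBD aromatic
# hump between 3 and 8.3 ppm, intense triglyceride bands, TMS, and complex
# white noise in the time domain. Amplitudes follow the qNMR response model
# (molar concentration x proton count x NS x RG / P1), so the PULCON algebra
# downstream is exercised with the same scaling it assumes on a spectrometer.

RESPONSE_CONST <- 1.0 # instrument response per mmol/L proton, arbitrary units
P1_REF_US <- 8.0 # reference pulse length the response is normalized to

#' Lineshape parameters of the synthetic spectra
#'
#' @param fwhm_hz Natural full width at half maximum of sharp analyte lines,
#'   Hz (before the exponential line broadening of processing).
#' @param hump_fwhm_hz Width of the broad CBD aromatic hump near 6.2 ppm, Hz.
#'   The hump is modeled as a single broad Lorentzian carrying the two
#'   aromatic CBD protons.
#' @param noise_sigma Standard deviation of the complex white noise added to
#'   each FID point (arbitrary amplitude units). The default is calibrated so
#'   a 140 mg/L Delta9-THC doublet ends up near signal-to-noise 50 after
#'   default processing, i.e. close to the method's practical detection regime.
#' @param shift_drift_ppm_per_gl Linear drift of the Delta8/Delta9/hump
#'   centers with CBD content, ppm per g/L of CBD; 0 disables drift.
#' @return An object of class `lineshape_params`.
#' @export
lineshape_params <- function(fwhm_hz = 1.2,
                             hump_fwhm_hz = 40,
                             noise_sigma = default_noise_sigma(),
                             shift_drift_ppm_per_gl = 0) {
  stopifnot(fwhm_hz > 0, hump_fwhm_hz > 0, noise_sigma >= 0)
  structure(
    list(
      fwhm_hz = fwhm_hz, hump_fwhm_hz = hump_fwhm_hz,
      noise_sigma = noise_sigma,
      shift_drift_ppm_per_gl = shift_drift_ppm_per_gl
    ),
    class = "lineshape_params"
  )
}

#' Default FID noise level
#'
#' Frozen calibration constant: with the default acquisition and processing
#' parameters, this sigma puts the fitted Delta9-THC doublet of a 140 mg/L
#' sample at a signal-to-noise ratio of about 50.
#'
#' @return A single number.
#' @export
default_noise_sigma <- function() 70

#' Composition of a synthetic sample
#'
#' @param ... Analyte mass concentrations in mg/L of sample solution, named
#'   by analyte key (`cbd`, `delta9_thc`, `delta8_thc`, `cbn`, `cbg`, `cbda`,
#'   `thca`). Concentrations must be non-negative.
#' @param matrix_kind `"hemp"`, `"MCT"` or `"none"`.
#' @param matrix_intensity Scale of the triglyceride bands (mmol/L proton
#'   equivalents); the default puts them two orders of magnitude above a
#'   1000 mg/L cannabinoid signal, as in a real oil.
#' @param saturation Named numeric vector of multiplicative partial-saturation
#'   attenuation factors in (0, 1] per analyte; unnamed analytes default to 1.
#' @param include_tms Add the 0.05 % TMS reference singlet at 0 ppm.
#' @return An object of class `sample_composition`.
#' @export
#' @examples
#' sample_composition(delta9_thc = 700, cbd = 15000, matrix_kind = "hemp")
sample_composition <- function(...,
                               matrix_kind = c("hemp", "MCT", "none"),
                               matrix_intensity = 500,
                               saturation = numeric(),
                               include_tms = TRUE) {
  matrix_kind <- match.arg(matrix_kind)
  conc <- c(...)
  if (length(conc)) {
    if (is.null(names(conc)) || any(!nzchar(names(conc)))) {
      stop("analyte concentrations must be named", call. = FALSE)
    }
    if (any(conc < 0)) {
      stop("analyte concentrations must be non-negative", call. = FALSE)
    }
    unknown <- setdiff(names(conc), names(molar_masses()))
    if (length(unknown)) {
      stop("unknown analyte(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  if (length(saturation) &&
    (any(saturation <= 0) || any(saturation > 1))) {
    stop("saturation factors must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(matrix_intensity >= 0)
  structure(
    list(
      conc_mg_l = conc, matrix_kind = matrix_kind,
      matrix_intensity = matrix_intensity, saturation = saturation,
      include_tms = include_tms
    ),
    class = "sample_composition"
  )
}

# first-order multiplet pattern: offsets (Hz) and binomial weights
multiplet_pattern <- function(multiplicity, j_hz) {
  switch(multiplicity,
    s = ,
    hump = list(offset = 0, weight = 1),
    d = list(offset = c(-0.5, 0.5) * j_hz, weight = c(1, 1) / 2),
    t = ,
    # narrow unresolved multiplets are approximated by a 1:2:1 triplet
    m = list(offset = c(-1, 0, 1) * j_hz, weight = c(1, 2, 1) / 4),
    quint = list(
      offset = c(-2, -1, 0, 1, 2) * j_hz,
      weight = c(1, 4, 6, 4, 1) / 16
    ),
    stop("unknown multiplicity: ", multiplicity, call. = FALSE)
  )
}

# triglyceride band model; MCT oils lack the bis-allylic (2.77 ppm) and
# olefinic (5.34 ppm) bands of hemp seed oil
matrix_bands <- function(matrix_kind) {
  bands <- tibble::tibble(
    center_ppm = c(0.88, 1.285, 1.615, 2.035, 2.31, 2.765, 5.34),
    fwhm_hz = c(6, 10, 8, 10, 8, 8, 12),
    rel = c(0.9, 1.0, 0.25, 0.4, 0.2, 0.15, 0.12)
  )
  if (matrix_kind == "MCT") {
    bands <- bands[!bands$center_ppm %in% c(2.765, 5.34), ]
  }
  bands
}

# assemble the line list (frequency offsets from carrier, amplitude, T2)
# for a composition under a given acquisition
line_list <- function(composition, acq, lineshape) {
  lib <- signal_library(
    if (composition$matrix_kind == "MCT") "MCT" else "hemp"
  )
  mm <- molar_masses()
  p1f <- P1_REF_US / acq$p1_us
  scale <- RESPONSE_CONST * acq$ns * acq$rg * p1f
  cbd_gl <- unname(composition$conc_mg_l["cbd"])
  cbd_gl <- if (is.na(cbd_gl) || !length(cbd_gl)) 0 else cbd_gl / 1000
  drift <- lineshape$shift_drift_ppm_per_gl * cbd_gl

  lines <- list()
  for (an in names(composition$conc_mg_l)) {
    conc <- composition$conc_mg_l[[an]]
    if (conc == 0) next
    sat <- composition$saturation[an]
    sat <- if (is.na(sat) || !length(sat)) 1 else unname(sat)
    c_mmol <- conc / mm[[an]]
    rows <- lib[lib$analyte == an, ]
    for (k in seq_len(nrow(rows))) {
      sig <- rows[k, ]
      center <- sig$center_ppm
      drifts <- an %in% c("delta8_thc", "delta9_thc") || sig$multiplicity == "hump"
      if (drifts) center <- center + drift
      fw <- if (sig$multiplicity == "hump") lineshape$hump_fwhm_hz else lineshape$fwhm_hz
      pat <- multiplet_pattern(sig$multiplicity, sig$j_hz)
      amp <- scale * c_mmol * sig$n_protons * sat
      lines[[length(lines) + 1L]] <- tibble::tibble(
        f_hz = (center - acq$o1_ppm) * acq$sf_mhz + pat$offset,
        amp = amp * pat$weight,
        fwhm_hz = fw
      )
    }
  }
  if (composition$matrix_kind != "none" && composition$matrix_intensity > 0) {
    bands <- matrix_bands(composition$matrix_kind)
    lines[[length(lines) + 1L]] <- tibble::tibble(
      f_hz = (bands$center_ppm - acq$o1_ppm) * acq$sf_mhz,
      amp = scale * composition$matrix_intensity * bands$rel,
      fwhm_hz = bands$fwhm_hz
    )
  }
  if (isTRUE(composition$include_tms)) {
    # 0.05 % v/v TMS: ~2.2 mmol/L x 12 equivalent protons
    lines[[length(lines) + 1L]] <- tibble::tibble(
      f_hz = (0 - acq$o1_ppm) * acq$sf_mhz,
      amp = scale * 26.4,
      fwhm_hz = lineshape$fwhm_hz
    )
  }
  if (!length(lines)) {
    return(tibble::tibble(f_hz = numeric(), amp = numeric(), fwhm_hz = numeric()))
  }
  dplyr::bind_rows(lines)
}

fid_from_lines <- function(lines, acq, noise_sigma = 0, seed = NULL) {
  n <- acq$td %/% 2L
  t <- (seq_len(n) - 1) / acq$sw_hz
  x <- complex(real = numeric(n), imaginary = numeric(n))
  for (k in seq_len(nrow(lines))) {
    r2 <- pi * lines$fwhm_hz[k] # 1/T2*
    x <- x + lines$amp[k] * exp(complex(
      real = -r2 * t,
      imaginary = 2 * pi * lines$f_hz[k] * t
    ))
  }
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    x <- x + complex(
      real = stats::rnorm(n, 0, noise_sigma),
      imaginary = stats::rnorm(n, 0, noise_sigma)
    )
  }
  x
}

#' Synthesize the FID of a CBD-oil sample
#'
#' Sums one exponentially decaying complex tone per multiplet transition
#' (`amplitude * exp(2i pi nu t) * exp(-t / T2*)`), with first-order binomial
#' multiplet intensity ratios, plus the triglyceride matrix bands, the broad
#' CBD aromatic hump, TMS, and complex Gaussian white noise. Amplitudes scale
#' as molar concentration x proton count x saturation x NS x RG / P1. The
#' result is deterministic given `seed`.
#'
#' @param composition A [sample_composition()].
#' @param acq An [acq_params()] object.
#' @param lineshape A [lineshape_params()] object.
#' @param seed Integer seed for the noise generator.
#' @return An [new_fid()] object of `td/2` complex points.
#' @export
#' @examples
#' acq <- acq_params(td = 8192L, si = 16384L)
#' fid <- synthesize_fid(
#'   sample_composition(cbd = 1000, matrix_kind = "none"),
#'   acq, lineshape_params(noise_sigma = 0), seed = 1
#' )
synthesize_fid <- function(composition, acq,
                           lineshape = lineshape_params(), seed = 1L) {
  stopifnot(
    inherits(composition, "sample_composition"),
    inherits(acq, "acq_params"), inherits(lineshape, "lineshape_params")
  )
  lines <- line_list(composition, acq, lineshape)
  x <- fid_from_lines(lines, acq, lineshape$noise_sigma, seed)
  new_fid(x, acq, provenance = list(list(
    step = "synthesize",
    matrix_kind = composition$matrix_kind, seed = seed,
    noise_sigma = lineshape$noise_sigma
  )))
}

#' Simulate the QR external-standard FID
#'
#' Generates the TCNB singlet (7.64-7.83 ppm range) and the three-proton EB
#' aromatic multiplet (7.0162-7.2341 ppm range). By default each component's
#' amplitude is attenuated by exactly `1/kappa` — the saturation the published
#' correction factors invert — so the ERETIC-factor algebra round-trips in
#' closed form. `saturation_mode = "physical"` instead applies
#' `1 - exp(-TR / T1)` with `TR = aq + d1`.
#'
#' @param qr A [qr_standard()] tibble; must carry kappa and T1 per component.
#' @param acq An [acq_params()] object.
#' @param seed Integer seed (used only when `noise_sigma > 0`).
#' @param noise_sigma FID noise standard deviation; the QR round trip is
#'   defined noiseless.
#' @param lineshape A [lineshape_params()] object (widths only).
#' @param saturation_mode `"kappa"` (default) or `"physical"`.
#' @return An [new_fid()] object.
#' @export
simulate_qr <- function(qr = qr_standard(), acq = acq_params(), seed = 1L,
                        noise_sigma = 0,
                        lineshape = lineshape_params(noise_sigma = 0),
                        saturation_mode = c("kappa", "physical")) {
  saturation_mode <- match.arg(saturation_mode)
  check_qr(qr)
  p1f <- P1_REF_US / acq$p1_us
  scale <- RESPONSE_CONST * acq$ns * acq$rg * p1f
  sat <- switch(saturation_mode,
    kappa = 1 / qr$kappa,
    physical = 1 - exp(-(acq$aq_s + acq$d1_s) / qr$t1_s)
  )
  lines <- purrr::map_dfr(seq_len(nrow(qr)), function(k) {
    pat <- multiplet_pattern(qr$multiplicity[k], qr$j_hz[k])
    amp <- scale * (qr$mass_mg_l[k] / qr$molar_mass[k]) * qr$n_protons[k] * sat[k]
    tibble::tibble(
      f_hz = (qr$center_ppm[k] - acq$o1_ppm) * acq$sf_mhz + pat$offset,
      amp = amp * pat$weight,
      fwhm_hz = lineshape$fwhm_hz
    )
  })
  # TMS for referencing
  lines <- dplyr::bind_rows(lines, tibble::tibble(
    f_hz = (0 - acq$o1_ppm) * acq$sf_mhz, amp = scale * 26.4,
    fwhm_hz = lineshape$fwhm_hz
  ))
  x <- fid_from_lines(lines, acq, noise_sigma, seed)
  new_fid(x, acq, provenance = list(list(
    step = "simulate_qr", saturation_mode = saturation_mode, seed = seed
  )))
}

#' Apply multiple suppression to an FID
#'
#' Emulates the selective saturation of the triglyceride resonances:
#' absorption content inside each band is attenuated to its
#' `residual_fraction` (FFT, mask, inverse FFT); content outside the bands is
#' preserved to numerical tolerance. An empty band table is the identity.
#'
#' Because an FID is causal, every resonance carries dispersion tails far
#' outside its own line: a naive complex-spectrum mask would remove only the
#' in-band absorption and leave half of the early-time signal behind. The
#' removed component is therefore built from the masked *absorption* profile
#' and re-made causal (its dispersion part follows by the Kramers-Kronig
#' relation), which removes in-band resonances the way on-resonance
#' presaturation does.
#'
#' @param fid An [new_fid()] object.
#' @param bands A tibble as from [suppression_bands()] (Hz from the 0 ppm
#'   reference). Bands must lie inside the spectral width.
#' @param taper_hz Width of the raised-cosine roll-off outside each band
#'   edge. A hard-edged mask rings across the whole spectrum once the FID is
#'   zero-filled (Dirichlet interpolation of a step); a few Hz of taper
#'   confines the edge response, as the finite-bandwidth saturation of a real
#'   presaturation pulse does.
#' @return A suppressed [new_fid()] object.
#' @export
apply_suppression <- function(fid, bands = suppression_bands(), taper_hz = 2) {
  stopifnot(inherits(fid, "nmr_fid"))
  if (!nrow(bands)) {
    return(fid)
  }
  if (any(bands$lo_hz >= bands$hi_hz)) {
    stop("suppression bands need lo_hz < hi_hz", call. = FALSE)
  }
  acq <- fid$acq
  ppm_max <- acq$o1_ppm + acq$sw_ppm / 2
  ppm_min <- acq$o1_ppm - acq$sw_ppm / 2
  band_ppm_hi <- bands$hi_hz / acq$sf_mhz
  band_ppm_lo <- bands$lo_hz / acq$sf_mhz
  if (any(band_ppm_hi > ppm_max | band_ppm_lo < ppm_min)) {
    stop("suppression band outside the spectral width", call. = FALSE)
  }
  n <- length(fid$data)
  # mask via linear (zero-padded) convolution: the spectral mask's impulse
  # response is two-sided in time, and with a circular FFT its anti-causal
  # half would wrap onto the tail of the FID and ring after zero filling
  n2 <- 2L * n
  # halve the first point for the transform (removes the flat DFT pedestal
  # of the t = 0 sample, which no frequency mask could suppress), undo after
  x0 <- fid$data
  x0[1] <- x0[1] * 0.5
  X <- stats::fft(c(x0, complex(real = numeric(n), imaginary = numeric(n))))
  j <- seq_len(n2) - 1L
  f_hz <- ifelse(j < n2 / 2, j, j - n2) * (acq$sw_hz / n2)
  ppm <- acq$o1_ppm + f_hz / acq$sf_mhz
  mask <- rep(1, n2)
  hz_rel <- ppm * acq$sf_mhz # Hz from the 0 ppm reference
  for (b in seq_len(nrow(bands))) {
    res <- bands$residual_fraction[b]
    lo <- bands$lo_hz[b]
    hi <- bands$hi_hz[b]
    inside <- hz_rel >= lo & hz_rel <= hi
    mask[inside] <- pmin(mask[inside], res)
    if (taper_hz > 0) {
      up <- hz_rel > hi & hz_rel <= hi + taper_hz
      frac <- (hz_rel[up] - hi) / taper_hz
      mask[up] <- pmin(mask[up], res + (1 - res) * (1 - cos(pi * frac)) / 2)
      dn <- hz_rel < lo & hz_rel >= lo - taper_hz
      frac <- (lo - hz_rel[dn]) / taper_hz
      mask[dn] <- pmin(mask[dn], res + (1 - res) * (1 - cos(pi * frac)) / 2)
    }
  }
  # removed component: masked absorption, made causal again so each
  # suppressed resonance takes its dispersion tails with it
  removed_abs <- Re(X) * (1 - mask)
  y_even <- stats::fft(removed_abs, inverse = TRUE) / n2
  y <- 2 * y_even[seq_len(n)]
  y[1] <- y_even[1]
  x <- x0 - y
  x[1] <- x[1] * 2
  new_fid(x, acq, provenance = add_step(fid$provenance, "suppression",
    n_bands = nrow(bands)
  ))
}

#' Generate a synthetic spiking (calibration) series
#'
#' One FID per spike level of one analyte on a constant matrix composition,
#' with independent noise per level plus a multiplicative per-level area
#' jitter (the "area noise" of the spiking experiment). Reproducible for a
#' given seed.
#'
#' @param analyte Analyte key (e.g. `"delta9_thc"`).
#' @param levels_mg_l Spike levels in mg/L; at least 3 (regression), and at
#'   least 5 are needed downstream for DIN 32645 limits.
#' @param matrix A [sample_composition()] giving the constant background
#'   (matrix bands, CBD content, ...).
#' @param acq,lineshape Acquisition and lineshape parameters.
#' @param seed Integer seed.
#' @param area_noise_cv Coefficient of the multiplicative area jitter
#'   (0.01 = 1 %).
#' @param suppress Apply the default suppression bands to each FID.
#' @return A tibble with columns `level_mg_l` and `fid` (list column).
#' @export
generate_calibration_set <- function(analyte, levels_mg_l, matrix,
                                     acq = acq_params(),
                                     lineshape = lineshape_params(),
                                     seed = 1L,
                                     area_noise_cv = 0.01,
                                     suppress = TRUE) {
  if (length(levels_mg_l) < 3) {
    stop("need at least 3 spike levels for a calibration regression", call. = FALSE)
  }
  stopifnot(inherits(matrix, "sample_composition"), analyte %in% names(molar_masses()))
  set.seed(as.integer(seed))
  fids <- purrr::map(seq_along(levels_mg_l), function(i) {
    jitter <- if (area_noise_cv > 0) 1 + stats::rnorm(1, 0, area_noise_cv) else 1
    conc <- matrix$conc_mg_l
    conc[analyte] <- max(
      0,
      (if (analyte %in% names(conc)) conc[[analyte]] else 0) +
        levels_mg_l[i] * jitter
    )
    comp <- matrix
    comp$conc_mg_l <- conc
    lines <- line_list(comp, acq, lineshape)
    x <- fid_from_lines(lines, acq, noise_sigma = 0)
    if (lineshape$noise_sigma > 0) {
      n <- length(x)
      x <- x + complex(
        real = stats::rnorm(n, 0, lineshape$noise_sigma),
        imaginary = stats::rnorm(n, 0, lineshape$noise_sigma)
      )
    }
    fid <- new_fid(x, acq, provenance = list(list(
      step = "synthesize", matrix_kind = comp$matrix_kind,
      level_mg_l = levels_mg_l[i], seed = seed
    )))
    if (suppress && comp$matrix_kind != "none") {
      fid <- apply_suppression(fid)
    }
    fid
  })
  tibble::tibble(level_mg_l = as.numeric(levels_mg_l), fid = fids)
}
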