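# Processing chain: zero fill, apodization, FT, automatic phasing, baseline,
# TMS referencing, and the composed pipeline contracts.

test_that("zero filling appends zeros and preserves the recorded samples", {
  acq <- acq_params(td = 1024L, si = 4096L)
  comp <- sample_composition(cbd = 1000, matrix_kind = "none")
  fid <- synthesize_fid(comp, acq, noiseless(), seed = 1)
  zf <- zero_fill(fid, 4096L)
  expect_length(zf$data, 2048L) # si real points = si/2 complex
  expect_identical(zf$data[1:512], fid$data)
  expect_true(all(zf$data[513:2048] == 0 + 0i))
  # si = td is the identity on the data
  expect_identical(zero_fill(fid, 1024L)$data, fid$data)
  # all-zero fid stays all-zero at the new length
  blank <- new_fid(complex(real = numeric(512), imaginary = numeric(512)), acq)
  expect_true(all(zero_fill(blank, 2048L)$data == 0 + 0i))
  expect_error(zero_fill(fid, 512L), "truncate")
})

test_that("exponential apodization follows exp(-pi lb t) with unit first point", {
  acq <- acq_params() # full TD so the printed AQ applies
  comp <- sample_composition(cbd = 1000, matrix_kind = "none")
  fid <- synthesize_fid(comp, acq, noiseless(), seed = 1)
  ap <- apodize_exponential(fid, 0.30)
  expect_identical(ap$data[1], fid$data[1]) # exp(0) = 1
  # last sample: t = (n-1) * dwell ~ AQ; factor = exp(-pi * 0.3 * t)
  n <- length(fid$data)
  t_last <- (n - 1) / acq$sw_hz
  expect_equal(
    as.numeric(Mod(ap$data[n] / fid$data[n])),
    exp(-pi * 0.3 * t_last),
    tolerance = 1e-10
  )
  # the stated acquisition time gives a ~5.5e-4 end factor
  expect_equal(exp(-pi * 0.3 * 7.9691777), 5.5e-4, tolerance = 0.01)
  expect_identical(apodize_exponential(fid, 0)$data, fid$data)
  expect_error(apodize_exponential(fid, -1), "non-negative")
})

test_that("apodization broadens the line (FWHM monotonicity)", {
  comp <- sample_composition(
    cbd = 1000, matrix_kind = "none",
    include_tms = FALSE
  )
  fwhm_of <- function(lb) {
    fid <- synthesize_fid(comp, small_acq(), noiseless(), seed = 1)
    spec <- process_fid(fid,
      lb_hz = lb, phase = FALSE, baseline = FALSE,
      reference = FALSE
    )
    idx <- which(spec$ppm < 5.66 & spec$ppm > 5.46)
    y <- spec$real[idx]
    half <- max(y) / 2
    sum(y > half) * abs(diff(spec$ppm[idx][1:2])) * spec$acq$sf_mhz
  }
  expect_gt(fwhm_of(0.3), fwhm_of(0))
})

test_that("the Fourier transform puts a pure tone at its ppm position", {
  acq <- small_acq()
  n <- acq$td %/% 2L
  t <- (seq_len(n) - 1) / acq$sw_hz
  nu <- (7.5 - acq$o1_ppm) * acq$sf_mhz # tone at 7.5 ppm
  fid <- new_fid(exp(complex(imaginary = 2 * pi * nu * t)), acq)
  spec <- fourier_transform(fid)
  expect_equal(spec$ppm[which.max(Mod(complex(
    real = spec$real,
    imaginary = spec$imag
  )))], 7.5, tolerance = 0.001)
  # all-zero fid transforms to an all-zero spectrum
  blank <- new_fid(complex(real = numeric(n), imaginary = numeric(n)), acq)
  bspec <- fourier_transform(blank)
  expect_true(all(bspec$real == 0) && all(bspec$imag == 0))
})

test_that("the absorption integral of a Lorentzian-decaying tone matches its amplitude", {
  acq <- small_acq()
  n <- acq$td %/% 2L
  t <- (seq_len(n) - 1) / acq$sw_hz
  amp <- 3.7
  fwhm <- 2.0
  nu <- (7.5 - acq$o1_ppm) * acq$sf_mhz
  fid <- new_fid(
    amp * exp(complex(real = -pi * fwhm * t, imaginary = 2 * pi * nu * t)),
    acq
  )
  spec <- fourier_transform(zero_fill(fid))
  got <- integrate_window(spec, high_ppm = 7.7, low_ppm = 7.3)
  # one-sided discrete FT with the halved first point: the absorption
  # integral over frequency equals amp * sw_hz / 2 (the t = 0 sample counts
  # half, exactly the continuous Lorentzian limit) times the analytic
  # captured-tail fraction of the 160 Hz window
  captured <- (2 / pi) * atan(2 * 80 / fwhm)
  expect_equal(got, amp * acq$sw_hz / 2 * captured, tolerance = 0.005)
})

test_that("integral of an isolated peak is invariant to zero filling", {
  # fully decayed line (2.5 Hz wide over a 1 s acquisition), so the zero
  # fill interpolates a ring-free spectrum
  acq <- acq_params(td = 16384L, si = 16384L)
  comp <- sample_composition(
    cbd = 1000, matrix_kind = "none",
    include_tms = FALSE
  )
  fid <- synthesize_fid(comp, acq, lineshape_params(
    fwhm_hz = 2.5,
    noise_sigma = 0
  ), seed = 1)
  a1 <- integrate_window(
    fourier_transform(fid),
    high_ppm = 5.66, low_ppm = 5.46
  )
  a2 <- integrate_window(
    fourier_transform(zero_fill(fid, 65536L)),
    high_ppm = 5.66, low_ppm = 5.46
  )
  expect_equal(a2 / a1, 1, tolerance = 0.001)
})

test_that("auto phasing is a fixed point on phased spectra and recovers rotations", {
  spec <- fourier_transform(zero_fill(apodize_exponential(
    simulate_qr(qr_standard(), small_acq(), seed = 1)
  )))
  phased <- auto_phase(spec)
  ph <- Filter(function(s) s$step == "auto_phase", phased$provenance)[[1]]
  expect_lt(abs(ph$phi0_deg), 1)
  # inject a 30 degree zeroth-order rotation and recover it
  rec <- auto_phase(phase_correct(spec, 30))
  ph2 <- Filter(function(s) s$step == "auto_phase", rec$provenance)[[1]]
  expect_equal(ph2$phi0_deg, -30, tolerance = 1)
  # round trip: integrals after correction match the unrotated reference
  rot <- phase_correct(spec, 25, 40)
  rec2 <- auto_phase(rot)
  a_ref <- integrate_window(phased, high_ppm = 7.83, low_ppm = 7.64)
  a_rec <- integrate_window(rec2, high_ppm = 7.83, low_ppm = 7.64)
  expect_equal(a_rec / a_ref, 1, tolerance = 0.01)
})

test_that("baseline correction removes offsets and ramps without touching areas", {
  spec <- qr_small_spec()
  a_ref <- integrate_window(spec, high_ppm = 7.83, low_ppm = 7.64)
  # flat offset
  off <- spec
  c0 <- 0.2 * max(spec$real)
  off$real <- off$real + c0
  corr <- baseline_correct(off)
  free <- corr$ppm < 4.5 & corr$ppm > 2.5
  expect_lt(abs(stats::median(corr$real[free])), 0.01 * c0)
  # linear ramp: areas equal the no-ramp reference within 1 %
  ramp <- spec
  ramp$real <- ramp$real + seq(0, c0, length.out = length(ramp$real))
  a_ramp <- integrate_window(baseline_correct(ramp),
    high_ppm = 7.83,
    low_ppm = 7.64
  )
  expect_equal(a_ramp / a_ref, 1, tolerance = 0.01)
  # zero spectrum stays zero
  zero <- new_spectrum(
    numeric(1000), numeric(1000),
    seq(10, 1, length.out = 1000), small_acq()
  )
  expect_true(all(abs(baseline_correct(zero)$real) < 1e-8))
  # everything excluded -> no signal-free region
  expect_error(
    baseline_correct(spec, exclude = cbind(17, -5)),
    "signal-free"
  )
})

test_that("TMS referencing shifts the axis so TMS sits at exactly 0", {
  comp <- sample_composition(
    cbd = 1000, matrix_kind = "none",
    include_tms = TRUE
  )
  fid <- synthesize_fid(comp, small_acq(), noiseless(), seed = 1)
  spec <- process_fid(fid, reference = FALSE)
  # shift the axis by +0.03 ppm, then reference
  shifted <- spec
  shifted$ppm <- shifted$ppm + 0.03
  ref <- reference_to_tms(shifted)
  i_tms <- which.max(ref$real[abs(ref$ppm) < 0.2])
  near0 <- ref$ppm[abs(ref$ppm) < 0.2]
  expect_lt(abs(near0[i_tms]), 0.002)
  # already referenced: the shift applied is ~0
  ref2 <- reference_to_tms(ref)
  steps <- Filter(function(s) s$step == "tms_reference", ref2$provenance)
  step <- steps[[length(steps)]]
  expect_lt(abs(step$shift_ppm), 0.002)
  # no TMS present -> warning + flag, axis unchanged
  comp2 <- sample_composition(
    cbd = 1000, matrix_kind = "none",
    include_tms = FALSE
  )
  spec2 <- process_fid(synthesize_fid(comp2, small_acq(), noiseless(), seed = 1),
    reference = FALSE
  )
  expect_warning(out <- reference_to_tms(spec2), "TMS")
  expect_true("tms_not_found" %in% out$flags)
  expect_identical(out$ppm, spec2$ppm)
})

test_that("Hz/ppm conversion matches the printed band edges", {
  expect_equal(hz_to_ppm(2156, 400), 5.39)
  expect_equal(hz_to_ppm(0, 400), 0)
  expect_equal(hz_to_ppm(400, 400), 1)
  expect_equal(ppm_to_hz(hz_to_ppm(347, 400), 400), 347)
})

test_that("the full chain preserves provenance and recovers signal positions", {
  comp <- sample_composition(
    cbd = 8000, delta9_thc = 900, cbn = 700,
    matrix_kind = "hemp"
  )
  spec <- quick_spectrum(comp)
  steps <- vapply(spec$provenance, `[[`, "", "step")
  expect_true(all(c(
    "apodize", "zero_fill", "fourier_transform",
    "auto_phase", "baseline", "tms_reference"
  ) %in% steps))
  # round trip: isolated signal centres recovered within 0.002 ppm
  for (target in c(3.88, 8.21)) {
    idx <- which(abs(spec$ppm - target) < 0.03)
    expect_lt(abs(spec$ppm[idx][which.max(spec$real[idx])] - target), 0.002)
  }
  # two-component area ratio equals the composition ratio (after molar and
  # proton normalization, CBD 3.88 vs CBN 8.21, both 1 proton)
  a_cbd <- integrate_window(spec, high_ppm = 3.92, low_ppm = 3.84)
  a_cbn <- integrate_window(spec, high_ppm = 8.25, low_ppm = 8.17)
  expect_equal(
    (a_cbd / a_cbn) / ((8000 / 314.47) / (700 / 310.44)),
    1,
    tolerance = 0.02
  )
})
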