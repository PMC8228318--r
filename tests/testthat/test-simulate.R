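# Synthetic-spectrum generator: signal library contents, FID synthesis
# linearity and determinism, QR construction, suppression behaviour.

test_that("signal library holds the quantification signals with per-matrix windows", {
  lib <- signal_library("hemp")
  quant <- lib[lib$quantified, ]
  d9 <- quant[quant$analyte == "delta9_thc", ]
  expect_equal(nrow(d9), 1)
  expect_equal(d9$center_ppm, 6.15)
  expect_equal(d9$multiplicity, "d")
  expect_equal(d9$n_protons, 1L)
  expect_equal(quant$center_ppm[quant$analyte == "delta8_thc"], 6.12)
  expect_setequal(
    quant$center_ppm[quant$analyte == "cbd"],
    c(3.88, 4.52, 4.63)
  )
  expect_setequal(
    quant$center_ppm[quant$analyte == "cbn"],
    c(7.05, 7.13, 8.21)
  )
  expect_true(all(quant$n_protons == 1L))
  # interferents are present but never quantified
  interf <- lib[!lib$quantified, ]
  expect_true(all(c(5.56, 6.33, 6.24, 6.23, 6.228) %in% interf$center_ppm))
  expect_true("hump" %in% interf$multiplicity)
  # windows contain their centres
  expect_true(all(lib$window_low <= lib$center_ppm &
    lib$center_ppm <= lib$window_high))
  # MCT: same signal set, narrowed Delta8/Delta9 search windows
  mct <- signal_library("MCT")
  expect_equal(mct$label, lib$label)
  w_hemp <- lib$window_high[lib$label == "D9-THC H-3'"] -
    lib$window_low[lib$label == "D9-THC H-3'"]
  w_mct <- mct$window_high[mct$label == "D9-THC H-3'"] -
    mct$window_low[mct$label == "D9-THC H-3'"]
  expect_lt(w_mct, w_hemp)
  expect_error(signal_library("olive"), "matrix_kind")
})

test_that("blank composition with zero noise synthesizes an all-zero FID", {
  comp <- sample_composition(matrix_kind = "none", include_tms = FALSE)
  fid <- synthesize_fid(comp, small_acq(), noiseless(), seed = 1)
  expect_equal(length(fid$data), small_acq()$td / 2)
  expect_true(all(fid$data == 0 + 0i))
  # and processes into a flat spectrum
  spec <- process_fid(fid, reference = FALSE)
  expect_true(all(abs(spec$real) < 1e-8))
})

test_that("a single CBD singlet yields exactly one peak, at 5.56 ppm", {
  comp <- sample_composition(cbd = 2000, matrix_kind = "none", include_tms = FALSE)
  spec <- quick_spectrum(comp)
  # peaks above 5 % of the maximum, merged per contiguous run
  thr <- 0.05 * max(spec$real)
  above <- spec$real > thr
  runs <- rle(above)
  peak_regions <- sum(runs$values)
  # CBD has several signals; restrict to a composition that only has the
  # 5.56 singlet by masking the others via the window around each
  peak_ppms <- spec$ppm[above]
  expect_true(any(abs(peak_ppms - 5.56) < 0.01))
  # every above-threshold point belongs to a known CBD signal of the library
  lib <- signal_library("hemp")
  cbd_centers <- lib$center_ppm[lib$analyte == "cbd"]
  ok <- vapply(peak_ppms, function(p) any(abs(p - cbd_centers) < 0.15), logical(1))
  expect_true(all(ok))
})

test_that("doubling the concentration doubles the processed peak area", {
  area_at <- function(conc) {
    comp <- sample_composition(
      cbd = conc, matrix_kind = "none",
      include_tms = FALSE
    )
    spec <- quick_spectrum(comp)
    integrate_window(spec, high_ppm = 3.92, low_ppm = 3.84)
  }
  r <- area_at(2000) / area_at(1000)
  expect_equal(r, 2, tolerance = 0.01)
})

test_that("area scales linearly with concentration x protons over a 10x range", {
  concs <- seq(500, 5000, length.out = 6)
  areas <- vapply(concs, function(conc) {
    spec <- quick_spectrum(sample_composition(
      cbn = conc, matrix_kind = "none",
      include_tms = FALSE
    ))
    integrate_window(spec, high_ppm = 8.25, low_ppm = 8.17)
  }, numeric(1))
  expect_gt(stats::cor(concs, areas), 0.9999)
})

test_that("synthesis is deterministic given the seed", {
  comp <- sample_composition(delta9_thc = 500, matrix_kind = "hemp")
  ls <- lineshape_params() # default noise on
  f1 <- synthesize_fid(comp, small_acq(), ls, seed = 7)
  f2 <- synthesize_fid(comp, small_acq(), ls, seed = 7)
  expect_identical(f1$data, f2$data)
  f3 <- synthesize_fid(comp, small_acq(), ls, seed = 8)
  expect_false(identical(f3$data, f1$data))
})

test_that("negative concentrations and invalid saturation are rejected", {
  expect_error(sample_composition(cbd = -1), "non-negative")
  expect_error(sample_composition(cbd = 10, saturation = c(cbd = 1.2)), "saturation")
  expect_error(sample_composition(unknown_thing = 5), "unknown analyte")
})

test_that("total spectral power equals FID power (Parseval)", {
  comp <- sample_composition(
    cbd = 3000, cbn = 500, matrix_kind = "none",
    include_tms = TRUE
  )
  fid <- synthesize_fid(comp, small_acq(), noiseless(), seed = 1)
  spec <- fourier_transform(fid, first_point_half = FALSE)
  lhs <- sum(spec$real^2 + spec$imag^2)
  rhs <- length(fid$data) * sum(Mod(fid$data)^2)
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("QR simulation reproduces the closed-form EB/TCNB area ratio", {
  spec <- qr_small_spec()
  a_tcnb <- integrate_window(spec, high_ppm = 7.83, low_ppm = 7.64)
  a_eb <- integrate_window(spec, high_ppm = 7.2341, low_ppm = 7.0162)
  expected <- (3 * 3506 / 106.17 * (1 / 1.22)) / (1 * 4662 / 260.89 * (1 / 1.30))
  expect_equal(a_eb / a_tcnb, expected, tolerance = 0.01)
})

test_that("QR with kappa = 1 gives identical per-proton molar response", {
  qr1 <- qr_standard()
  qr1$kappa <- c(1, 1)
  spec <- process_fid(simulate_qr(qr1, small_acq(), seed = 1))
  a_tcnb <- integrate_window(spec, high_ppm = 7.83, low_ppm = 7.64)
  a_eb <- integrate_window(spec, high_ppm = 7.2341, low_ppm = 7.0162)
  resp_tcnb <- a_tcnb / (1 * 4662 / 260.89)
  resp_eb <- a_eb / (3 * 3506 / 106.17)
  expect_equal(resp_tcnb / resp_eb, 1, tolerance = 0.005)
})

test_that("QR spectrum has no signal outside the aromatic region", {
  spec <- qr_small_spec() # includes TMS at 0 for referencing
  outside <- spec$ppm < 6.9 & spec$ppm > 0.5
  floor_level <- stats::median(abs(spec$real))
  expect_lt(max(spec$real[outside]), 5 * max(floor_level, 1e-9) +
    0.001 * max(spec$real))
  expect_error(
    simulate_qr(qr_standard()[, setdiff(names(qr_standard()), "kappa")], small_acq()),
    "kappa"
  )
})

test_that("suppression attenuates in-band content and preserves the rest", {
  acq <- small_acq()
  # pure lipid band at 5.34 ppm
  comp <- sample_composition(
    matrix_kind = "hemp", matrix_intensity = 100,
    include_tms = FALSE
  )
  fid <- synthesize_fid(comp, acq, noiseless(), seed = 1)
  area_534 <- function(f) {
    spec <- process_fid(f, phase = FALSE, baseline = FALSE, reference = FALSE)
    integrate_window(spec, high_ppm = 5.39, low_ppm = 5.29)
  }
  supp <- apply_suppression(fid, suppression_bands(0.01))
  expect_lt(area_534(supp) / area_534(fid), 0.01 + 0.02)
  # empty band list is the identity, bit-exactly
  expect_identical(apply_suppression(fid, suppression_bands()[0, ])$data, fid$data)
  # an analyte at 6.15 ppm is untouched by all seven default bands
  comp2 <- sample_composition(
    delta9_thc = 1000, matrix_kind = "none",
    include_tms = FALSE
  )
  fid2 <- synthesize_fid(comp2, acq, noiseless(), seed = 1)
  area_615 <- function(f) {
    spec <- process_fid(f, phase = FALSE, baseline = FALSE, reference = FALSE)
    integrate_window(spec, high_ppm = 6.19, low_ppm = 6.11)
  }
  rel <- abs(area_615(apply_suppression(fid2)) / area_615(fid2) - 1)
  expect_lt(rel, 0.005)
  # bands outside the spectral width error
  bad <- tibble::tibble(lo_hz = 9000, hi_hz = 9100, residual_fraction = 0)
  expect_error(apply_suppression(fid2, bad), "outside")
})

test_that("calibration sets are monotone, reproducible, and validated", {
  m <- sample_composition(matrix_kind = "hemp")
  set1 <- generate_calibration_set("delta9_thc", c(140, 420, 700, 980, 1260),
    m,
    acq = small_acq(), lineshape = noiseless(), seed = 3
  )
  expect_equal(nrow(set1), 5)
  areas <- vapply(set1$fid, function(fid) {
    spec <- process_fid(fid)
    sig <- signal_library("hemp")
    sig <- sig[sig$label == "D9-THC H-3'", ]
    fit_doublet_on_baseline(spec, sig)$area
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
  set2 <- generate_calibration_set("delta9_thc", c(140, 420, 700, 980, 1260),
    m,
    acq = small_acq(), lineshape = noiseless(), seed = 3
  )
  expect_identical(
    lapply(set1$fid, `[[`, "data"),
    lapply(set2$fid, `[[`, "data")
  )
  expect_error(
    generate_calibration_set("delta9_thc", c(100, 200), m, acq = small_acq()),
    "at least 3"
  )
  # single zero level on no matrix with zero noise is a blank FID
  blank <- generate_calibration_set(
    "delta9_thc", c(0, 0, 0),
    sample_composition(matrix_kind = "none", include_tms = FALSE),
    acq = small_acq(), lineshape = noiseless(), seed = 1, area_noise_cv = 0
  )
  expect_true(all(blank$fid[[1]]$data == 0 + 0i))
})
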