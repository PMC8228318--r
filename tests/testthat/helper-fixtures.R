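# Shared fixtures. Most tests run on a reduced acquisition (TD 16384,
# SI 32768) for speed; the spectral width, carrier and Hz<->ppm mapping are
# the full-size ones, so ppm positions and areas are directly comparable.

small_acq <- function() acq_params(td = 16384L, si = 32768L)

noiseless <- function() lineshape_params(noise_sigma = 0)

# processed spectrum of a composition (suppression applied when a matrix is
# present), small acquisition unless stated
quick_spectrum <- function(comp, acq = small_acq(), lineshape = noiseless(),
                           seed = 1L, suppress = comp$matrix_kind != "none") {
  fid <- synthesize_fid(comp, acq, lineshape, seed = seed)
  if (suppress) fid <- apply_suppression(fid)
  process_fid(fid, reference = isTRUE(comp$include_tms))
}

# QR spectrum + ERETIC factor are reused by many tests; computed once
qr_small_spec <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- process_fid(simulate_qr(qr_standard(), small_acq(), seed = 1))
    }
    val
  }
})

eretic_small <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- compute_eretic_factor(qr_small_spec())
    val
  }
})

# frequency-domain synthetic Lorentzian spectrum with known unit area,
# independent of the simulator (oracle for the integration routines)
lorentzian_spectrum <- function(center_ppm, fwhm_hz, area = 1,
                                acq = small_acq(), n = 16384L,
                                baseline = function(ppm) 0) {
  ppm <- seq(acq$o1_ppm + acq$sw_ppm / 2, acq$o1_ppm - acq$sw_ppm / 2,
    length.out = n
  )
  hz <- ppm * acq$sf_mhz
  y <- area * (2 / (pi * fwhm_hz)) /
    (1 + (2 * (hz - center_ppm * acq$sf_mhz) / fwhm_hz)^2) +
    baseline(ppm)
  new_spectrum(y, numeric(n), ppm, acq)
}
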