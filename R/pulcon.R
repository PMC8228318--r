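# PULCON/ERETIC external-standard quantification: signal areas -> mg/L of
# sample solution -> mg/kg of oil, with below-LOD censoring, CBD/CBN signal
# aggregation and control-sample checking. All reconstruction algebra of the
# concentration relation lives in this file.

#' Compute the ERETIC factor from a QR spectrum
#'
#' The instrument response per proton per mmol/L, normalized to unit NS x RG
#' and to the reference pulse length. Per component
#' `f_c = (A_c * kappa_c * P1_qr) / (n_c * (mass_c / M_c) * NS_qr * RG_qr)`,
#' where the empirical correction factor kappa restores the fully relaxed
#' intensity of the partially saturated long-T1 standard. The reported value
#' is the arithmetic mean over the used components.
#'
#' @param qr_spec The processed QR spectrum.
#' @param qr A [qr_standard()] tibble.
#' @param acq_qr Acquisition parameters of the QR experiment (defaults to the
#'   spectrum's own).
#' @param components Which components to use (default both; the acceptance
#'   round trips use a single component).
#' @return An object of class `eretic_factor`: `value`, `component_values`,
#'   `areas`, `acq_qr`.
#' @export
compute_eretic_factor <- function(qr_spec, qr = qr_standard(),
                                  acq_qr = qr_spec$acq,
                                  components = qr$component) {
  stopifnot(inherits(qr_spec, "nmr_spectrum"))
  check_qr(qr)
  qr <- qr[qr$component %in% components, ]
  if (!nrow(qr)) stop("no QR components selected", call. = FALSE)
  areas <- vapply(seq_len(nrow(qr)), function(k) {
    integrate_window(qr_spec,
      high_ppm = qr$range_high_ppm[k],
      low_ppm = qr$range_low_ppm[k]
    )
  }, numeric(1))
  if (any(areas <= 0)) {
    stop("QR signal area is non-positive; cannot derive an ERETIC factor",
      call. = FALSE
    )
  }
  fc <- (areas * qr$kappa * acq_qr$p1_us) /
    (qr$n_protons * (qr$mass_mg_l / qr$molar_mass) * acq_qr$ns * acq_qr$rg)
  structure(
    list(
      value = mean(fc),
      component_values = stats::setNames(fc, qr$component),
      areas = stats::setNames(areas, qr$component),
      acq_qr = acq_qr
    ),
    class = "eretic_factor"
  )
}

#' @export
print.eretic_factor <- function(x, ...) {
  cat("<eretic_factor> ", signif(x$value, 6), " (components: ",
    paste(sprintf("%s=%.5g", names(x$component_values), x$component_values),
      collapse = ", "
    ), ")\n",
    sep = ""
  )
  invisible(x)
}

#' PULCON mass concentration of an analyte signal
#'
#' Converts a signal area to the analyte's mass concentration in the sample
#' solution: `rho = (A * P1_s) / (f * n * NS_s * RG_s) * M` (mg/L, with mass
#' concentrations of the QR expressed in mg/L and molar masses in g/mol).
#' Valid only when sample and QR share the spectrometer context, enforced as
#' equal `sf_mhz` and equal temperature (everything is acquired at 300.0 K,
#' so the generic temperature ratio of PULCON drops out).
#'
#' @param area Signal area (same unit convention as the QR integration).
#' @param n_protons Number of protons behind the signal.
#' @param molar_mass Analyte molar mass, g/mol.
#' @param acq_sample Acquisition parameters of the sample experiment.
#' @param f An `eretic_factor` object.
#' @return Mass concentration in mg/L of sample solution.
#' @export
pulcon_mass_concentration <- function(area, n_protons, molar_mass,
                                      acq_sample, f) {
  stopifnot(inherits(f, "eretic_factor"), n_protons >= 1, molar_mass > 0)
  if (!isTRUE(all.equal(acq_sample$sf_mhz, f$acq_qr$sf_mhz))) {
    stop("PULCON requires the sample and QR spectrometer frequencies to match",
      call. = FALSE
    )
  }
  if (!isTRUE(all.equal(acq_sample$temperature_k, f$acq_qr$temperature_k))) {
    stop("PULCON requires equal sample and QR temperatures (300.0 K)",
      call. = FALSE
    )
  }
  (area * acq_sample$p1_us) / (f$value * n_protons * acq_sample$ns * acq_sample$rg) *
    molar_mass
}

#' Convert a solution concentration to an oil content
#'
#' `w = rho * V_total / m_sample` with `V_total = v_solvent + m_sample /
#' density`: the simplified conversion that neglects mixing volume
#' contraction, fixes the sample weight at 100 mg, and uses the average CBD
#' oil density of 0.89 g/mL. At the defaults 1 mg/L corresponds to
#' ~7.124 mg/kg.
#'
#' @param rho_mg_l Concentration in the sample solution, mg/L.
#' @param m_sample_mg Sample weight, mg.
#' @param v_solvent_ml Solvent volume, mL.
#' @param oil_density_g_ml Carrier-oil density, g/mL.
#' @return Content in mg/kg of sample.
#' @export
#' @examples
#' convert_to_mg_per_kg(100) # ~712.4
convert_to_mg_per_kg <- function(rho_mg_l, m_sample_mg = 100,
                                 v_solvent_ml = 0.6, oil_density_g_ml = 0.89) {
  if (m_sample_mg <= 0) stop("sample mass must be positive", call. = FALSE)
  stopifnot(v_solvent_ml > 0, oil_density_g_ml > 0)
  v_total_ml <- v_solvent_ml + (m_sample_mg / 1000) / oil_density_g_ml
  rho_mg_l * v_total_ml * 1000 / m_sample_mg
}

#' Quantify one QR component against the other's ERETIC factor
#'
#' Cross-wise control quantification of the external standard itself: the
#' component's signal range is integrated, its saturation is corrected by its
#' own kappa, and the PULCON relation is applied against an ERETIC factor
#' derived from the *other* component alone. On a correctly simulated or
#' measured QR this recovers the known mass concentrations (4662 mg/L TCNB,
#' 3506 mg/L EB).
#'
#' @param qr_spec The processed QR spectrum.
#' @param component `"tcnb"` or `"eb"`: the component to quantify.
#' @param qr A [qr_standard()] tibble.
#' @param acq Acquisition parameters (default: the spectrum's own).
#' @return Recovered mass concentration in mg/L.
#' @export
quantify_qr_component <- function(qr_spec, component, qr = qr_standard(),
                                  acq = qr_spec$acq) {
  stopifnot(component %in% qr$component)
  other <- setdiff(qr$component, component)
  f <- compute_eretic_factor(qr_spec, qr, acq, components = other)
  row <- qr[qr$component == component, ]
  area <- integrate_window(qr_spec,
    high_ppm = row$range_high_ppm,
    low_ppm = row$range_low_ppm
  )
  pulcon_mass_concentration(
    area * row$kappa, row$n_protons, row$molar_mass, acq, f
  )
}

#' Quantify every library signal of a processed sample spectrum
#'
#' Integrates (fixed windows) or line-fits (constrained doublets on a local
#' baseline) every quantification signal, converts areas to mg/L by the
#' PULCON relation and to mg/kg of oil, censors below-LOD analytes to exactly
#' 0 with a flag, marks values between LOD and LOQ as qualitative-only, and
#' aggregates: CBD as the mean of "CBD 1" (3.88 ppm) and "CBD 3" (4.63 ppm)
#' ("CBD 2" is reported for QC only), Delta9/Delta8-THC from the
#' swap-guarded doublet assignment, and CBN as the mean of its uncensored
#' signals.
#'
#' @param spec A processed sample spectrum.
#' @param f An `eretic_factor` from [compute_eretic_factor()].
#' @param library A [signal_library()] tibble.
#' @param acq_sample Acquisition parameters of the sample (default: the
#'   spectrum's own).
#' @param lod_table Optional tibble `label`, `lod_mg_kg`, `loq_mg_kg`
#'   overriding the library's censoring limits.
#' @param m_sample_mg,v_solvent_ml,oil_density_g_ml Conversion constants.
#' @param censor Apply below-LOD censoring.
#' @return A `quant_report`: list with `signals` (per-signal tibble),
#'   `analytes` (per-analyte tibble), `constants`, `eretic`.
#' @export
quantify_sample <- function(spec, f, library = signal_library("hemp"),
                            acq_sample = spec$acq, lod_table = NULL,
                            m_sample_mg = 100, v_solvent_ml = 0.6,
                            oil_density_g_ml = 0.89, censor = TRUE) {
  stopifnot(inherits(spec, "nmr_spectrum"), inherits(f, "eretic_factor"))
  matrix_kind <- library$matrix_kind[1]
  quant <- library[library$quantified, ]
  if (!is.null(lod_table)) {
    quant$lod_mg_kg <- NULL
    quant$loq_mg_kg <- NULL
    quant <- dplyr::left_join(quant, lod_table, by = "label")
  }
  drift <- estimate_hump_offset(spec)

  thc_rows <- quant[quant$analyte %in% c("delta9_thc", "delta8_thc"), ]
  other_rows <- quant[!quant$analyte %in% c("delta9_thc", "delta8_thc"), ]

  measure_row <- function(sig, drift_shift = 0) {
    if (sig$mode == "window") {
      tibble::tibble(
        label = sig$label, mode = "window",
        area = integrate_window(spec, sig), center_ppm = sig$center_ppm,
        converged = TRUE, flags = ""
      )
    } else {
      win <- c(sig$window_high, sig$window_low) + drift_shift
      fit <- fit_doublet_on_baseline(spec, sig, search_window = win)
      tibble::tibble(
        label = sig$label, mode = "linefit", area = fit$area,
        center_ppm = fit$center_ppm, converged = fit$converged,
        flags = fit$flags
      )
    }
  }

  res_other <- purrr::map_dfr(seq_len(nrow(other_rows)), function(k) {
    measure_row(other_rows[k, ])
  })
  # THC doublets: fit both targets around the drift-corrected windows, then
  # resolve the Delta9/Delta8 identities through the swap guard
  res_thc <- NULL
  if (nrow(thc_rows)) {
    fits <- find_thc_doublets(spec, thc_rows, drift_offset_ppm = drift)
    assigned <- assign_delta_thc(fits, matrix_kind, drift_offset_ppm = drift)
    res_thc <- purrr::map_dfr(seq_len(nrow(thc_rows)), function(k) {
      sig <- thc_rows[k, ]
      a <- assigned[assigned$analyte == sig$analyte, ]
      tibble::tibble(
        label = sig$label, mode = "linefit", area = a$area,
        center_ppm = a$center_ppm, converged = a$converged, flags = a$flags
      )
    })
  }
  res <- dplyr::bind_rows(res_other, res_thc)
  res <- dplyr::left_join(
    res,
    quant[, c(
      "label", "analyte", "n_protons", "molar_mass", "qc_only",
      "lod_mg_kg", "loq_mg_kg"
    )],
    by = "label"
  )
  res$mg_l <- vapply(seq_len(nrow(res)), function(k) {
    pulcon_mass_concentration(
      res$area[k], res$n_protons[k], res$molar_mass[k], acq_sample, f
    )
  }, numeric(1))
  res$mg_kg_raw <- convert_to_mg_per_kg(
    res$mg_l, m_sample_mg, v_solvent_ml, oil_density_g_ml
  )
  # censoring: below LOD -> exactly 0; LOD <= x < LOQ -> qualitative only
  res$censored <- censor & !is.na(res$lod_mg_kg) & res$mg_kg_raw < res$lod_mg_kg
  res$qualitative <- !res$censored & censor & !is.na(res$loq_mg_kg) &
    res$mg_kg_raw < res$loq_mg_kg
  res$mg_kg <- ifelse(res$censored, 0, res$mg_kg_raw)

  agg <- res[!res$qc_only, ] |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(
      mg_kg = if (all(.data$censored)) 0 else mean(.data$mg_kg[!.data$censored]),
      mg_l = if (all(.data$censored)) 0 else mean(.data$mg_l[!.data$censored]),
      n_signals_used = sum(!.data$censored),
      qualitative = !all(.data$censored) &&
        all(.data$qualitative[!.data$censored]),
      # assigned last: summarise evaluates sequentially and this name
      # shadows the per-signal column
      censored = all(.data$censored),
      .groups = "drop"
    )
  structure(
    list(
      signals = res,
      analytes = agg,
      constants = list(
        m_sample_mg = m_sample_mg, v_solvent_ml = v_solvent_ml,
        oil_density_g_ml = oil_density_g_ml,
        mg_kg_per_mg_l = convert_to_mg_per_kg(
          1, m_sample_mg, v_solvent_ml, oil_density_g_ml
        ),
        matrix_kind = matrix_kind, drift_offset_ppm = drift
      ),
      eretic = f$value
    ),
    class = "quant_report"
  )
}

#' @export
print.quant_report <- function(x, ...) {
  cat("<quant_report> (matrix: ", x$constants$matrix_kind, ")\n", sep = "")
  df <- as.data.frame(x$analytes)
  df$mg_kg <- signif(df$mg_kg, 3)
  df$mg_l <- signif(df$mg_l, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @rdname quantify_sample
#' @param x A `quant_report`.
#' @param ... Unused.
#' @method tidy quant_report
#' @export
tidy.quant_report <- function(x, ...) x$signals

#' @rdname quantify_sample
#' @method glance quant_report
#' @export
glance.quant_report <- function(x, ...) {
  tidyr::pivot_wider(x$analytes[, c("analyte", "mg_kg")],
    names_from = "analyte", values_from = "mg_kg"
  )
}

#' Control-sample check
#'
#' A control sample measured at the end of a series passes when its result
#' deviates from the mean of the precision measurements by no more than twice
#' their standard deviation.
#'
#' @param result Measured value of the control sample.
#' @param control_mean,control_sd Mean and standard deviation of the
#'   precision measurements (`control_sd > 0`).
#' @return `TRUE` (pass) or `FALSE` (fail), vectorized over `result`.
#' @export
control_sample_check <- function(result, control_mean, control_sd) {
  stopifnot(control_sd > 0)
  abs(result - control_mean) <= 2 * control_sd
}
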