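# Method-validation battery: calibration linearity, DIN 32645 detection and
# quantification limits, recovery, precision with a Shapiro-Wilk normality
# gate, sample stability, and regression comparison against a reference
# (LC-MS/MS) method.

#' Fit a calibration line
#'
#' Ordinary least squares of signal area against target concentration, with
#' the process statistics of the calibration-line method: residual standard
#' deviation `s_y`, process standard deviation `s_x0 = s_y / slope`, and the
#' procedural coefficient of variation `V_x0 = 100 * s_x0 / mean(x)`.
#'
#' @param points A data frame with columns `x` (concentration, mg/L) and `y`
#'   (area); or two numeric vectors via `x`/`y`.
#' @param x,y Alternative numeric-vector interface.
#' @param r_min Correlation threshold below which the fit is flagged
#'   non-linear (0.997 is the acceptance criterion of the method).
#' @return A `qnmr_calibration` object.
#' @export
#' @examples
#' fit <- fit_calibration(x = c(140, 420, 700, 980, 1260),
#'                        y = c(1.4, 4.2, 7.0, 9.8, 12.6))
#' glance(fit)
fit_calibration <- function(points = NULL, x = NULL, y = NULL, r_min = 0.997) {
  if (!is.null(points)) {
    x <- points$x %||% points$level_mg_l
    y <- points$y %||% points$area
  }
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 calibration points", call. = FALSE)
  if (length(unique(x)) < 2) {
    stop("degenerate calibration: all concentrations equal", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  n <- length(x)
  s_y <- sqrt(sum(stats::resid(fit)^2) / (n - 2))
  r <- stats::cor(x, y)
  x_bar <- mean(x)
  q_x <- sum((x - x_bar)^2)
  s_x0 <- if (slope != 0) s_y / abs(slope) else Inf
  cv <- 100 * s_x0 / x_bar
  structure(
    list(
      slope = slope, intercept = intercept, pearson_r = r,
      s_y = s_y, s_x0 = s_x0, cv_percent = cv,
      n = n, x_bar = x_bar, q_x = q_x,
      linear = is.finite(r) && r >= r_min,
      x = x, y = y, lm = fit
    ),
    class = "qnmr_calibration"
  )
}

#' @export
print.qnmr_calibration <- function(x, ...) {
  cat("<qnmr_calibration> n=", x$n,
    ", slope=", signif(x$slope, 5),
    ", r=", signif(x$pearson_r, 5),
    ", s_x0=", signif(x$s_x0, 4),
    " (CV ", signif(x$cv_percent, 3), "%)",
    if (!x$linear) " [flag: non-linear]", "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname fit_calibration
#' @method tidy qnmr_calibration
#' @export
tidy.qnmr_calibration <- function(x, ...) {
  se <- suppressWarnings(summary(x$lm)$coefficients[, "Std. Error"])
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = unname(se)
  )
}

#' @rdname fit_calibration
#' @method glance qnmr_calibration
#' @export
glance.qnmr_calibration <- function(x, ...) {
  tibble::tibble(
    n = x$n, slope = x$slope, intercept = x$intercept,
    pearson_r = x$pearson_r, s_y = x$s_y, s_x0 = x$s_x0,
    cv_percent = x$cv_percent, linear = x$linear
  )
}

#' @rdname fit_calibration
#' @param object A `qnmr_calibration`.
#' @param ... Unused.
#' @method autoplot qnmr_calibration
#' @export
autoplot.qnmr_calibration <- function(object, ...) {
  df <- tibble::tibble(x = object$x, y = object$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept,
      linetype = 2
    ) +
    ggplot2::labs(
      x = "concentration (mg/L)", y = "signal area (a.u.)",
      subtitle = sprintf(
        "r = %.5f, V_x0 = %.2f %%",
        object$pearson_r, object$cv_percent
      )
    ) +
    ggplot2::theme_minimal()
}

#' Detection and quantification limits (calibration-line method, DIN 32645)
#'
#' `LOD = s_x0 * t(f, 1 - alpha_lod) * sqrt(1/m + 1/n + x_bar^2 / Q_x)` with
#' `f = n - 2` degrees of freedom, and the LOQ solved by fixed-point
#' iteration from
#' `LOQ = k * s_x0 * t(f, 1 - alpha_loq) * sqrt(1/m + 1/n + (LOQ - x_bar)^2 / Q_x)`
#' starting at `3 * LOD` (k = 3, tolerance 1e-6, at most 100 iterations).
#' One-sided t quantiles at significance 0.05 (LOD) and 0.025 (LOQ).
#'
#' @param fit A `qnmr_calibration` from [fit_calibration()].
#' @param m_replicates Number of replicate analyses of the future sample.
#' @param alpha_lod,alpha_loq Significance levels.
#' @param k Relative result-uncertainty factor of the LOQ (k = 3 means 33 %).
#' @return A tibble with `lod`, `loq`, `alpha_lod`, `alpha_loq`, `k`, `dof`,
#'   `ratio` (LOQ/LOD), in the units of `x`.
#' @export
lod_loq_din32645 <- function(fit, m_replicates = 1,
                             alpha_lod = 0.05, alpha_loq = 0.025, k = 3) {
  stopifnot(inherits(fit, "qnmr_calibration"))
  dof <- fit$n - 2
  if (dof < 1) stop("need at least 3 calibration points (dof >= 1)", call. = FALSE)
  base <- 1 / m_replicates + 1 / fit$n
  if (fit$s_y == 0) {
    return(tibble::tibble(
      lod = 0, loq = 0, alpha_lod = alpha_lod, alpha_loq = alpha_loq,
      k = k, dof = dof, ratio = NA_real_
    ))
  }
  t_lod <- stats::qt(1 - alpha_lod, dof)
  t_loq <- stats::qt(1 - alpha_loq, dof)
  lod <- fit$s_x0 * t_lod * sqrt(base + fit$x_bar^2 / fit$q_x)
  loq <- 3 * lod
  for (i in seq_len(100)) {
    loq_new <- k * fit$s_x0 * t_loq *
      sqrt(base + (loq - fit$x_bar)^2 / fit$q_x)
    if (abs(loq_new - loq) < 1e-6) {
      loq <- loq_new
      break
    }
    loq <- loq_new
    if (i == 100) {
      stop(sprintf(
        "LOQ fixed-point iteration did not converge (last value %.6g)", loq
      ), call. = FALSE)
    }
  }
  tibble::tibble(
    lod = lod, loq = loq, alpha_lod = alpha_lod, alpha_loq = alpha_loq,
    k = k, dof = dof, ratio = loq / lod
  )
}

#' Spike recovery
#'
#' `100 * (measured - blank) / spiked` percent, the recovery after blank
#' subtraction.
#'
#' @param measured Measured content of the spiked sample.
#' @param blank Blank (unspiked) content.
#' @param spiked Spiked amount (> 0), same units.
#' @return Recovery in percent (vectorized).
#' @export
#' @examples
#' compute_recovery(1058.4, 0, 1260) # 84
compute_recovery <- function(measured, blank, spiked) {
  if (any(spiked <= 0)) stop("spiked amount must be positive", call. = FALSE)
  100 * (measured - blank) / spiked
}

#' Precision as a coefficient of variation with a normality gate
#'
#' A Shapiro-Wilk test (default 95 % certainty) is applied first; the CV
#' (`100 * sd / mean`) is always reported, flagged unreliable when the
#' normality gate fails.
#'
#' @param values Replicate measurements (n >= 3, non-zero mean).
#' @param gate_alpha Significance level of the Shapiro-Wilk gate.
#' @return A tibble: `cv_percent`, `normality_pass`, `shapiro_p`, `n`.
#' @export
precision_cv <- function(values, gate_alpha = 0.05) {
  if (length(values) < 3) stop("need at least 3 replicates", call. = FALSE)
  if (mean(values) == 0) stop("mean of replicates is zero", call. = FALSE)
  if (stats::sd(values) == 0) {
    return(tibble::tibble(
      cv_percent = 0, normality_pass = TRUE, shapiro_p = NA_real_,
      n = length(values)
    ))
  }
  sw <- stats::shapiro.test(values)
  tibble::tibble(
    cv_percent = 100 * stats::sd(values) / mean(values),
    normality_pass = sw$p.value >= gate_alpha,
    shapiro_p = sw$p.value,
    n = length(values)
  )
}

#' Stability of a repeatedly measured control sample
#'
#' The control sample is re-measured over a period of up to 60 h; a signal is
#' stable when its maximum relative drift from the initial value stays within
#' twice the measurement CV.
#'
#' @param times_h Measurement times in hours (>= 3 points).
#' @param areas Signal areas (or contents) at those times; a matrix or data
#'   frame with one column per signal is accepted.
#' @param tolerance_percent Measurement CV in percent.
#' @return A tibble per signal: `signal`, `max_drift_percent`, `pass`.
#' @export
stability_check <- function(times_h, areas, tolerance_percent = 1) {
  if (length(times_h) < 3) stop("need at least 3 time points", call. = FALSE)
  if (any(times_h < 0) || max(times_h) > 60) {
    warning("stability was assessed for measurement periods up to 60 h")
  }
  areas <- as.data.frame(areas)
  if (nrow(areas) != length(times_h)) {
    stop("areas must have one row per time point", call. = FALSE)
  }
  purrr::map_dfr(names(areas), function(sig) {
    v <- areas[[sig]]
    drift <- 100 * abs(v - v[1]) / abs(v[1])
    tibble::tibble(
      signal = sig,
      max_drift_percent = max(drift),
      pass = max(drift) <= 2 * tolerance_percent
    )
  })
}

#' Compare NMR results against a reference method
#'
#' Linear regression `y = a * x + b` of the NMR results on the reference
#' (LC-MS/MS) results for all samples whose reference content exceeds the
#' NMR detection limit. Outliers are flagged by externally studentized
#' residual and the regression is reported both with and without them (never
#' silently dropped); a paired two-sided t-test on the differences judges
#' systematic deviation at 95 % confidence; per-sample relative deviations
#' are returned.
#'
#' @param pairs A data frame with columns `nmr` and `ref` (mg/kg); an
#'   optional `sample_id` column is carried through.
#' @param lod Detection limit used to filter pairs (on the reference value).
#' @param outlier_threshold Studentized-residual magnitude above which a pair
#'   is an outlier.
#' @param conf_level Confidence level of the t-test.
#' @return A `qnmr_comparison` object.
#' @export
compare_with_reference <- function(pairs, lod = 0, outlier_threshold = 3,
                                   conf_level = 0.95) {
  stopifnot(all(c("nmr", "ref") %in% names(pairs)))
  pairs <- tibble::as_tibble(pairs)
  if (!"sample_id" %in% names(pairs)) {
    pairs$sample_id <- seq_len(nrow(pairs))
  }
  used <- pairs[pairs$ref > lod, ]
  if (nrow(used) < 3) {
    stop("fewer than 3 pairs above the detection limit", call. = FALSE)
  }
  fit_all <- stats::lm(nmr ~ ref, data = used)
  rs <- stats::rstudent(fit_all)
  used$outlier <- is.finite(rs) & abs(rs) > outlier_threshold
  clean <- used[!used$outlier, ]
  fit_clean <- if (nrow(clean) >= 3 && any(used$outlier)) {
    stats::lm(nmr ~ ref, data = clean)
  } else {
    fit_all
  }
  diffs <- clean$nmr - clean$ref
  tt <- if (stats::sd(diffs) < .Machine$double.eps^0.5 * max(1, mean(abs(clean$ref)))) {
    # identical methods: no scatter to test against
    list(statistic = c(t = 0), p.value = 1)
  } else {
    stats::t.test(clean$nmr, clean$ref, paired = TRUE, conf.level = conf_level)
  }
  used$relative_deviation_percent <- 100 * used$nmr / used$ref
  mk <- function(fit, d) {
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      pearson_r = stats::cor(d$ref, d$nmr),
      n = nrow(d)
    )
  }
  structure(
    list(
      all = mk(fit_all, used),
      clean = mk(fit_clean, clean),
      outliers = used$sample_id[used$outlier],
      n_pairs = nrow(used),
      n_excluded_below_lod = nrow(pairs) - nrow(used),
      t_statistic = unname(tt$statistic),
      t_p_value = tt$p.value,
      systematic_difference = tt$p.value < (1 - conf_level),
      pairs = used
    ),
    class = "qnmr_comparison"
  )
}

#' @export
print.qnmr_comparison <- function(x, ...) {
  cat("<qnmr_comparison> n=", x$n_pairs,
    " (", length(x$outliers), " outlier(s): ",
    paste(x$outliers, collapse = ", "), ")\n",
    "  cleaned fit: a=", signif(x$clean$slope, 5),
    ", b=", signif(x$clean$intercept, 5),
    ", r=", signif(x$clean$pearson_r, 5), "\n",
    "  paired t-test p=", signif(x$t_p_value, 3),
    if (x$systematic_difference) {
      " -> systematic difference"
    } else {
      " -> no systematic difference (95 %)"
    }, "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname compare_with_reference
#' @param x A `qnmr_comparison`.
#' @param ... Unused.
#' @method tidy qnmr_comparison
#' @export
tidy.qnmr_comparison <- function(x, ...) x$pairs

#' @rdname compare_with_reference
#' @method glance qnmr_comparison
#' @export
glance.qnmr_comparison <- function(x, ...) {
  tibble::tibble(
    slope = x$clean$slope, intercept = x$clean$intercept,
    pearson_r = x$clean$pearson_r, n = x$clean$n,
    n_outliers = length(x$outliers),
    t_p_value = x$t_p_value,
    systematic_difference = x$systematic_difference
  )
}
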