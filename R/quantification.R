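#' Spectrometer sensitivity from the free-EDTA reference peak
#'
#' Sensitivity of a spectrometer operating at field f: the integral of
#' the reference free-EDTA peak divided by the spectral noise,
#' `S_f = Int_EDTA,peak1,f / sigma_f`. Dimensionless up to the ppm unit
#' of the integral; only ratios `S_ref / S_f` enter the normalization,
#' so any common unit cancels.
#'
#' @param edta_ref_integral reference free-EDTA peak integral
#'   (intensity x ppm).
#' @param noise_sigma spectral noise sd (intensity units), `> 0`.
#' @return scalar sensitivity.
#' @export
spectrometer_sensitivity <- function(edta_ref_integral, noise_sigma) {
  if (!is.finite(noise_sigma) || noise_sigma <= 0) {
    stop("noise_sigma must be > 0")
  }
  edta_ref_integral / noise_sigma
}

#' Field-normalized integral of a metal-EDTA complex
#'
#' `I_norm = (Int_M / Int_EDTA,peak1) * (S_ref / S_f)`: the complex
#' integral scaled by the free-EDTA reference integral of the same
#' spectrometer and by the sensitivity ratio to the reference field,
#' making one calibration curve per ion valid across spectrometers.
#'
#' @param metal_integral deconvoluted complex integral (intensity x ppm).
#' @param edta_ref_integral reference free-EDTA integral at the same
#'   field (intensity x ppm), `> 0`.
#' @param s_ref sensitivity of the reference spectrometer.
#' @param s_f sensitivity of the measuring spectrometer, `> 0`.
#' @return scalar normalized integral (dimensionless).
#' @export
normalized_integral <- function(metal_integral, edta_ref_integral,
                                s_ref, s_f) {
  if (!is.finite(edta_ref_integral) || edta_ref_integral <= 0) {
    stop("edta_ref_integral must be > 0")
  }
  if (!is.finite(s_f) || s_f <= 0) stop("s_f must be > 0")
  (metal_integral / edta_ref_integral) * (s_ref / s_f)
}

#' Measure the per-field free-EDTA reference quantities
#'
#' From a metal-free EDTA reference spectrum acquired on a given
#' spectrometer, fits the reference free-EDTA singlet (the template
#' flagged `reference = TRUE`), estimates the noise, and returns the
#' reference integral and instrument sensitivity that normalize all
#' sample integrals measured at that field.
#'
#' @param spectrum the reference [nmr_spectrum()] (EDTA in buffer, no
#'   metal ions).
#' @param templates template database, default [default_templates()].
#' @param search_ppm half-width of the search window around the
#'   template's default center (ppm), default 0.1.
#' @return list of class `field_reference`: `field_mhz`, `ref_integral`,
#'   `noise_sigma`, `sensitivity`, `line_width_ppm`, `center`.
#' @export
measure_field_reference <- function(spectrum,
                                    templates = default_templates(),
                                    search_ppm = 0.1) {
  ref_tpl <- Filter(function(t) isTRUE(t$reference), templates)[[1]]
  sigma <- estimate_noise(spectrum)
  lw_def <- 1.5 / spectrum$field_mhz
  pk <- assign_peak(spectrum, ref_tpl$default_center,
                    window_lw = 2 * search_ppm / lw_def,
                    line_width_ppm = lw_def, noise_sigma = sigma)
  if (pk$status != "assigned") {
    stop("free-EDTA reference peak not found in the reference spectrum")
  }
  lw <- measure_linewidth(spectrum, pk$delta)
  if (!is.finite(lw) || lw <= 0) lw <- lw_def
  fit <- fit_spin_system(spectrum, ref_tpl, pk$delta, lw, sigma)
  if (fit$status == "fit_failure") stop("reference free-EDTA fit failed")
  structure(list(field_mhz = spectrum$field_mhz,
                 ref_integral = fit$integral, noise_sigma = sigma,
                 sensitivity = spectrometer_sensitivity(fit$integral, sigma),
                 line_width_ppm = lw, center = fit$center),
            class = "field_reference")
}

#' Fit a universal calibration curve for one ion
#'
#' OLS fit of known concentration on normalized integral,
#' `C_M = a_M * I_norm + b_M`, with the 95% confidence interval of the
#' intercept and a flag for whether the curve passes statistically
#' through the origin.
#'
#' @param concentrations known ion concentrations (mM), `>= 3` values
#'   spanning a non-zero range.
#' @param norm_integrals matching normalized integrals.
#' @param ion ion label (`"ca"`, `"mg"`, `"zn"`, ...).
#' @param s_ref reference sensitivity recorded with the curve.
#' @return object of class `calibration_curve`: `ion`, `slope`,
#'   `intercept`, `intercept_ci95`, `through_origin`, `s_ref`,
#'   `n_points`, `r_squared`, `residual_sd`.
#' @export
fit_calibration <- function(concentrations, norm_integrals, ion = "ion",
                            s_ref = NA_real_) {
  if (length(concentrations) != length(norm_integrals) ||
      length(concentrations) < 3) {
    stop("need >= 3 calibration points")
  }
  if (stats::var(norm_integrals) == 0) {
    stop("degenerate calibration design: constant normalized integrals")
  }
  fit <- stats::lm(concentrations ~ norm_integrals)
  # confint on an exactly collinear calibration warns about the perfect
  # fit; the zero-width interval it returns is the right answer
  ci <- suppressWarnings(stats::confint(fit, level = 0.95)[1, ])
  res <- stats::residuals(fit)
  sst <- sum((concentrations - mean(concentrations))^2)
  structure(list(ion = ion,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 intercept_ci95 = unname(ci),
                 through_origin = ci[1] <= 0 && ci[2] >= 0,
                 s_ref = s_ref, n_points = length(concentrations),
                 r_squared = if (sst > 0) 1 - sum(res^2) / sst else 1,
                 residual_sd = stats::sd(res)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve %s: C = %.4g * I + %.4g, intercept CI95 [%.4g, %.4g]%s, n %d>\n",
              x$ion, x$slope, x$intercept, x$intercept_ci95[1],
              x$intercept_ci95[2],
              if (x$through_origin) " (through origin)" else "",
              x$n_points))
  invisible(x)
}

#' Write / read calibration curves as JSON
#'
#' @param curves named list of [fit_calibration()] results.
#' @param path JSON file path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` the named list.
#' @export
write_calibration <- function(curves, path) {
  jsonlite::write_json(lapply(curves, unclass), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(x) structure(x, class = "calibration_curve"))
}

# singlet used for each ion's quantification
ion_species <- c(ca = "ca_edta_singlet", mg = "mg_edta_singlet",
                 zn = "zn_edta_singlet")

#' Quantify ion concentrations from deconvoluted fits
#'
#' Converts each ion's deconvoluted EDTA-complex singlet integral into a
#' normalized integral (against the per-field free-EDTA reference) and
#' then into an absolute concentration through that ion's universal
#' calibration curve, propagating the integral uncertainty through the
#' linear map. Species below detection are reported as such, not as
#' 0 mM; concentrations below the curve's LOD (when `lod` is present on
#' the curve) are flagged `below_LOD`.
#'
#' @param fits named list of `fitted_system` objects from
#'   [deconvolute_all()].
#' @param curves named list of [fit_calibration()] curves (names `ca`,
#'   `mg`, `zn`).
#' @param reference the [measure_field_reference()] result for the
#'   spectrometer that produced the sample spectrum.
#' @param s_ref reference sensitivity; defaults to the first curve's
#'   recorded `s_ref`, falling back to the reference's own sensitivity.
#' @param noise_sigma per-sample noise sd. The per-spectrum sensitivity
#'   `S_f` is the per-field reference integral over *this* spectrum's
#'   noise, so noise-level fluctuations enter as per-sample scatter
#'   rather than as a per-spectrometer bias; when `NA`, the reference
#'   acquisition's own sensitivity is used.
#' @param label sample label.
#' @return data.frame of class `quant_report`: one row per ion with
#'   `sample`, `ion`, `integral`, `i_norm`, `conc_mM`, `uncertainty_mM`,
#'   `status`; attributes `s_f`, `sigma_f`, `edta_ref_integral` (the
#'   per-field reference) and `free_edta_integral` (in-sample).
#' @export
quantify_ions <- function(fits, curves, reference, s_ref = NULL,
                          noise_sigma = NA_real_, label = "sample") {
  if (is.null(fits$free_edta_1) || fits$free_edta_1$status == "fit_failure") {
    stop("free-EDTA reference fit missing or failed for this sample")
  }
  s_ref <- s_ref %||% curves[[1]]$s_ref
  if (is.null(s_ref) || !is.finite(s_ref)) s_ref <- reference$sensitivity
  s_f <- if (is.finite(noise_sigma) && noise_sigma > 0) {
    spectrometer_sensitivity(reference$ref_integral, noise_sigma)
  } else {
    reference$sensitivity
  }
  rows <- lapply(names(ion_species), function(ion) {
    sp <- ion_species[[ion]]
    fit <- fits[[sp]]
    curve <- curves[[ion]]
    if (is.null(fit) || is.null(curve)) {
      stop("missing fit or calibration curve for ion '", ion, "'")
    }
    if (fit$status == "below_detection") {
      return(data.frame(sample = label, ion = ion, integral = 0,
                        i_norm = NA_real_, conc_mM = NA_real_,
                        uncertainty_mM = NA_real_,
                        status = "below_detection",
                        stringsAsFactors = FALSE))
    }
    inorm <- normalized_integral(fit$integral, reference$ref_integral,
                                 s_ref, s_f)
    conc <- curve$slope * inorm + curve$intercept
    unc <- if (is.finite(fit$uncertainty)) {
      abs(curve$slope) * (fit$uncertainty / reference$ref_integral) *
        (s_ref / s_f)
    } else NA_real_
    status <- fit$status
    if (!is.null(curve$lod) && is.finite(curve$lod) && conc < curve$lod) {
      status <- "below_LOD"
    }
    data.frame(sample = label, ion = ion, integral = fit$integral,
               i_norm = inorm, conc_mM = conc, uncertainty_mM = unc,
               status = status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "s_f") <- s_f
  attr(out, "sigma_f") <- noise_sigma
  attr(out, "edta_ref_integral") <- reference$ref_integral
  attr(out, "free_edta_integral") <- fits$free_edta_1$integral
  class(out) <- c("quant_report", class(out))
  out
}

#' Extra-sum-of-squares F-test of regression coincidence
#'
#' Tests whether two calibration/validation point sets share one
#' regression line (pooled single-line model vs separate per-cohort
#' lines), or whether a point set is consistent with a fixed reference
#' line such as the 1:1 identity. Used to show that curves measured on
#' different spectrometers coincide after normalization.
#'
#' @param x1,y1 cohort 1 pairs (`>= 3` points).
#' @param x2,y2 cohort 2 pairs, or `NULL` when testing only against
#'   `reference`.
#' @param reference optional fixed line `c(intercept, slope)` (the 1:1
#'   line is `c(0, 1)`). With two cohorts the pooled data are tested
#'   against it; with one cohort that cohort is.
#' @return list with `f`, `df1`, `df2`, `p_value`, `rss_full`,
#'   `rss_reduced`, `comparison`.
#' @export
regression_coincidence_test <- function(x1, y1, x2 = NULL, y2 = NULL,
                                        reference = NULL) {
  rss_line <- function(x, y) sum(stats::residuals(stats::lm(y ~ x))^2)
  if (length(x1) < 3 || stats::var(x1) == 0) {
    stop("cohort 1 is degenerate (need >= 3 points with spread)")
  }
  if (!is.null(x2)) {
    if (length(x2) < 3 || stats::var(x2) == 0) {
      stop("cohort 2 is degenerate (need >= 3 points with spread)")
    }
  }
  if (is.null(reference)) {
    if (is.null(x2)) stop("need either a second cohort or a reference line")
    rss_full <- rss_line(x1, y1) + rss_line(x2, y2)
    x <- c(x1, x2); y <- c(y1, y2)
    rss_red <- rss_line(x, y)
    df1 <- 2L
    df2 <- length(x) - 4L
    comparison <- "pooled line vs separate lines"
  } else {
    x <- c(x1, x2); y <- c(y1, y2)
    rss_full <- rss_line(x, y)
    rss_red <- sum((y - (reference[1] + reference[2] * x))^2)
    df1 <- 2L
    df2 <- length(x) - 2L
    comparison <- "fixed reference line vs fitted line"
  }
  if (df2 < 1) stop("not enough points for the F-test")
  f <- max((rss_red - rss_full) / df1, 0) / (rss_full / df2)
  list(f = f, df1 = df1, df2 = df2,
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
       rss_full = rss_full, rss_reduced = rss_red,
       comparison = comparison)
}

#' Detection limits and spike recovery
#'
#' ICH-style limits on the `C = a * I + b` calibration
#' parameterization: `LOD = 3.3 * blank_sd * a`, `LOQ = 10 * blank_sd *
#' a`, with `blank_sd` the standard deviation of the blank's normalized
#' integral; spike recovery is `100 * (spiked - base) / added`.
#'
#' @param curve a [fit_calibration()] curve.
#' @param blank_sd blank variability in normalized-integral units.
#' @param spiked measured concentration after spiking (mM).
#' @param base measured concentration before spiking (mM).
#' @param added spiked-in concentration (mM), `> 0`.
#' @return list with `lod_mM`, `loq_mM`, `recovery_pct`.
#' @export
lod_loq_recovery <- function(curve, blank_sd, spiked = NA_real_,
                             base = NA_real_, added = NA_real_) {
  if (!is.finite(curve$slope) || curve$slope <= 0) {
    stop("calibration slope must be > 0")
  }
  lod <- 3.3 * blank_sd * curve$slope
  loq <- 10 * blank_sd * curve$slope
  rec <- NA_real_
  if (is.finite(spiked) || is.finite(added)) {
    if (!is.finite(added) || added <= 0) stop("added must be > 0")
    rec <- 100 * (spiked - base) / added
  }
  list(lod_mM = lod, loq_mM = loq, recovery_pct = rec)
}
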