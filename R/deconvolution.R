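#' Fit a template-constrained Voigt model to one spin system
#'
#' Nonlinear least squares over a local fit region (template span plus
#' three line widths on each side). Free parameters: the overall area, a
#' small center shift (bounded by half a line width -- the assignment
#' already localized the system), a shared width scale applied to both
#' Voigt width components, and a local linear baseline. Component
#' offsets and area ratios are fixed by the template, so fitted
#' component areas keep the template ratios exactly.
#'
#' The integral uncertainty is a white-noise propagation of the fit
#' residuals: residual rms x sqrt(region width x point spacing).
#'
#' @param spectrum an [nmr_spectrum()].
#' @param template a [spin_system()].
#' @param assigned_delta assigned system center (ppm).
#' @param line_width_ppm line width (FWHM, ppm) used for widths, bounds
#'   and the fit-region margin.
#' @param noise_sigma optional noise sd stored for diagnostics.
#' @param exclude optional list of `(low, high)` ppm intervals masked
#'   from the residual (used when a known foreign signal -- e.g. the
#'   Zn-EDTA singlet inside the asparagine multiplet -- sits inside the
#'   fit region and must not bias the fit).
#' @return an object of class `fitted_system`: `species`, `peaks` (list
#'   of [voigt_peak()]), `integral`, `uncertainty`, `residual_rms`,
#'   `center`, `width_scale`, `baseline` (c(b0, b1) about the region
#'   midpoint), `region`, `status` (`"ok"`, `"clipped"` or
#'   `"fit_failure"`), `diagnostics`.
#' @export
fit_spin_system <- function(spectrum, template, assigned_delta,
                            line_width_ppm, noise_sigma = NA_real_,
                            exclude = NULL) {
  span <- template_span_ppm(template, spectrum$field_mhz)
  region <- c(assigned_delta + span[1] - 3 * line_width_ppm,
              assigned_delta + span[2] + 3 * line_width_ppm)
  rng <- range(spectrum$ppm_axis)
  if (region[1] < rng[1] || region[2] > rng[2]) {
    stop("fit region lies outside the spectrum axis")
  }
  reg <- spectrum_region(spectrum, region)
  x <- reg$ppm; yobs <- reg$intensity
  wts <- rep(1, length(x))
  for (ex in exclude %||% list()) {
    wts[x >= min(ex) & x <= max(ex)] <- 0
  }
  if (sum(wts > 0) < 8) stop("fit region almost fully masked")
  mid <- mean(region)
  dx <- ppm_spacing(spectrum)
  # initial Voigt widths from the package-wide lineshape convention
  w0 <- voigt_widths_from_fwhm(line_width_ppm)
  gl0 <- w0$gamma_l
  sg0 <- max(w0$sigma_g, 1e-6)
  model_fun <- function(p) {
    y <- p[4] + p[5] * (x - mid)
    for (i in seq_along(template$offsets_hz)) {
      pk <- voigt_peak(assigned_delta + p[2] +
                         template$offsets_hz[i] / spectrum$field_mhz,
                       sg0 * p[3], gl0 * p[3],
                       max(p[1], 0) * template$ratios[i])
      y <- y + voigt_profile(x, pk)
    }
    y
  }
  b0_start <- stats::median(c(utils::head(yobs, 5), utils::tail(yobs, 5)))
  a_start <- max(sum(yobs - b0_start) * dx, 0)
  start <- c(area = a_start, shift = 0, wscale = 1, b0 = b0_start, b1 = 0)
  lower <- c(0, -0.5 * line_width_ppm, 0.4, -Inf, -Inf)
  upper <- c(Inf, 0.5 * line_width_ppm, 2.5, Inf, Inf)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = function(p) wts * (model_fun(p) - yobs),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error") ||
      !fit$info %in% c(1, 2, 3, 4)) {
    msg <- if (inherits(fit, "error")) conditionMessage(fit) else fit$message
    return(structure(list(species = template$species, peaks = list(),
                          integral = NA_real_, uncertainty = NA_real_,
                          residual_rms = NA_real_, center = assigned_delta,
                          width_scale = NA_real_, baseline = c(NA, NA),
                          region = region, status = "fit_failure",
                          noise_sigma = noise_sigma,
                          diagnostics = msg),
                     class = "fitted_system"))
  }
  p <- unname(fit$par)
  status <- "ok"
  if (p[1] < 0) { p[1] <- 0; status <- "clipped" }
  res <- (model_fun(p) - yobs)[wts > 0]
  rms <- sqrt(mean(res^2))
  width <- diff(region)
  unc <- rms * sqrt(width * dx)
  center <- assigned_delta + p[2]
  peaks <- lapply(seq_along(template$offsets_hz), function(i) {
    voigt_peak(center + template$offsets_hz[i] / spectrum$field_mhz,
               sg0 * p[3], gl0 * p[3], p[1] * template$ratios[i])
  })
  structure(list(species = template$species, peaks = peaks,
                 integral = p[1], uncertainty = unc, residual_rms = rms,
                 center = center, width_scale = unname(p[3]),
                 baseline = unname(p[4:5]), region = region,
                 status = status, noise_sigma = noise_sigma,
                 diagnostics = NULL),
            class = "fitted_system")
}

#' @export
print.fitted_system <- function(x, ...) {
  cat(sprintf("<fitted_system %s: integral %.4g +- %.3g, center %.4f ppm, %s>\n",
              x$species, x$integral, x$uncertainty, x$center, x$status))
  invisible(x)
}

# evaluate a fitted system's peaks (no baseline) on a ppm grid
evaluate_fitted_system <- function(fit, ppm) {
  y <- numeric(length(ppm))
  for (pk in fit$peaks) y <- y + voigt_profile(ppm, pk)
  y
}

#' Subtract the asparagine multiplet from a spectrum
#'
#' Fits the asparagine CH2 doublet-of-doublets template inside its
#' region and subtracts the fitted peaks (not the baseline), leaving all
#' other intensity untouched. When no asparagine signal rises three
#' noise standard deviations above the local background the input is
#' returned unchanged with `absent = TRUE` -- this is the correction that
#' unmasks the overlapping Zn-EDTA singlet.
#'
#' @param spectrum an [nmr_spectrum()].
#' @param asn_template the asparagine [spin_system()].
#' @param center asparagine system center (ppm; assigned or predicted).
#' @param line_width_ppm line width (FWHM, ppm).
#' @param noise_sigma noise sd; estimated from the default region when
#'   `NULL`.
#' @param exclude optional list of ppm intervals masked from the
#'   asparagine fit (typically the Zn-EDTA singlet window, so that the
#'   overlapping foreign peak does not inflate the asparagine model).
#' @return list with `spectrum` (corrected copy), `fit` (the
#'   `fitted_system` or `NULL`), `absent` (logical).
#' @export
subtract_asparagine <- function(spectrum, asn_template, center,
                                line_width_ppm, noise_sigma = NULL,
                                exclude = NULL) {
  if (is.null(noise_sigma)) noise_sigma <- estimate_noise(spectrum)
  span <- template_span_ppm(asn_template, spectrum$field_mhz)
  region <- c(center + span[1] - 3 * line_width_ppm,
              center + span[2] + 3 * line_width_ppm)
  idx <- region_indices(spectrum, region)
  if (length(idx) < 11) stop("asparagine region lies outside the axis")
  # detect on a lightly smoothed trace so the maximum of a few hundred
  # raw noise points does not masquerade as signal
  sm <- spectrum
  sm$intensity <- signal::sgolayfilt(spectrum$intensity, p = 3, n = 9)
  bg <- window_background(sm, idx)
  if (max(sm$intensity[idx] - bg) <= 3 * noise_sigma) {
    return(list(spectrum = spectrum, fit = NULL, absent = TRUE))
  }
  fit <- fit_spin_system(spectrum, asn_template, center, line_width_ppm,
                         noise_sigma, exclude = exclude)
  if (fit$status == "fit_failure") {
    return(list(spectrum = spectrum, fit = fit, absent = FALSE))
  }
  out <- spectrum
  out$intensity[idx] <- out$intensity[idx] -
    evaluate_fitted_system(fit, out$ppm_axis[idx])
  list(spectrum = out, fit = fit, absent = FALSE)
}

#' Deconvolute all assigned EDTA-related systems
#'
#' Fits the free-EDTA singlets, the Ca-EDTA singlet and AB quartet, the
#' Mg-EDTA singlet and -- after asparagine subtraction -- the Zn-EDTA
#' singlet and quartet. Species whose assignment status is
#' `below_detection` yield a zero integral flagged `below_detection`
#' rather than a fit.
#'
#' @param spectrum an [nmr_spectrum()].
#' @param assignments an `assignment_result` from [assign_all_species()].
#' @param templates template database, default [default_templates()].
#' @return named list of `fitted_system` objects (one per EDTA-related
#'   species, plus `asparagine_dd` when it was fitted for subtraction).
#' @export
deconvolute_all <- function(spectrum, assignments,
                            templates = default_templates()) {
  lw <- attr(assignments, "line_width_ppm")
  sigma <- attr(assignments, "noise_sigma")
  row_of <- function(sp) assignments[assignments$species == sp, , drop = FALSE]
  below <- function(sp) {
    r <- row_of(sp)
    nrow(r) == 0 || r$status == "below_detection"
  }
  out <- list()
  plain <- c("free_edta_1", "free_edta_2", "ca_edta_quartet",
             "ca_edta_singlet", "mg_edta_singlet")
  work <- spectrum
  for (sp in plain) {
    out[[sp]] <- if (below(sp)) {
      below_detection_fit(sp)
    } else {
      fit_spin_system(work, templates[[sp]], row_of(sp)$assigned, lw, sigma)
    }
  }
  # asparagine subtraction ahead of the Zn-EDTA systems
  asn_center <- if (!below("asparagine_dd")) row_of("asparagine_dd")$assigned
                else row_of("asparagine_dd")$predicted
  zn_row <- row_of("zn_edta_singlet")
  zn_pos <- if (nrow(zn_row) && is.finite(zn_row$assigned)) zn_row$assigned
            else if (nrow(zn_row)) zn_row$predicted else NA_real_
  zn_mask <- if (is.finite(zn_pos)) {
    list(c(zn_pos - 2.5 * lw, zn_pos + 2.5 * lw))
  } else NULL
  zn_spec <- work
  if (is.finite(asn_center)) {
    sub <- subtract_asparagine(work, templates$asparagine_dd, asn_center,
                               lw, sigma, exclude = zn_mask)
    zn_spec <- sub$spectrum
    if (!is.null(sub$fit)) out$asparagine_dd <- sub$fit
  }
  for (sp in c("zn_edta_singlet", "zn_edta_quartet")) {
    out[[sp]] <- if (below(sp)) {
      below_detection_fit(sp)
    } else {
      fit_spin_system(zn_spec, templates[[sp]], row_of(sp)$assigned, lw, sigma)
    }
  }
  out
}

below_detection_fit <- function(species) {
  structure(list(species = species, peaks = list(), integral = 0,
                 uncertainty = NA_real_, residual_rms = NA_real_,
                 center = NA_real_, width_scale = NA_real_,
                 baseline = c(NA, NA), region = c(NA, NA),
                 status = "below_detection", noise_sigma = NA_real_,
                 diagnostics = NULL),
            class = "fitted_system")
}
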