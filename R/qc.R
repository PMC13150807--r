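# smooth monotone cubic interpolation between two anchor levels
smoothstep_fill <- function(n, y_left, y_right) {
  t <- seq(0, 1, length.out = n)
  y_left + (y_right - y_left) * (3 * t^2 - 2 * t^3)
}

edta_targets <- function(mode) {
  free <- c("free_edta_1", "free_edta_2")
  if (mode == "free_only") free
  else c(free, "ca_edta_singlet", "ca_edta_quartet", "mg_edta_singlet",
         "zn_edta_singlet", "zn_edta_quartet")
}

# ppm interval spanned by a fitted system's components +- margin
fit_region_ppm <- function(fit, margin_ppm) {
  centers <- vapply(fit$peaks, `[[`, numeric(1), "center")
  c(min(centers) - margin_ppm, max(centers) + margin_ppm)
}

merge_intervals <- function(regions) {
  if (!length(regions)) return(list())
  m <- do.call(rbind, regions)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- list(m[1, ])
  for (i in seq_len(nrow(m))[-1]) {
    last <- out[[length(out)]]
    if (m[i, 1] <= last[2]) {
      out[[length(out)]] <- c(last[1], max(last[2], m[i, 2]))
    } else {
      out[[length(out) + 1L]] <- m[i, ]
    }
  }
  out
}

#' Remove EDTA-related signals with baseline reconstruction
#'
#' Replaces the region spanned by each targeted fitted system (plus a
#' three-line-width margin) with a smooth monotone cubic interpolant
#' through baseline anchors flanking the region (medians of 0.01 ppm
#' windows on each side). Targets are the free-EDTA singlets alone
#' (`mode = "free_only"`) or all free and metal-EDTA systems
#' (`mode = "all_edta"`). A targeted system whose region overlaps a
#' fitted non-target system (e.g. the Zn-EDTA singlet inside the
#' asparagine multiplet) is removed by subtracting its fitted model
#' instead of replacing the region, so the co-resonating metabolite
#' survives. Every point outside removed regions is bit-identical to
#' the input.
#'
#' @param spectrum an [nmr_spectrum()].
#' @param fits named list of `fitted_system` objects from
#'   [deconvolute_all()] (non-target entries, such as the asparagine
#'   fit, inform the overlap rule).
#' @param mode `"free_only"` or `"all_edta"`.
#' @param anchor_ppm width of the flanking anchor windows (ppm).
#' @param noise_sigma noise sd for the report's residual column and
#'   optional re-injection; estimated when `NULL`.
#' @param reinject_noise add white noise of sd `noise_sigma` to
#'   reconstructed regions (default FALSE: cleaned spectra are smooth).
#' @return list with `spectrum` (cleaned copy) and `report`, a
#'   `clean_report` list: `mode`, `removed_regions`, `subtracted`
#'   (species removed by model subtraction), `anchors`,
#'   `max_residual_sigma`.
#' @export
remove_edta_signals <- function(spectrum, fits,
                                mode = c("free_only", "all_edta"),
                                anchor_ppm = 0.01, noise_sigma = NULL,
                                reinject_noise = FALSE) {
  mode <- match.arg(mode)
  if (is.null(noise_sigma)) noise_sigma <- estimate_noise(spectrum)
  targets <- edta_targets(mode)
  margin <- 3 * default_clean_lw(spectrum, fits)
  present <- function(f) !is.null(f) && length(f$peaks) > 0 &&
    f$status %in% c("ok", "clipped")
  target_fits <- fits[intersect(targets, names(fits))]
  target_fits <- Filter(present, target_fits)
  other_fits <- fits[setdiff(names(fits), targets)]
  other_fits <- Filter(present, other_fits)
  out <- spectrum
  subtracted <- character(0)
  chop_regions <- list()
  chop_centers <- numeric(0)
  sub_resid <- numeric(0)
  for (sp in names(target_fits)) {
    fit <- target_fits[[sp]]
    region <- fit_region_ppm(fit, margin)
    overlaps <- any(vapply(other_fits, function(of) {
      r2 <- fit_region_ppm(of, 0)
      region[1] <= r2[2] && r2[1] <= region[2]
    }, logical(1)))
    if (overlaps) {
      idx <- region_indices(out, region)
      out$intensity[idx] <- out$intensity[idx] -
        evaluate_fitted_system(fit, out$ppm_axis[idx])
      subtracted <- c(subtracted, sp)
      sub_resid <- c(sub_resid, fit$residual_rms / noise_sigma)
    } else {
      chop_regions[[length(chop_regions) + 1L]] <- region
      chop_centers <- c(chop_centers,
                        vapply(fit$peaks, `[[`, numeric(1), "center"))
    }
  }
  chop_regions <- merge_intervals(chop_regions)
  anchors <- list()
  for (region in chop_regions) {
    idx <- region_indices(out, region)
    if (length(idx) < 2) next
    left_idx <- region_indices(out, c(region[2], region[2] + anchor_ppm))
    right_idx <- region_indices(out, c(region[1] - anchor_ppm, region[1]))
    left_idx <- setdiff(left_idx, idx)
    right_idx <- setdiff(right_idx, idx)
    y_left <- stats::median(out$intensity[left_idx])
    y_right <- stats::median(out$intensity[right_idx])
    fill <- smoothstep_fill(length(idx), y_left, y_right)
    if (reinject_noise && noise_sigma > 0) {
      fill <- fill + stats::rnorm(length(idx), 0, noise_sigma)
    }
    out$intensity[idx] <- fill
    anchors[[length(anchors) + 1L]] <- c(left = y_left, right = y_right)
  }
  # residual above local background at each chopped peak center; for
  # model-subtracted systems (which may sit inside foreign multiplets,
  # where a smooth-background reference is meaningless) the fit residual
  # rms quantifies what the removal left behind
  resid <- vapply(chop_centers, function(ct) {
    idx <- region_indices(out, c(ct - 0.01, ct + 0.01))
    if (length(idx) < 7) return(0)
    bg <- window_background(out, idx)
    k <- which.min(abs(out$ppm_axis[idx] - ct))
    (out$intensity[idx][k] - bg[k]) / noise_sigma
  }, numeric(1))
  resid <- c(resid, sub_resid)
  report <- structure(list(mode = mode, removed_regions = chop_regions,
                           subtracted = subtracted, anchors = anchors,
                           max_residual_sigma = if (length(resid)) max(abs(resid)) else 0),
                      class = "clean_report")
  list(spectrum = out, report = report)
}

# line width implied by the fitted peaks (fallback 1.5 Hz / field)
default_clean_lw <- function(spectrum, fits) {
  for (f in fits) {
    if (length(f$peaks)) {
      pk <- f$peaks[[1]]
      return(voigt_fwhm(pk$sigma_g, pk$gamma_l))
    }
  }
  1.5 / spectrum$field_mhz
}

#' Principal component scores of a binned spectral table
#'
#' Singular value decomposition of an already mean-centered
#' samples-by-bins matrix (see [bin_and_center()]); explained variance
#' per component in percent of total.
#'
#' @param binned mean-centered matrix, or the list returned by
#'   [bin_and_center()].
#' @param k number of components, `<= min(samples - 1, bins)`.
#' @return list with `scores` (samples x k), `loadings` (bins x k),
#'   `explained_variance` (length k, percent).
#' @export
pca_scores <- function(binned, k = 2L) {
  x <- if (is.list(binned) && !is.null(binned$matrix)) binned$matrix else binned
  x <- as.matrix(x)
  if (k > min(nrow(x) - 1L, ncol(x))) {
    stop("k exceeds min(samples - 1, bins)")
  }
  if (max(abs(colMeans(x))) > 1e-6 * max(abs(x), 1e-300)) {
    stop("matrix must be mean-centered (see bin_and_center)")
  }
  s <- svd(x)
  total <- sum(s$d^2)
  list(scores = s$u[, seq_len(k), drop = FALSE] %*%
         diag(s$d[seq_len(k)], k, k),
       loadings = s$v[, seq_len(k), drop = FALSE],
       explained_variance = 100 * s$d[seq_len(k)]^2 / total)
}

#' Feature-wise Pearson correlation against a target variable
#'
#' Pearson r of every feature column (binned or full-resolution) against
#' a per-sample target such as an independently measured ion
#' concentration; the feature map of where a quantity lives in the
#' spectrum.
#'
#' @param features samples x features matrix.
#' @param target per-sample values, non-zero variance, `>= 3` samples.
#' @return list with `r` (per feature; 0 for constant features) and
#'   `constant` (logical flag per feature).
#' @export
feature_correlation <- function(features, target) {
  x <- as.matrix(features)
  if (nrow(x) < 3) stop("need at least 3 samples")
  if (stats::var(target) == 0) stop("target has zero variance")
  sds <- apply(x, 2, stats::sd)
  const <- sds == 0
  r <- rep(0, ncol(x))
  if (any(!const)) {
    r[!const] <- drop(stats::cor(x[, !const, drop = FALSE], target))
  }
  list(r = r, constant = const)
}
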