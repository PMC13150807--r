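#' Derivative-based small-molecule enhancement
#'
#' Magnitude of the numerical first derivative of the intensity with
#' respect to point index, optionally Savitzky--Golay smoothed. Sharp
#' peaks (whose derivative scales inversely with line width) are strongly
#' enhanced relative to broad macromolecule features, so peak picking on
#' the enhanced trace ignores the baseline envelope.
#'
#' @param spectrum an [nmr_spectrum()] with `>= 3` points.
#' @param smooth apply Savitzky--Golay smoothing/differentiation
#'   (default TRUE; falls back to a central difference when FALSE).
#' @param sg_n Savitzky--Golay window length (odd, default 7).
#' @return numeric vector of |d intensity / d index|, same length as the
#'   spectrum.
#' @export
derivative_enhance <- function(spectrum, smooth = TRUE, sg_n = 7L) {
  y <- spectrum$intensity
  if (length(y) < 3) stop("spectrum must have >= 3 points")
  if (smooth && length(y) > sg_n) {
    d <- signal::sgolayfilt(y, p = 3, n = sg_n, m = 1)
  } else {
    d <- c(0, diff(y))
    d <- (d + c(d[-1], 0)) / 2          # central difference
  }
  abs(d)
}

# signed smoothed derivative (internal; zero crossings locate apexes)
signed_derivative <- function(spectrum, smooth = TRUE, sg_n = 7L) {
  y <- spectrum$intensity
  if (smooth && length(y) > sg_n) {
    signal::sgolayfilt(y, p = 3, n = sg_n, m = 1)
  } else {
    d <- c(0, diff(y))
    (d + c(d[-1], 0)) / 2
  }
}

# parabolic (3-point) apex refinement around grid index k
refine_apex <- function(spectrum, k) {
  n <- length(spectrum$ppm_axis)
  if (k <= 1 || k >= n) {
    return(list(ppm = spectrum$ppm_axis[k], height = spectrum$intensity[k]))
  }
  y0 <- spectrum$intensity[k - 1]; y1 <- spectrum$intensity[k]
  y2 <- spectrum$intensity[k + 1]
  denom <- y0 - 2 * y1 + y2
  p <- if (abs(denom) > 0) 0.5 * (y0 - y2) / denom else 0
  p <- max(min(p, 0.5), -0.5)
  list(ppm = spectrum$ppm_axis[k] +
         p * (spectrum$ppm_axis[min(k + 1, n)] - spectrum$ppm_axis[k]),
       height = y1 - 0.25 * (y0 - y2) * p)
}

# local maxima (grid indices) of intensity within an index set
local_maxima <- function(y, idx) {
  idx <- idx[idx > 1 & idx < length(y)]
  idx[y[idx] > y[idx - 1] & y[idx] >= y[idx + 1]]
}

# topographic prominence of a candidate maximum inside a window: height
# above the higher of the two valleys separating it from taller terrain
# (or the window edge). Noise wiggles riding a peak flank have shallow
# notches on their uphill side and are rejected by a 3-sigma prominence
# threshold; genuine resolved lines keep their full height.
peak_prominence <- function(y, idx, k) {
  pos <- match(k, idx)
  yy <- y[idx]
  left_min <- yy[pos]; i <- pos
  while (i > 1) {
    i <- i - 1
    left_min <- min(left_min, yy[i])
    if (yy[i] > yy[pos]) break
  }
  right_min <- yy[pos]; i <- pos
  while (i < length(yy)) {
    i <- i + 1
    right_min <- min(right_min, yy[i])
    if (yy[i] > yy[pos]) break
  }
  yy[pos] - max(left_min, right_min)
}

# background under a (possibly peak-filling) search window: the line
# through the medians of two flanking segments just outside the window,
# evaluated at each window point -- the peak's own flanks never
# contaminate the reference level, and sloping local structure (e.g. the
# tail of a neighboring multiplet line) is tracked instead of flagged as
# signal
flank_background <- function(spectrum, idx, flank_n = NULL) {
  n <- length(spectrum$intensity)
  k <- flank_n %||% max(4L, length(idx))
  left <- seq.int(max(1L, idx[1] - k), max(1L, idx[1] - 1L))
  right <- seq.int(min(n, idx[length(idx)] + 1L),
                   min(n, idx[length(idx)] + k))
  stats::approx(x = c(mean(left), mean(right)),
                y = c(stats::median(spectrum$intensity[left]),
                      stats::median(spectrum$intensity[right])),
                xout = idx, rule = 2)$y
}

# local background: line through the medians of the window's edge fifths
window_background <- function(spectrum, idx) {
  n <- length(idx)
  k <- max(2L, floor(n / 5))
  lo <- stats::median(spectrum$intensity[idx[seq_len(k)]])
  hi <- stats::median(spectrum$intensity[idx[seq.int(n - k + 1L, n)]])
  stats::approx(x = c(idx[1], idx[n]), y = c(lo, hi), xout = idx)$y
}

#' Locate the glucose anomeric doublet anchor
#'
#' Scans the derivative-enhanced trace of a search region for pairs of
#' resolved maxima whose separation matches the anomeric
#' doublet coupling within a tolerance, and returns the midpoint of the
#' highest-intensity qualifying pair. This anchors the whole
#' chemical-shift prediction chain on an actual spectral feature.
#'
#' @param spectrum an [nmr_spectrum()].
#' @param search_region `(low, high)` ppm pair, default `c(5.1, 5.4)`.
#' @param j_hz doublet splitting (Hz), default 3.8.
#' @param j_tol relative tolerance on the splitting (default 0.2).
#' @param noise_sigma noise sd; estimated from the default region when
#'   `NULL`.
#' @return list with `delta` (doublet midpoint, ppm), `peaks` (the two
#'   refined line positions) and `height` (summed apex intensity).
#'   Signals an error of class `edtaqc_anchor_error` when no qualifying
#'   pair exists.
#' @export
find_glucose_anchor <- function(spectrum, search_region = c(5.1, 5.4),
                                j_hz = 3.8, j_tol = 0.2,
                                noise_sigma = NULL) {
  idx <- region_indices(spectrum, search_region)
  if (length(idx) < 5) stop("search region outside the spectrum axis")
  if (is.null(noise_sigma)) noise_sigma <- estimate_noise(spectrum)
  y <- spectrum$intensity
  bg <- window_background(spectrum, idx)
  cand <- local_maxima(y, idx)
  keep <- (y[cand] - bg[match(cand, idx)]) > 3 * noise_sigma &
    vapply(cand, function(k) peak_prominence(y, idx, k), numeric(1)) >
      3 * noise_sigma
  cand <- cand[keep]
  if (length(cand) >= 2) {
    ref <- lapply(cand, function(k) refine_apex(spectrum, k))
    pos <- vapply(ref, `[[`, numeric(1), "ppm")
    ht <- vapply(ref, `[[`, numeric(1), "height")
    best <- NULL; best_ht <- -Inf
    for (i in seq_along(pos)) {
      for (j in seq_along(pos)) {
        if (j <= i) next
        sep_hz <- abs(pos[i] - pos[j]) * spectrum$field_mhz
        if (abs(sep_hz - j_hz) <= j_tol * j_hz) {
          tot <- ht[i] + ht[j]
          if (tot > best_ht) { best_ht <- tot; best <- c(i, j) }
        }
      }
    }
    if (!is.null(best)) {
      return(list(delta = mean(pos[best]), peaks = sort(pos[best]),
                  height = best_ht))
    }
  }
  stop(errorCondition(
    sprintf("no anomeric doublet (J = %.1f Hz) found in [%.2f, %.2f] ppm",
            j_hz, min(search_region), max(search_region)),
    class = c("edtaqc_anchor_error", "error", "condition")))
}

#' Fit a linear chemical-shift prediction model
#'
#' Ordinary least squares of one spin system's chemical shift on
#' another's across a training cohort. The residual scale (root mean
#' squared residual, in ppm) is what defines the assignment search
#' window.
#'
#' @param x predictor shifts (ppm).
#' @param y response shifts (ppm).
#' @param predictor,response spin-system identifiers (metadata).
#' @param id model identifier.
#' @return an object of class `shift_model` with `slope`, `intercept`,
#'   `r_squared`, `rrmse` (ppm), `n_train`.
#' @export
fit_shift_model <- function(x, y, predictor = "x", response = "y",
                            id = NULL) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length x and y with >= 3 points")
  }
  if (stats::var(x) == 0) stop("degenerate fit: constant predictor")
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  ssr <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  structure(list(id = id %||% paste0(predictor, "->", response),
                 predictor = predictor, response = response,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (sst > 0) 1 - ssr / sst else 1,
                 rrmse = sqrt(mean(res^2)),
                 n_train = length(x)),
            class = "shift_model")
}

#' @export
print.shift_model <- function(x, ...) {
  cat(sprintf("<shift_model %s: %s -> %s, slope %.4f, R2 %.4f, rRMSE %.5f ppm, n %d>\n",
              x$id, x$predictor, x$response, x$slope, x$r_squared,
              x$rrmse, x$n_train))
  invisible(x)
}

predict_shift <- function(model, x) model$slope * x + model$intercept

#' Assign a peak inside a windowed search region
#'
#' Looks for local maxima exceeding the local background by three noise
#' standard deviations inside a window centered on the predicted
#' chemical shift, and returns the qualifying maximum nearest to the
#' prediction (ties broken by height), refined by 3-point parabolic
#' interpolation.
#'
#' @param spectrum an [nmr_spectrum()].
#' @param predicted predicted chemical shift (ppm).
#' @param window_lw total window width in line widths.
#' @param line_width_ppm line width (FWHM) in ppm.
#' @param noise_sigma noise sd (intensity units).
#' @param exclude_ppm positions of lines already attributed to other
#'   species; candidates within half a line width of one are never "the
#'   peak of interest" and are skipped.
#' @return list with `delta` (ppm or `NA`), `status` (`"assigned"` or
#'   `"below_detection"`), `height`.
#' @export
assign_peak <- function(spectrum, predicted, window_lw, line_width_ppm,
                        noise_sigma, exclude_ppm = numeric(0)) {
  half <- window_lw * line_width_ppm / 2
  rng <- range(spectrum$ppm_axis)
  if (predicted - half < rng[1] || predicted + half > rng[2]) {
    stop("search window lies outside the spectrum axis")
  }
  idx <- region_indices(spectrum, c(predicted - half, predicted + half))
  if (length(idx) < 3) {
    return(list(delta = NA_real_, status = "below_detection", height = NA_real_))
  }
  y <- spectrum$intensity
  bg <- flank_background(spectrum, idx)
  cand <- local_maxima(y, idx)
  cand <- cand[y[cand] - bg[match(cand, idx)] > 3 * noise_sigma]
  if (!length(cand)) {
    return(list(delta = NA_real_, status = "below_detection", height = NA_real_))
  }
  ref <- lapply(cand, function(k) refine_apex(spectrum, k))
  pos <- vapply(ref, `[[`, numeric(1), "ppm")
  ht <- vapply(ref, `[[`, numeric(1), "height")
  if (length(exclude_ppm)) {
    foreign <- vapply(pos, function(p) {
      any(abs(p - exclude_ppm) < 0.5 * line_width_ppm)
    }, logical(1))
    pos <- pos[!foreign]; ht <- ht[!foreign]
    if (!length(pos)) {
      return(list(delta = NA_real_, status = "below_detection",
                  height = NA_real_))
    }
  }
  d <- abs(pos - predicted)
  best <- which(d < min(d) + 1e-12)
  if (length(best) > 1) best <- best[which.max(ht[best])]
  list(delta = pos[best], status = "assigned", height = ht[best])
}

#' Measure a peak's line width (FWHM)
#'
#' Numerical full width at half maximum of the peak nearest `delta`,
#' measured above the local background by interpolated half-height
#' crossings.
#'
#' @param spectrum an [nmr_spectrum()].
#' @param delta apex position (ppm).
#' @param span_ppm half-width of the measurement window (ppm).
#' @return FWHM in ppm, or `NA` if the crossings cannot be bracketed.
#' @export
measure_linewidth <- function(spectrum, delta, span_ppm = 0.02) {
  idx <- region_indices(spectrum, c(delta - span_ppm, delta + span_ppm))
  if (length(idx) < 7) return(NA_real_)
  y <- spectrum$intensity[idx]
  x <- spectrum$ppm_axis[idx]
  bg <- window_background(spectrum, idx)
  yc <- y - bg
  k <- which.min(abs(x - delta))
  # walk to the true local apex
  while (k > 1 && yc[k - 1] > yc[k]) k <- k - 1
  while (k < length(yc) && yc[k + 1] > yc[k]) k <- k + 1
  h2 <- yc[k] / 2
  if (h2 <= 0) return(NA_real_)
  left <- NA_real_; right <- NA_real_
  for (i in seq.int(k, 2)) {
    if (yc[i - 1] <= h2 && yc[i] > h2) {
      f <- (yc[i] - h2) / (yc[i] - yc[i - 1])
      left <- x[i] + f * (x[i - 1] - x[i]); break
    }
  }
  for (i in seq.int(k, length(yc) - 1L)) {
    if (yc[i + 1] <= h2 && yc[i] > h2) {
      f <- (yc[i] - h2) / (yc[i] - yc[i + 1])
      right <- x[i] + f * (x[i + 1] - x[i]); break
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  abs(left - right)
}

#' Default assignment chain
#'
#' Order and model wiring of the sequential assignment: glucose anchors
#' the free-EDTA singlets and the Ca-EDTA quartet (model A); the quartet
#' predicts the Ca-EDTA singlet (model B); the Ca singlet predicts the
#' Mg singlet (model C); both Zn-EDTA systems are predicted directly
#' from glucose (models D1/D2); the asparagine multiplet (needed for the
#' Zn deconvolution) is also glucose-anchored and assigned ahead of the
#' Zn systems, so its lines are known -- and excluded -- when the
#' overlapping Zn-EDTA singlet is searched. Each non-glucose-anchored
#' step has a glucose-anchored fallback applied with a widened (2.5 line
#' width) window when the primary window contains no qualifying peak.
#'
#' @return data.frame with columns `species`, `primary`, `fallback`.
#' @export
default_chain <- function() {
  data.frame(
    species = c("free_edta_1", "free_edta_2", "ca_edta_quartet",
                "ca_edta_singlet", "mg_edta_singlet", "asparagine_dd",
                "zn_edta_singlet", "zn_edta_quartet"),
    primary = c("E1", "E2", "A", "B", "C", "F", "D1", "D2"),
    fallback = c(NA, NA, NA, "FB_ca_s", "FB_mg_s", NA, NA, NA),
    stringsAsFactors = FALSE)
}

# model ids -> (predictor, response) pairs of the default chain
default_model_specs <- function() {
  list(A = c("glucose_anomeric", "ca_edta_quartet"),
       B = c("ca_edta_quartet", "ca_edta_singlet"),
       C = c("ca_edta_singlet", "mg_edta_singlet"),
       D1 = c("glucose_anomeric", "zn_edta_singlet"),
       D2 = c("glucose_anomeric", "zn_edta_quartet"),
       E1 = c("glucose_anomeric", "free_edta_1"),
       E2 = c("glucose_anomeric", "free_edta_2"),
       F = c("glucose_anomeric", "asparagine_dd"),
       FB_ca_s = c("glucose_anomeric", "ca_edta_singlet"),
       FB_mg_s = c("glucose_anomeric", "mg_edta_singlet"))
}

#' Train the default shift-model set from ground-truth centers
#'
#' Fits every model of the default chain by OLS on a table of true (or
#' expert-assigned) chemical shifts, one row per training spectrum --
#' the synthetic counterpart of training on large assigned cohorts.
#'
#' @param centers data.frame (or matrix) with one column per spin
#'   system, one row per sample, in ppm.
#' @return named list of [fit_shift_model()] results, class
#'   `shift_model_set`.
#' @export
fit_shift_models_from_truth <- function(centers) {
  centers <- as.data.frame(centers)
  specs <- default_model_specs()
  out <- lapply(names(specs), function(id) {
    pr <- specs[[id]][1]; rs <- specs[[id]][2]
    fit_shift_model(centers[[pr]], centers[[rs]], predictor = pr,
                    response = rs, id = id)
  })
  names(out) <- names(specs)
  structure(out, class = "shift_model_set")
}

#' Write / read a shift-model set as JSON
#'
#' @param models a `shift_model_set`.
#' @param path JSON file path.
#' @return `write_shift_models()` returns `path` invisibly;
#'   `read_shift_models()` the model set.
#' @export
write_shift_models <- function(models, path) {
  jsonlite::write_json(lapply(models, unclass), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_shift_models
#' @export
read_shift_models <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(raw, function(m) structure(m, class = "shift_model"))
  structure(out, class = "shift_model_set")
}

#' Sequentially assign all EDTA-related spin systems
#'
#' Applies the trained shift models in chain order, anchoring every
#' prediction on an already-assigned spectral feature: the search window
#' half-width is `max(rRMSE, 0.5 line width)` capped so the total
#' primary window stays below two line widths; when the primary window
#' contains no qualifying maximum, the glucose-anchored fallback model
#' is applied with a 2.5-line-width window. Failures become statuses,
#' never errors.
#'
#' @param spectrum an [nmr_spectrum()].
#' @param models a `shift_model_set`.
#' @param anchor glucose anomeric doublet midpoint (ppm), from
#'   [find_glucose_anchor()].
#' @param noise_sigma noise sd; estimated from the default region when
#'   `NULL`.
#' @param line_width_ppm line width (FWHM, ppm); when `NULL`, measured
#'   from the assigned free-EDTA reference singlet, falling back to
#'   1.5 Hz / field.
#' @param chain assignment order, default [default_chain()].
#' @param templates template database; supplies the dominant-line offset
#'   at which each multiplet is actually searched (the system center of
#'   a quartet is a trough, not a peak; the observed feature is its
#'   strongest line, and the assigned center is recovered by removing
#'   that line's fixed Hz offset).
#' @return data.frame of class `assignment_result` with one row per spin
#'   system: `species`, `assigned`, `predicted`, `model`, `window_lw`,
#'   `status`; attributes `anchor`, `line_width_ppm`, `noise_sigma`.
#' @export
assign_all_species <- function(spectrum, models, anchor,
                               noise_sigma = NULL, line_width_ppm = NULL,
                               chain = default_chain(),
                               templates = default_templates()) {
  if (is.null(noise_sigma)) noise_sigma <- estimate_noise(spectrum)
  default_lw <- 1.5 / spectrum$field_mhz
  lw <- line_width_ppm
  assigned <- c(glucose_anomeric = anchor)
  line_positions <- function(species, center) {
    tpl <- templates[[species]]
    if (is.null(tpl)) center else center + tpl$offsets_hz / spectrum$field_mhz
  }
  known_lines <- line_positions("glucose_anomeric", anchor)
  rows <- vector("list", nrow(chain))
  for (i in seq_len(nrow(chain))) {
    step <- chain[i, ]
    res <- list(delta = NA_real_, status = "below_detection")
    used_model <- NA_character_; pred <- NA_real_; wlw <- NA_real_
    lw_now <- lw %||% default_lw
    tpl <- templates[[step$species]]
    line_off <- if (!is.null(tpl)) {
      tpl$offsets_hz[which.max(tpl$ratios)] / spectrum$field_mhz
    } else 0
    primary <- models[[step$primary]]
    x <- if (is.null(primary)) NA_real_ else assigned[primary$predictor]
    if (!is.null(primary) && !is.na(x)) {
      pred <- predict_shift(primary, x)
      # five model-sigmas make a miss of a present peak vanishingly
      # rare while the total window stays below two line widths
      half <- min(max(5 * primary$rrmse, 0.5 * lw_now), 0.95 * lw_now)
      wlw <- 2 * half / lw_now
      res <- assign_peak(spectrum, pred + line_off, wlw, lw_now, noise_sigma,
                         exclude_ppm = known_lines)
      used_model <- step$primary
    }
    if (res$status == "below_detection" && !is.na(step$fallback)) {
      fb <- models[[step$fallback]]
      xf <- if (is.null(fb)) NA_real_ else assigned[fb$predictor]
      if (!is.null(fb) && !is.na(xf)) {
        pred <- predict_shift(fb, xf)
        wlw <- 2.5
        res <- assign_peak(spectrum, pred + line_off, wlw, lw_now, noise_sigma,
                           exclude_ppm = known_lines)
        used_model <- step$fallback
        if (res$status == "assigned") res$status <- "fallback_assigned"
      }
    }
    assigned[step$species] <- if (res$status == "below_detection") NA_real_
                              else res$delta - line_off
    if (!is.na(assigned[step$species])) {
      known_lines <- c(known_lines,
                       line_positions(step$species, assigned[step$species]))
    }
    if (step$species == "free_edta_1" && is.null(lw) &&
        !is.na(assigned[step$species])) {
      mlw <- measure_linewidth(spectrum, assigned[step$species])
      lw <- if (is.finite(mlw) && mlw > 0) mlw else default_lw
    }
    rows[[i]] <- data.frame(species = step$species,
                            assigned = unname(assigned[step$species]),
                            predicted = pred, model = used_model,
                            window_lw = wlw, status = res$status,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- rbind(data.frame(species = "glucose_anomeric", assigned = anchor,
                          predicted = anchor, model = "anchor",
                          window_lw = NA_real_, status = "assigned",
                          stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  attr(out, "anchor") <- anchor
  attr(out, "line_width_ppm") <- lw %||% default_lw
  attr(out, "noise_sigma") <- noise_sigma
  class(out) <- c("assignment_result", class(out))
  out
}
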