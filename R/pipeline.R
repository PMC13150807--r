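#' Train the shift-model chain on a synthetic cohort
#'
#' Generates a training cohort with [generate_cohort()] and fits every
#' model of the default chain on the ground-truth centers -- the
#' synthetic counterpart of training on large expert-assigned cohorts.
#'
#' @param n_train training cohort size (default 100).
#' @param seed master seed.
#' @param config_args passed to [synth_config()] via [generate_cohort()].
#' @param zn_dropout passed to [generate_cohort()]; default 0 so every
#'   training spectrum carries all species.
#' @return a `shift_model_set`.
#' @export
train_shift_models <- function(n_train = 100L, seed = 1L,
                               config_args = list(), zn_dropout = 0) {
  cohort <- generate_cohort(n_train, seed = seed, zn_dropout = zn_dropout,
                            config_args = config_args)
  centers <- as.data.frame(do.call(rbind,
                                   lapply(cohort, function(s) s$truth$centers)))
  fit_shift_models_from_truth(centers)
}

#' Assign and deconvolute one spectrum
#'
#' The per-sample front half of the pipeline: find the glucose anchor,
#' run the chained assignment, deconvolute all EDTA-related systems
#' (with asparagine subtraction ahead of the Zn-EDTA fits).
#'
#' @param spectrum an [nmr_spectrum()].
#' @param models a `shift_model_set`.
#' @param templates template database, default [default_templates()].
#' @param noise_region `(low, high)` ppm pair for noise estimation.
#' @return list with `anchor`, `assignments`, `fits`, `noise_sigma`,
#'   `line_width_ppm`.
#' @export
process_spectrum <- function(spectrum, models,
                             templates = default_templates(),
                             noise_region = c(13, 14)) {
  sigma <- estimate_noise(spectrum, noise_region)
  anchor <- find_glucose_anchor(spectrum, noise_sigma = sigma)
  assignments <- assign_all_species(spectrum, models, anchor$delta,
                                    noise_sigma = sigma)
  fits <- deconvolute_all(spectrum, assignments, templates)
  list(anchor = anchor$delta, assignments = assignments, fits = fits,
       noise_sigma = sigma,
       line_width_ppm = attr(assignments, "line_width_ppm"))
}

# fit one species of an aqueous standard at its default position
fit_standard_species <- function(spectrum, template, sigma,
                                 line_width_ppm = NULL) {
  lw <- line_width_ppm %||% (1.5 / spectrum$field_mhz)
  pk <- assign_peak(spectrum, template$default_center, window_lw = 2,
                    line_width_ppm = lw, noise_sigma = sigma)
  if (pk$status != "assigned") return(below_detection_fit(template$species))
  fit_spin_system(spectrum, template, pk$delta, lw, sigma)
}

#' Build universal calibration curves from synthetic standards
#'
#' Renders single-ion aqueous EDTA standards at each field, measures the
#' metal-EDTA singlet integrals at their default positions, normalizes
#' them against the per-field free-EDTA reference and fits one
#' calibration curve per ion (plus a pooled per-proton curve used for
#' EDTA mass-balance checks).
#'
#' @param reference a [measure_field_reference()] result for the field
#'   the standards are rendered at.
#' @param levels named list of in-tube concentration series (mM) per
#'   ion; defaults span the physiological ranges.
#' @param seed master seed.
#' @param s_ref reference sensitivity for the normalization (defaults to
#'   `reference$sensitivity`, i.e. this field is the reference field).
#' @param config_args passed to [synth_config()] via [synth_standard()].
#' @param templates template database.
#' @return list with `curves` (named per-ion [fit_calibration()]
#'   results), `per_proton` (pooled curve of concentration vs per-proton
#'   normalized integral), `points` (the raw calibration table).
#' @export
calibrate_from_standards <- function(reference, levels = NULL, seed = 1L,
                                     s_ref = NULL,
                                     config_args = list(),
                                     templates = default_templates()) {
  defaults <- list(ca = seq(0.4, 1.8, length.out = 8),
                   mg = seq(0.1, 0.8, length.out = 8),
                   zn = seq(0.0015, 0.012, length.out = 8))
  levels <- utils::modifyList(defaults, levels %||% list())
  s_ref <- s_ref %||% reference$sensitivity
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L,
                      sum(lengths(levels)))
  k <- 0L
  pts <- list()
  for (ion in names(levels)) {
    tpl <- templates[[ion_species[[ion]]]]
    for (conc in levels[[ion]]) {
      k <- k + 1L
      std <- synth_standard(ion, conc, seed = seeds[k],
                            config_args = config_args)
      sigma <- estimate_noise(std$spectrum)
      fit <- fit_standard_species(std$spectrum, tpl, sigma)
      if (fit$status == "below_detection") next
      s_f <- spectrometer_sensitivity(reference$ref_integral, sigma)
      inorm <- normalized_integral(fit$integral, reference$ref_integral,
                                   s_ref, s_f)
      pts[[length(pts) + 1L]] <- data.frame(
        ion = ion, conc_mM = conc, i_norm = inorm,
        i_norm_per_proton = inorm / tpl$n_protons,
        stringsAsFactors = FALSE)
    }
  }
  pts <- do.call(rbind, pts)
  curves <- lapply(split(pts, pts$ion), function(d) {
    fit_calibration(d$conc_mM, d$i_norm, ion = d$ion[1], s_ref = s_ref)
  })
  per_proton <- fit_calibration(pts$conc_mM * 1,
                                pts$i_norm_per_proton,
                                ion = "per_proton", s_ref = s_ref)
  list(curves = curves[c("ca", "mg", "zn")], per_proton = per_proton,
       points = pts)
}

#' Quantify one sample spectrum end to end
#'
#' [process_spectrum()] followed by [quantify_ions()].
#'
#' @param spectrum an [nmr_spectrum()].
#' @param models a `shift_model_set`.
#' @param curves per-ion calibration curves.
#' @param reference the [measure_field_reference()] for this
#'   spectrometer.
#' @param s_ref reference-field sensitivity (defaults to the curves'
#'   recorded value).
#' @param templates template database.
#' @return list with `report` (a `quant_report`) and `processed` (the
#'   [process_spectrum()] result).
#' @export
quantify_spectrum <- function(spectrum, models, curves, reference,
                              s_ref = NULL,
                              templates = default_templates()) {
  proc <- process_spectrum(spectrum, models, templates)
  report <- quantify_ions(proc$fits, curves, reference, s_ref = s_ref,
                          noise_sigma = proc$noise_sigma,
                          label = spectrum$label)
  list(report = report, processed = proc)
}

#' EDTA mass balance of one processed sample
#'
#' Converts the free-EDTA and three metal-EDTA integrals of a sample
#' into concentrations through the pooled per-proton calibration and
#' sums them; in a closed tube the sum equals the total EDTA added with
#' the buffer (~2.8 mmol/L for standard collection tubes diluted 1:1).
#'
#' @param fits named list from [deconvolute_all()].
#' @param per_proton the pooled per-proton [fit_calibration()] curve.
#' @param reference the [measure_field_reference()] for this field.
#' @param s_ref reference sensitivity (defaults to the curve's).
#' @param noise_sigma per-sample noise sd for the per-spectrum
#'   sensitivity; the reference acquisition's own sensitivity is used
#'   when `NA`.
#' @param templates template database (for proton counts).
#' @return list with `species` (named mM vector: free_edta, ca, mg, zn)
#'   and `total_mM`.
#' @export
edta_mass_balance <- function(fits, per_proton, reference, s_ref = NULL,
                              noise_sigma = NA_real_,
                              templates = default_templates()) {
  s_ref <- s_ref %||% per_proton$s_ref
  if (is.null(s_ref) || !is.finite(s_ref)) s_ref <- reference$sensitivity
  s_f <- if (is.finite(noise_sigma) && noise_sigma > 0) {
    spectrometer_sensitivity(reference$ref_integral, noise_sigma)
  } else {
    reference$sensitivity
  }
  species <- c(free_edta = "free_edta_1", ca = "ca_edta_singlet",
               mg = "mg_edta_singlet", zn = "zn_edta_singlet")
  conc <- vapply(names(species), function(nm) {
    sp <- species[[nm]]
    fit <- fits[[sp]]
    if (is.null(fit) || fit$status == "below_detection") return(0)
    n_p <- templates[[sp]]$n_protons
    inorm <- normalized_integral(fit$integral, reference$ref_integral,
                                 s_ref, s_f)
    per_proton$slope * (inorm / n_p) + per_proton$intercept
  }, numeric(1))
  list(species = conc, total_mM = sum(conc))
}
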