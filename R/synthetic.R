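#' Configuration for the synthetic serum/plasma-EDTA spectrum generator
#'
#' Collects the composition and acquisition settings from which
#' [generate_spectrum()] renders a spectrum. Concentrations are in-tube
#' values (mM), i.e. after the 1:1 dilution of sample with EDTA buffer;
#' the default total EDTA of 2.8 mM matches a 5.649 mM buffer diluted
#' 50% into the NMR tube. Free EDTA is the total minus the three
#' chelated pools (metal-EDTA binding is quantitative at pH 7.4).
#'
#' The signal-to-noise setting `snr` is referenced to the apex of the
#' Zn-EDTA singlet at a fixed 6 uM reference concentration -- the weakest
#' signal the pipeline quantifies; the implied free-EDTA peak SNR is of
#' order 10^4, as in real cryoprobe serum spectra.
#'
#' @param field_mhz spectrometer 1H frequency (MHz); 500.13 and 600.13
#'   are the fields of interest.
#' @param ppm_range `(low, high)` ppm pair of the rendered axis; must
#'   cover the 13--14 ppm noise region.
#' @param n_points grid size (default 32768, a desk-scale stand-in for
#'   the 98k points of production acquisitions).
#' @param ca,mg,zn,glucose,asparagine in-tube concentrations (mM).
#' @param edta_total total EDTA in the tube (mM), default 2.8.
#' @param linewidth_hz natural line width (FWHM, Hz) of the sharp
#'   signals; split into a Lorentzian HWHM of 0.5 Hz and a Gaussian sd
#'   of 0.36 Hz by default.
#' @param gamma_l_hz,sigma_g_hz explicit Voigt width components (Hz);
#'   derived from `linewidth_hz` when `NULL`.
#' @param response spectrometer response: peak area per (mM x proton);
#'   scales as field^(3/2) around 1000 at 500.13 MHz.
#' @param snr apex signal-to-noise of the Zn-EDTA singlet at the 6 uM
#'   reference concentration; `noise_sd` overrides when given.
#' @param noise_sd additive white-noise sd (intensity units), or `NULL`.
#' @param latent latent physicochemical condition variable in `[-1, 1]`
#'   driving coordinated chemical-shift displacement, or `NULL` to draw
#'   uniformly per sample.
#' @param shift_sensitivity named ppm-per-unit-latent slopes per species.
#' @param jitter_sd independent per-species center jitter sd (ppm).
#' @param baseline_scale multiplier on the broad macromolecule baseline
#'   (three very broad Gaussians); 0 disables (aqueous standards).
#' @param receiver_gain,num_scans acquisition metadata carried into the
#'   spectrum.
#' @param templates spin-system database, default [default_templates()].
#' @param support_ppm half-width of the evaluation support of each Voigt
#'   component when rendering (profile tails beyond this are dropped;
#'   1 ppm leaves truncation far below the noise floor).
#' @return a `synth_config` list.
#' @export
synth_config <- function(field_mhz = 500.13,
                         ppm_range = c(-0.5, 14.5),
                         n_points = 32768L,
                         ca = 1.2, mg = 0.45, zn = 0.006,
                         glucose = 2.5, asparagine = 0.04,
                         edta_total = 2.8,
                         linewidth_hz = 1.5,
                         gamma_l_hz = NULL, sigma_g_hz = NULL,
                         response = NULL,
                         snr = 100, noise_sd = NULL,
                         latent = NULL,
                         shift_sensitivity = NULL,
                         jitter_sd = 3e-4,
                         baseline_scale = 1,
                         receiver_gain = 1, num_scans = 32L,
                         templates = default_templates(),
                         support_ppm = 1.0) {
  conc <- c(ca = ca, mg = mg, zn = zn, glucose = glucose,
            asparagine = asparagine)
  if (any(conc < 0) || edta_total < 0) {
    stop("concentrations must be non-negative")
  }
  if (edta_total == 0) {
    # no chelator: metal aquo ions carry no 1H signal, nothing resonates
    free_edta <- 0
    ca_c <- mg_c <- zn_c <- 0
  } else {
    free_edta <- edta_total - ca - mg - zn
    if (free_edta < 0) stop("chelated metals exceed total EDTA")
    ca_c <- ca; mg_c <- mg; zn_c <- zn
  }
  if (is.null(gamma_l_hz) || is.null(sigma_g_hz)) {
    w <- voigt_widths_from_fwhm(linewidth_hz)
    if (is.null(gamma_l_hz)) gamma_l_hz <- w$gamma_l
    if (is.null(sigma_g_hz)) sigma_g_hz <- w$sigma_g
  }
  if (is.null(response)) response <- 1000 * (field_mhz / 500.13)^1.5
  if (is.null(shift_sensitivity)) {
    shift_sensitivity <- c(glucose_anomeric = 0.004,
                           free_edta_1 = 0.003, free_edta_2 = 0.003,
                           ca_edta_singlet = 0.005, ca_edta_quartet = 0.006,
                           mg_edta_singlet = 0.0045,
                           zn_edta_singlet = 0.0055, zn_edta_quartet = 0.005,
                           asparagine_dd = 0.004)
  }
  structure(list(field_mhz = field_mhz, ppm_range = ppm_range,
                 n_points = as.integer(n_points),
                 ca = ca_c, mg = mg_c, zn = zn_c, glucose = glucose,
                 asparagine = asparagine, edta_total = edta_total,
                 free_edta = free_edta,
                 linewidth_hz = linewidth_hz,
                 gamma_l_hz = gamma_l_hz, sigma_g_hz = sigma_g_hz,
                 response = response, snr = snr, noise_sd = noise_sd,
                 latent = latent, shift_sensitivity = shift_sensitivity,
                 jitter_sd = jitter_sd, baseline_scale = baseline_scale,
                 receiver_gain = receiver_gain,
                 num_scans = as.integer(num_scans),
                 templates = templates, support_ppm = support_ppm),
            class = "synth_config")
}

# concentration feeding each spin system
species_concentration <- function(config, species) {
  switch(species,
         glucose_anomeric = config$glucose,
         free_edta_1 = , free_edta_2 = config$free_edta,
         ca_edta_singlet = , ca_edta_quartet = config$ca,
         mg_edta_singlet = config$mg,
         zn_edta_singlet = , zn_edta_quartet = config$zn,
         asparagine_dd = config$asparagine,
         stop("unknown species '", species, "'"))
}

# Noise sd implied by the configured SNR (Zn-EDTA singlet at 6 uM).
# The reference height is evaluated at the 500.13 MHz lineshape whatever
# the actual field, so noise scales purely with the spectrometer
# response: the virtual instruments then operate at matched sensitivity
# (equal S_f), as multicenter SOPs aim for, while the per-field apex SNR
# grows mildly with field as sharper ppm lineshapes concentrate signal.
config_noise_sd <- function(config) {
  if (!is.null(config$noise_sd)) return(config$noise_sd)
  if (is.null(config$snr) || config$snr <= 0) return(0)
  ref <- voigt_peak(0, config$sigma_g_hz / 500.13,
                    config$gamma_l_hz / 500.13,
                    area = 0.006 * 4 * config$response)
  voigt_height(ref) / config$snr
}

# render one template (all Voigt components) onto the grid, local support
render_system <- function(ppm, center, template, area_total, config) {
  y <- numeric(length(ppm))
  sg <- config$sigma_g_hz / config$field_mhz
  gl <- config$gamma_l_hz / config$field_mhz
  for (i in seq_along(template$offsets_hz)) {
    c_i <- center + template$offsets_hz[i] / config$field_mhz
    idx <- which(abs(ppm - c_i) <= config$support_ppm)
    if (!length(idx)) next
    pk <- voigt_peak(c_i, sg, gl, area_total * template$ratios[i])
    y[idx] <- y[idx] + voigt_profile(ppm[idx], pk)
  }
  y
}

# smooth macromolecule envelope: three very broad Gaussians
render_baseline <- function(ppm, config, amps = c(1, 1, 1)) {
  if (config$baseline_scale <= 0) return(numeric(length(ppm)))
  centers <- c(1.5, 3.0, 3.8)
  sds <- c(0.5, 0.8, 0.6)
  heights <- c(8, 12, 6) * config$response * config$baseline_scale * amps
  y <- numeric(length(ppm))
  for (i in 1:3) y <- y + heights[i] * exp(-(ppm - centers[i])^2 / (2 * sds[i]^2))
  y
}

#' Generate a synthetic serum/plasma-EDTA spectrum with ground truth
#'
#' Renders every configured spin system as Voigt multiplets with area
#' proportional to concentration x proton count, adds a broad smooth
#' macromolecule baseline and white Gaussian noise, and displaces every
#' species center by an affine function of a latent per-sample condition
#' variable plus small independent jitter -- emulating the coordinated
#' chemical-shift covariation seen across real serum cohorts that the
#' shift-prediction models exploit.
#'
#' @param config a [synth_config()].
#' @param seed integer seed; identical seed + config give bit-identical
#'   output.
#' @return list with `spectrum` (an [nmr_spectrum()]) and `truth`, a list
#'   recording per-species true centers (ppm) and areas, the species
#'   concentrations, the latent variable, line width, noise sd and seed.
#' @export
generate_spectrum <- function(config = synth_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  ppm <- seq(config$ppm_range[2], config$ppm_range[1],
             length.out = config$n_points)
  u <- config$latent %||% stats::runif(1, -1, 1)
  centers <- numeric(0)
  areas <- numeric(0)
  signal <- numeric(length(ppm))
  for (sp in names(config$templates)) {
    tpl <- config$templates[[sp]]
    conc <- species_concentration(config, sp)
    sens <- config$shift_sensitivity[[sp]] %||% 0
    center <- tpl$default_center + sens * u +
      stats::rnorm(1, 0, config$jitter_sd)
    centers[sp] <- center
    area <- conc * tpl$n_protons * config$response
    areas[sp] <- area
    if (area > 0) signal <- signal + render_system(ppm, center, tpl, area, config)
  }
  amps <- stats::runif(3, 0.8, 1.2)            # sample-to-sample envelope change
  baseline <- render_baseline(ppm, config, amps)
  sd_noise <- config_noise_sd(config)
  noise <- if (sd_noise > 0) stats::rnorm(length(ppm), 0, sd_noise) else 0
  intensity <- (signal + baseline + noise) * config$receiver_gain
  spec <- nmr_spectrum(ppm, intensity, field_mhz = config$field_mhz,
                       receiver_gain = config$receiver_gain,
                       num_scans = config$num_scans,
                       label = sprintf("synthetic_seed%d", seed),
                       metadata = list(synthetic = TRUE))
  truth <- list(centers = centers, areas = areas,
                concentrations = c(free_edta = config$free_edta,
                                   ca = config$ca, mg = config$mg,
                                   zn = config$zn,
                                   glucose = config$glucose,
                                   asparagine = config$asparagine),
                edta_total = config$edta_total,
                latent = u, seed = seed,
                linewidth_hz = config$linewidth_hz,
                linewidth_ppm = config$linewidth_hz / config$field_mhz,
                noise_sd = sd_noise, response = config$response,
                baseline_amps = amps)
  list(spectrum = spec, truth = truth)
}

#' Generate a synthetic cohort
#'
#' Draws per-sample concentrations uniformly from physiological in-tube
#' ranges (anchored to blood reference intervals: total serum calcium
#' 2.0--2.8 mM, magnesium 0.7--1.1 mM, zinc 6--18 uM, halved by the 1:1
#' tube dilution) and renders each sample with its own deterministic
#' sub-seed. A configurable fraction of samples receives zero zinc to
#' emulate the minority of real samples in which the Zn-EDTA signal is
#' below detection.
#'
#' @param n number of samples, `>= 1`.
#' @param ranges named list of `(low, high)` in-tube concentration ranges
#'   (mM) for `ca`, `mg`, `zn`, `glucose`, `asparagine`.
#' @param seed master integer seed.
#' @param zn_dropout fraction of samples with Zn below detection
#'   (default 0.06).
#' @param config_args further arguments passed to [synth_config()]
#'   (e.g. `field_mhz`, `snr`).
#' @return list of `list(spectrum, truth)` pairs, length `n`.
#' @export
generate_cohort <- function(n, ranges = NULL, seed = 1L, zn_dropout = 0.06,
                            config_args = list()) {
  if (n < 1) stop("n must be >= 1")
  defaults <- list(ca = c(1.0, 1.4), mg = c(0.35, 0.55),
                   zn = c(0.003, 0.009), glucose = c(2.0, 3.0),
                   asparagine = c(0.02, 0.06))
  ranges <- utils::modifyList(defaults, ranges %||% list())
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  draws <- lapply(names(ranges), function(k) {
    stats::runif(n, ranges[[k]][1], ranges[[k]][2])
  })
  names(draws) <- names(ranges)
  drop_zn <- stats::runif(n) < zn_dropout
  draws$zn[drop_zn] <- 0
  lapply(seq_len(n), function(i) {
    args <- utils::modifyList(
      list(ca = draws$ca[i], mg = draws$mg[i], zn = draws$zn[i],
           glucose = draws$glucose[i], asparagine = draws$asparagine[i]),
      config_args)
    generate_spectrum(do.call(synth_config, args), seed = sub_seeds[i])
  })
}

#' Synthetic calibration standard
#'
#' Buffer-matrix standard: EDTA plus a single metal ion, no serum
#' metabolites, no macromolecule baseline, negligible shift variability
#' (aqueous standards sit at reproducible positions).
#'
#' @param ion one of `"ca"`, `"mg"`, `"zn"`.
#' @param conc_mM in-tube ion concentration (mM).
#' @param seed integer seed.
#' @param config_args further [synth_config()] arguments.
#' @return `list(spectrum, truth)`.
#' @export
synth_standard <- function(ion = c("ca", "mg", "zn"), conc_mM, seed = 1L,
                           config_args = list()) {
  ion <- match.arg(ion)
  args <- list(ca = 0, mg = 0, zn = 0, glucose = 0, asparagine = 0,
               baseline_scale = 0, latent = 0, jitter_sd = 5e-5)
  args[[ion]] <- conc_mM
  args <- utils::modifyList(args, config_args)
  generate_spectrum(do.call(synth_config, args), seed = seed)
}

#' Synthetic metal-free EDTA reference spectrum
#'
#' The per-spectrometer reference acquisition: EDTA in buffer with no
#' metal ions, from which the reference free-EDTA integral and the
#' instrument sensitivity are measured.
#'
#' @param seed integer seed.
#' @param config_args further [synth_config()] arguments (notably
#'   `field_mhz`).
#' @return `list(spectrum, truth)`.
#' @export
synth_reference <- function(seed = 1L, config_args = list()) {
  args <- utils::modifyList(
    list(ca = 0, mg = 0, zn = 0, glucose = 0, asparagine = 0,
         baseline_scale = 0, latent = 0, jitter_sd = 5e-5),
    config_args)
  generate_spectrum(do.call(synth_config, args), seed = seed)
}
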