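#' Construct a spin-system template
#'
#' Describes a species' multiplet fingerprint as a set of components with
#' relative frequency offsets (in Hz, so that patterns scale correctly
#' with spectrometer field) and relative areas summing to one. Templates
#' are what the deconvolution fits, with only an overall area, a small
#' center shift and a shared width scale free.
#'
#' @param species species identifier (e.g. `"ca_edta_singlet"`).
#' @param offsets_hz numeric vector of component offsets from the system
#'   center (Hz).
#' @param ratios relative component areas (normalized to sum 1).
#' @param n_protons number of protons giving rise to the system.
#' @param default_center default chemical shift of the system center (ppm).
#' @param reference logical; marks the free-EDTA reference peak used in
#'   the sensitivity equation.
#' @return an object of class `spin_system`.
#' @export
spin_system <- function(species, offsets_hz, ratios, n_protons,
                        default_center, reference = FALSE) {
  stopifnot(length(offsets_hz) == length(ratios), n_protons >= 1,
            all(ratios > 0))
  structure(list(species = species,
                 offsets_hz = as.numeric(offsets_hz),
                 ratios = as.numeric(ratios) / sum(ratios),
                 n_protons = as.integer(n_protons),
                 default_center = default_center,
                 reference = isTRUE(reference)),
            class = "spin_system")
}

#' AB-quartet line pattern
#'
#' Frequencies and roof-effect intensities of the four transitions of two
#' strongly coupled inequivalent protons, from the coupling constant `j_hz`
#' and the chemical-shift difference `dnu_hz` of the two sites:
#' lines at +-(D - J)/2 (inner) and +-(D + J)/2 (outer) with
#' D = sqrt(dnu^2 + J^2), intensities proportional to 1 + J/D (inner) and
#' 1 - J/D (outer).
#'
#' @param j_hz coupling constant (Hz).
#' @param dnu_hz shift difference of the two protons (Hz).
#' @return list with `offsets_hz` (4) and `ratios` (4, summing to 1).
#' @export
ab_quartet_pattern <- function(j_hz, dnu_hz) {
  D <- sqrt(dnu_hz^2 + j_hz^2)
  offs <- c(-(D + j_hz) / 2, -(D - j_hz) / 2, (D - j_hz) / 2, (D + j_hz) / 2)
  ints <- c(1 - j_hz / D, 1 + j_hz / D, 1 + j_hz / D, 1 - j_hz / D)
  list(offsets_hz = offs, ratios = ints / sum(ints))
}

# doublet-of-doublets pattern for one proton
dd_pattern <- function(j1_hz, j2_hz) {
  offs <- c(-(j1_hz + j2_hz) / 2, -(j1_hz - j2_hz) / 2,
            (j1_hz - j2_hz) / 2, (j1_hz + j2_hz) / 2)
  list(offsets_hz = offs, ratios = rep(0.25, 4))
}

#' Default spin-system template database
#'
#' Fingerprints of the species the pipeline handles: the glucose anomeric
#' doublet (assignment anchor), two free-EDTA singlets (the downfield one,
#' from the acetate CH2 protons, is the sensitivity reference), the
#' Ca-EDTA singlet + acetate AB quartet, the Mg-EDTA singlet, the Zn-EDTA
#' singlet + AB quartet, and the asparagine CH2 doublet-of-doublets that
#' overlaps the Zn-EDTA singlet. Default centers are configurable
#' starting points, not constants of nature: in real samples every center
#' moves with the physicochemical environment, which is exactly what the
#' shift-model chain exploits. The Zn-EDTA singlet default sits inside
#' the asparagine multiplet span to reproduce the documented overlap
#' challenge.
#'
#' @param glucose_j_hz anomeric doublet coupling (default 3.8 Hz).
#' @return named list of [spin_system()] objects.
#' @export
default_templates <- function(glucose_j_hz = 3.8) {
  ca_ab <- ab_quartet_pattern(j_hz = 16.0, dnu_hz = 12.0)
  zn_ab <- ab_quartet_pattern(j_hz = 16.5, dnu_hz = 20.0)
  asn_a <- dd_pattern(16.9, 7.0)   # proton A, -20 Hz from system center
  asn_b <- dd_pattern(16.9, 4.3)   # proton B, +20 Hz
  list(
    glucose_anomeric = spin_system("glucose_anomeric",
      offsets_hz = c(-glucose_j_hz / 2, glucose_j_hz / 2),
      ratios = c(0.5, 0.5), n_protons = 1, default_center = 5.23),
    free_edta_1 = spin_system("free_edta_1", 0, 1, n_protons = 8,
      default_center = 3.60, reference = TRUE),
    free_edta_2 = spin_system("free_edta_2", 0, 1, n_protons = 4,
      default_center = 3.17),
    ca_edta_singlet = spin_system("ca_edta_singlet", 0, 1, n_protons = 4,
      default_center = 2.55),
    ca_edta_quartet = spin_system("ca_edta_quartet", ca_ab$offsets_hz,
      ca_ab$ratios, n_protons = 8, default_center = 3.08),
    mg_edta_singlet = spin_system("mg_edta_singlet", 0, 1, n_protons = 4,
      default_center = 2.70),
    zn_edta_singlet = spin_system("zn_edta_singlet", 0, 1, n_protons = 4,
      default_center = 2.88),
    zn_edta_quartet = spin_system("zn_edta_quartet", zn_ab$offsets_hz,
      zn_ab$ratios, n_protons = 8, default_center = 3.30),
    asparagine_dd = spin_system("asparagine_dd",
      offsets_hz = c(asn_a$offsets_hz - 20, asn_b$offsets_hz + 20),
      ratios = rep(1 / 8, 8), n_protons = 2, default_center = 2.90)
  )
}

# ppm span (min, max offset in ppm) of a template at a given field
template_span_ppm <- function(template, field_mhz) {
  range(template$offsets_hz) / field_mhz
}

#' Write / read a template database as JSON
#'
#' @param templates named list of [spin_system()] objects.
#' @param path JSON file path.
#' @return `write_templates()` returns `path` invisibly;
#'   `read_templates()` the named list.
#' @export
write_templates <- function(templates, path) {
  jsonlite::write_json(lapply(templates, unclass), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_templates
#' @export
read_templates <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(raw, function(x) {
    spin_system(x$species, x$offsets_hz, x$ratios, x$n_protons,
                x$default_center, reference = isTRUE(x$reference))
  })
  names(out) <- vapply(out, `[[`, "", "species")
  out
}
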