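# Shared fixtures, built once per test run. Everything is generated in
# code from fixed seeds; nothing is read from disk.

.fx_env <- new.env(parent = emptyenv())

fx <- function(name) {
  if (is.null(.fx_env[[name]])) {
    .fx_env[[name]] <- switch(
      name,
      models = train_shift_models(60, seed = 101),
      ref5 = measure_field_reference(synth_reference(seed = 991)$spectrum),
      ref6 = measure_field_reference(
        synth_reference(seed = 992,
                        config_args = list(field_mhz = 600.13))$spectrum),
      cal = calibrate_from_standards(fx("ref5"), seed = 55),
      sample1 = generate_spectrum(
        synth_config(ca = 1.2, mg = 0.45, zn = 0.006), seed = 321),
      stop("unknown fixture '", name, "'")
    )
  }
  .fx_env[[name]]
}

# quiet uniform grid spectrum for unit tests
flat_spectrum <- function(n = 4096, value = 0, field_mhz = 500.13,
                          ppm = c(-0.5, 14.5)) {
  nmr_spectrum(seq(ppm[2], ppm[1], length.out = n), rep(value, n),
               field_mhz = field_mhz)
}

# numerical integral of a spectrum over a ppm interval (baseline not
# subtracted) -- the independent check against fitted areas
numeric_integral <- function(spectrum, region) {
  reg <- spectrum_region(spectrum, region)
  dx <- stats::median(abs(diff(spectrum$ppm_axis)))
  sum(reg$intensity) * dx
}
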