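mk_spectrum <- function(peaks, noise_sd = 0, seed = 1, n = 32768,
                        baseline = function(ppm) 0 * ppm) {
  ppm <- seq(14.5, -0.5, length.out = n)
  y <- baseline(ppm)
  for (pk in peaks) y <- y + voigt_profile(ppm, pk)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(n, 0, noise_sd)
  }
  nmr_spectrum(ppm, y, 500.13)
}

lw_default <- 1.5 / 500.13
wd <- voigt_widths_from_fwhm(lw_default)   # the package lineshape mix

test_that("a noise-free singlet is recovered to 0.1% with exact template ratios", {
  tpl <- spin_system("s", 0, 1, 4, 3.0)
  sp <- mk_spectrum(list(voigt_peak(3.0004, wd$sigma_g, wd$gamma_l, 1234)))
  fit <- fit_spin_system(sp, tpl, 3.0004, lw_default)
  expect_equal(fit$status, "ok")
  expect_equal(fit$integral, 1234, tolerance = 1e-3)
  expect_equal(sum(vapply(fit$peaks, `[[`, numeric(1), "area")),
               fit$integral, tolerance = 1e-12)
})

test_that("two singlets one line width apart are fitted jointly to 2%", {
  off <- lw_default * 500.13              # 1 line width, in Hz
  tpl <- spin_system("pair", c(0, off), c(0.6, 0.4), 2, 3.0)
  truth <- 800
  pk1 <- voigt_peak(3.0, wd$sigma_g, wd$gamma_l, truth * 0.6)
  pk2 <- voigt_peak(3.0 + off / 500.13, wd$sigma_g, wd$gamma_l, truth * 0.4)
  sp <- mk_spectrum(list(pk1, pk2), noise_sd = 0.05)
  fit <- fit_spin_system(sp, tpl, 3.0, lw_default, noise_sigma = 0.05)
  expect_equal(fit$integral, truth, tolerance = 0.02)
  areas <- vapply(fit$peaks, `[[`, numeric(1), "area")
  expect_equal(areas[1] / areas[2], 0.6 / 0.4, tolerance = 1e-12)
})

test_that("reported uncertainty scales with the noise level", {
  tpl <- spin_system("s", 0, 1, 4, 3.0)
  ratios <- vapply(1:6, function(seed) {
    u <- vapply(c(1, 2), function(k) {
      sp <- mk_spectrum(list(voigt_peak(3.0, wd$sigma_g, wd$gamma_l, 500)),
                        noise_sd = 0.5 * k, seed = seed)
      fit_spin_system(sp, tpl, 3.0, lw_default, noise_sigma = 0.5 * k)$uncertainty
    }, numeric(1))
    u[2] / u[1]
  }, numeric(1))
  expect_equal(mean(ratios), 2, tolerance = 0.25)
})

test_that("isolated-Voigt fits agree with a dense grid-search oracle", {
  true_area <- 640
  true_shift <- 0.0004
  sg <- wd$sigma_g; gl <- wd$gamma_l
  tpl <- spin_system("s", 0, 1, 4, 3.0)
  sp <- mk_spectrum(list(voigt_peak(3.0 + true_shift, sg, gl, true_area)),
                    noise_sd = 0.02, seed = 4)
  fit <- fit_spin_system(sp, tpl, 3.0, lw_default, noise_sigma = 0.02)
  # brute-force grid search over (area, shift) with the generating widths
  reg <- spectrum_region(sp, fit$region)
  grid_rss <- function(area, shift) {
    model <- voigt_profile(reg$ppm, voigt_peak(3.0 + shift, sg, gl, area))
    sum((model - reg$intensity)^2)
  }
  areas <- seq(600, 680, length.out = 81)
  shifts <- seq(-0.001, 0.001, length.out = 81)
  rss <- outer(areas, shifts, Vectorize(grid_rss))
  best <- which(rss == min(rss), arr.ind = TRUE)
  expect_equal(fit$integral, areas[best[1]], tolerance = 0.005)
  expect_equal(fit$center - 3.0, shifts[best[2]], tolerance = 2.5e-5)
})

test_that("asparagine subtraction unmasks the overlapping Zn singlet", {
  models <- fx("models")
  g <- generate_spectrum(synth_config(zn = 0.007, asparagine = 0.05),
                         seed = 606)
  p <- process_spectrum(g$spectrum, models)
  zn_true <- g$truth$areas[["zn_edta_singlet"]]
  expect_equal(p$fits$zn_edta_singlet$integral, zn_true, tolerance = 0.05)
})

test_that("subtraction is a no-op when asparagine is absent", {
  g <- generate_spectrum(synth_config(asparagine = 0, zn = 0), seed = 707)
  sigma <- estimate_noise(g$spectrum)
  res <- subtract_asparagine(g$spectrum, default_templates()$asparagine_dd,
                             2.90, lw_default, noise_sigma = sigma)
  expect_true(res$absent)
  expect_identical(res$spectrum$intensity, g$spectrum$intensity)
})

test_that("an asparagine-only region is flattened to near the noise floor", {
  cfg <- synth_config(ca = 0, mg = 0, zn = 0, glucose = 0,
                      asparagine = 0.05, edta_total = 0,
                      baseline_scale = 0, noise_sd = 5, snr = NULL)
  g <- generate_spectrum(cfg, seed = 808)
  ct <- g$truth$centers[["asparagine_dd"]]
  res <- subtract_asparagine(g$spectrum, default_templates()$asparagine_dd,
                             ct, lw_default, noise_sigma = 5)
  expect_false(res$absent)
  reg <- spectrum_region(res$spectrum, c(ct - 0.05, ct + 0.05))
  expect_lte(sqrt(mean(reg$intensity^2)), 1.5 * 5)
})

test_that("deconvoluted singlet integrals are linear in true concentration", {
  models <- fx("models")
  cohort <- generate_cohort(10, seed = 909, zn_dropout = 0,
                            config_args = list(snr = NULL))
  ints <- t(vapply(cohort, function(s) {
    p <- process_spectrum(s$spectrum, models)
    c(ca = p$fits$ca_edta_singlet$integral,
      mg = p$fits$mg_edta_singlet$integral,
      zn = p$fits$zn_edta_singlet$integral)
  }, numeric(3)))
  conc <- t(vapply(cohort, function(s)
    s$truth$concentrations[c("ca", "mg", "zn")], numeric(3)))
  for (i in 1:3) {
    expect_gte(cor(ints[, i], conc[, i]), 0.999)
    expect_true(all(ints[, i] >= 0))
  }
})

test_that("removing zinc zeroes its integral and leaves the rest untouched", {
  models <- fx("models")
  base <- generate_spectrum(synth_config(latent = 0.2, jitter_sd = 0,
                                         noise_sd = 40, snr = NULL),
                            seed = 111)
  # drop Zn but keep the free-EDTA pool identical, so any change in the
  # other fits would reflect non-locality of the fitting itself
  nozn <- generate_spectrum(synth_config(zn = 0, edta_total = 2.8 - 0.006,
                                         latent = 0.2, jitter_sd = 0,
                                         noise_sd = 40, snr = NULL),
                            seed = 111)
  p1 <- process_spectrum(base$spectrum, models)
  p2 <- process_spectrum(nozn$spectrum, models)
  expect_equal(p2$fits$zn_edta_singlet$integral, 0)
  expect_equal(p2$fits$zn_edta_singlet$status, "below_detection")
  for (sp in c("free_edta_1", "ca_edta_singlet", "mg_edta_singlet")) {
    expect_equal(p2$fits[[sp]]$integral, p1$fits[[sp]]$integral,
                 tolerance = 0.005)
  }
})
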