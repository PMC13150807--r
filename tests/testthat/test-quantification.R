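test_that("sensitivity and normalized-integral arithmetic", {
  expect_equal(spectrometer_sensitivity(1000, 10), 100)
  # scale invariance: both integral and noise scale with k
  expect_equal(spectrometer_sensitivity(7 * 1000, 7 * 10),
               spectrometer_sensitivity(1000, 10))
  expect_error(spectrometer_sensitivity(1000, 0), "noise_sigma")
  expect_equal(normalized_integral(50, 200, 3, 3), 50 / 200)
  expect_equal(normalized_integral(100, 400, 3, 3),
               normalized_integral(50, 200, 3, 3))
  expect_error(normalized_integral(50, 0, 1, 1), "edta_ref_integral")
  expect_error(normalized_integral(50, 10, 1, 0), "s_f")
})

test_that("calibration on an exact line recovers it and flags the origin", {
  i_norm <- seq(0.1, 1, length.out = 8)
  cal <- fit_calibration(2 * i_norm, i_norm, ion = "ca")
  expect_equal(cal$slope, 2, tolerance = 1e-10)
  expect_equal(cal$intercept, 0, tolerance = 1e-10)
  expect_true(cal$through_origin)
  expect_error(fit_calibration(c(1, 2), c(1, 2)), ">= 3")
  expect_error(fit_calibration(c(1, 2, 3), c(1, 1, 1)), "degenerate")
})

test_that("the intercept CI covers zero for origin-true data in most seeds", {
  hits <- vapply(1:20, function(seed) {
    set.seed(seed)
    x <- runif(10, 0.1, 1)
    cal <- fit_calibration(3 * x + rnorm(10, 0, 0.05), x)
    cal$through_origin
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("quantification applies the linear map and honors statuses", {
  fake_fit <- function(sp, integral, status = "ok") {
    structure(list(species = sp, peaks = list(), integral = integral,
                   uncertainty = 1, residual_rms = 1, center = 3,
                   width_scale = 1, baseline = c(0, 0), region = c(0, 1),
                   status = status, diagnostics = NULL),
              class = "fitted_system")
  }
  reference <- structure(list(field_mhz = 500.13, ref_integral = 1000,
                              noise_sigma = 10, sensitivity = 100,
                              line_width_ppm = 0.003, center = 3.6),
                         class = "field_reference")
  curve <- function(ion, a, b) structure(
    list(ion = ion, slope = a, intercept = b,
         intercept_ci95 = c(-1, 1), through_origin = TRUE,
         s_ref = 100, n_points = 8), class = "calibration_curve")
  fits <- list(free_edta_1 = fake_fit("free_edta_1", 500),
               ca_edta_singlet = fake_fit("ca_edta_singlet", 1000),
               mg_edta_singlet = fake_fit("mg_edta_singlet", 0),
               zn_edta_singlet = fake_fit("zn_edta_singlet", 0,
                                          "below_detection"))
  curves <- list(ca = curve("ca", 2, 0.1), mg = curve("mg", 5, 0.25),
                 zn = curve("zn", 4, 0))
  rep <- quantify_ions(fits, curves, reference)
  # I_norm = 1000/1000 = 1 -> C = 2 * 1 + 0.1
  expect_equal(rep$conc_mM[rep$ion == "ca"], 2.1)
  # zero integral -> C = b
  expect_equal(rep$conc_mM[rep$ion == "mg"], 0.25)
  expect_equal(rep$status[rep$ion == "zn"], "below_detection")
  expect_true(is.na(rep$conc_mM[rep$ion == "zn"]))
  # missing reference fit is a report-level failure
  expect_error(quantify_ions(fits["ca_edta_singlet"], curves, reference),
               "free-EDTA reference")
})

test_that("end-to-end recovery has unit slope across a small cohort", {
  models <- fx("models")
  ref5 <- fx("ref5")
  cal <- fx("cal")
  cohort <- generate_cohort(10, seed = 2024, zn_dropout = 0)
  est <- t(vapply(cohort, function(s) {
    q <- quantify_spectrum(s$spectrum, models, cal$curves, ref5,
                           s_ref = ref5$sensitivity)$report
    setNames(q$conc_mM, q$ion)
  }, numeric(3)))
  truth <- t(vapply(cohort, function(s)
    s$truth$concentrations[c("ca", "mg", "zn")], numeric(3)))
  for (ion in 1:3) {
    sl <- coef(lm(est[, ion] ~ truth[, ion]))[2]
    expect_gte(sl, 0.95)
    expect_lte(sl, 1.05)
  }
})

test_that("regression coincidence testing behaves at both extremes", {
  set.seed(5)
  x <- runif(30, 0, 1)
  y <- 1.0 * x + rnorm(30, 0, 0.01)
  # duplicated cohort: separate lines explain nothing extra
  same <- regression_coincidence_test(x, y, x, y)
  expect_lt(same$f, 1e-10)
  expect_gt(same$p_value, 0.999)
  # clearly different slopes are detected
  y2 <- 2 * x + rnorm(30, 0, 0.01)
  diff <- regression_coincidence_test(x, y, x, y2)
  expect_lt(diff$p_value, 0.01)
  expect_error(regression_coincidence_test(x[1:2], y[1:2], x, y),
               "degenerate")
  expect_error(regression_coincidence_test(x, y), "reference")
})

test_that("data on the identity line rarely reject the fixed 1:1 reference", {
  rejections <- vapply(1:20, function(seed) {
    set.seed(seed)
    x <- runif(30, 0, 1)
    y <- x + rnorm(30, 0, 0.01)
    regression_coincidence_test(x, y, reference = c(0, 1))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(!rejections), 0.9)
})

test_that("detection limits follow the ICH convention on the C = aI + b fit", {
  curve <- structure(list(ion = "zn", slope = 1, intercept = 0,
                          intercept_ci95 = c(-1, 1), through_origin = TRUE,
                          s_ref = 1, n_points = 8),
                     class = "calibration_curve")
  r <- lod_loq_recovery(curve, blank_sd = 0.01)
  expect_equal(r$lod_mM, 0.033)
  expect_equal(r$loq_mM, 0.10)
  expect_equal(r$loq_mM / r$lod_mM, 10 / 3.3)
  r2 <- lod_loq_recovery(curve, 0.01, spiked = 1.1, base = 0.6, added = 0.5)
  expect_equal(r2$recovery_pct, 100)
  expect_error(lod_loq_recovery(curve, 0.01, spiked = 1, base = 0.5,
                                added = 0), "added")
})

test_that("calibration curves round-trip through JSON", {
  cal <- fx("cal")
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal$curves, path)
  back <- read_calibration(path)
  expect_equal(back$ca$slope, cal$curves$ca$slope, tolerance = 1e-12)
  expect_equal(back$zn$intercept_ci95, cal$curves$zn$intercept_ci95,
               tolerance = 1e-12)
})
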