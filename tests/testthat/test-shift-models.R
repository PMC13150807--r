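test_that("derivative enhancement suppresses broad features", {
  expect_equal(derivative_enhance(flat_spectrum(512)), rep(0, 512))
  # narrow vs broad Lorentzian of equal height: enhanced maxima scale
  # inversely with width
  ppm <- seq(6, 0, length.out = 30000)
  narrow <- voigt_profile(ppm, voigt_peak(4, 0, 1.5 / 500.13 / 2, 1))
  broad <- voigt_profile(ppm, voigt_peak(2, 0, 50 / 500.13 / 2, 1))
  broad <- broad * max(narrow) / max(broad)       # equal heights
  sp <- nmr_spectrum(ppm, narrow + broad, 500.13)
  enh <- derivative_enhance(sp)
  near <- function(x, d) abs(sp$ppm_axis - x) < d
  ratio <- max(enh[near(4, 0.05)]) / max(enh[near(2, 0.2)])
  expect_gte(ratio, 10)
})

test_that("enhanced-trace apexes coincide with intensity maxima for isolated peaks", {
  ppm <- seq(6, 2, length.out = 8192)
  y <- voigt_profile(ppm, voigt_peak(4.2, 0.001, 0.001, 1)) +
    voigt_profile(ppm, voigt_peak(3.1, 0.001, 0.001, 0.6))
  sp <- nmr_spectrum(ppm, y, 500.13)
  d <- edtaqc:::signed_derivative(sp)
  # + to - zero crossings of the derivative (descending axis: apex where
  # intensity stops rising)
  for (ct in c(4.2, 3.1)) {
    idx <- which(abs(sp$ppm_axis - ct) < 0.01)
    k_true <- idx[which.max(sp$intensity[idx])]
    cross <- idx[which(d[idx] > 0 & d[idx + 1] <= 0)]
    expect_true(any(abs(cross - k_true) <= 1))
  }
})

test_that("the glucose anchor is found by J-matched pair search", {
  g <- fx("sample1")
  anchor <- find_glucose_anchor(g$spectrum)
  lw <- g$truth$linewidth_ppm
  expect_lt(abs(anchor$delta - g$truth$centers[["glucose_anomeric"]]),
            0.5 * lw)
  expect_equal(diff(anchor$peaks) * 500.13, 3.8, tolerance = 0.2 * 3.8)
  # a region containing only singlets raises the anchor error
  expect_error(find_glucose_anchor(g$spectrum, search_region = c(3.5, 3.7)),
               class = "edtaqc_anchor_error")
})

test_that("a pair at twice the coupling is rejected in favor of the true doublet", {
  ppm <- seq(6, 4.5, length.out = 16384)
  lw <- list(s = 0.0007, g = 0.0005)
  mk <- function(center, j_hz, area) {
    voigt_profile(ppm, voigt_peak(center - j_hz / 2 / 500.13, lw$s, lw$g, area / 2)) +
      voigt_profile(ppm, voigt_peak(center + j_hz / 2 / 500.13, lw$s, lw$g, area / 2))
  }
  # decoy doublet at 2x J is five times more intense
  y <- mk(5.23, 3.8, 1) + mk(5.05, 7.6, 5)
  sp <- nmr_spectrum(ppm, y, 500.13)
  anchor <- find_glucose_anchor(sp, search_region = c(4.9, 5.4), j_hz = 3.8,
                                noise_sigma = 1e-6)
  expect_equal(anchor$delta, 5.23, tolerance = 0.001)
})

test_that("shift-model fitting matches the normal-equations oracle", {
  x <- c(1, 2, 3, 4)
  m <- fit_shift_model(x, 0.5 * x + 2)
  expect_equal(m$r_squared, 1)
  expect_equal(m$rrmse, 0, tolerance = 1e-12)
  expect_equal(m$slope, 0.5)
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    xs <- rnorm(n); ys <- rnorm(n)
    if (var(xs) == 0) next
    m <- fit_shift_model(xs, ys)
    X <- cbind(1, xs)
    beta <- solve(t(X) %*% X, t(X) %*% ys)   # brute-force normal equations
    expect_equal(m$intercept, beta[1], tolerance = 1e-10)
    expect_equal(m$slope, beta[2], tolerance = 1e-10)
  }
})

test_that("shift-model fitting recovers a unit slope with honest rRMSE", {
  set.seed(99)
  slopes <- replicate(20, {
    x <- runif(100, 5.22, 5.24)
    m <- fit_shift_model(x, x + rnorm(100, 0, 0.001))
    c(m$slope, m$rrmse)
  })
  expect_equal(mean(slopes[1, ]), 1, tolerance = 0.05)
  expect_equal(mean(slopes[2, ]), 0.001, tolerance = 0.2)
})

test_that("degenerate shift-model inputs error out", {
  expect_error(fit_shift_model(1:2, 1:2), "equal-length")
  expect_error(fit_shift_model(c(1, 1, 1), c(1, 2, 3)), "constant predictor")
  expect_silent(fit_shift_model(c(1, 1, 2, 3), c(0, 1, 2, 3)))
})

test_that("windowed peak assignment finds the nearest qualifying maximum", {
  ppm <- seq(4, 2, length.out = 16384)
  lw <- 0.003
  y <- voigt_profile(ppm, voigt_peak(3.0, 0.0007, 0.0005, 1))
  sp <- nmr_spectrum(ppm, y, 500.13)
  hit <- assign_peak(sp, 3.0, window_lw = 2, line_width_ppm = lw,
                     noise_sigma = 1e-4)
  expect_equal(hit$status, "assigned")
  expect_equal(hit$delta, 3.0, tolerance = 1e-4)
  # true apex offset by +0.8 line widths still lands on the apex
  hit2 <- assign_peak(sp, 3.0 - 0.8 * lw, window_lw = 2, line_width_ppm = lw,
                      noise_sigma = 1e-4)
  expect_equal(hit2$delta, 3.0, tolerance = diff(range(ppm)) / 16384)
  # empty window: nothing above 3 sigma
  miss <- assign_peak(sp, 2.5, window_lw = 2, line_width_ppm = lw,
                      noise_sigma = 1e-4)
  expect_equal(miss$status, "below_detection")
  expect_error(assign_peak(sp, 4.2, 2, lw, 1e-4), "outside")
})

test_that("assignment is monotone in window width", {
  ppm <- seq(4, 2, length.out = 16384)
  y <- voigt_profile(ppm, voigt_peak(3.0, 0.0007, 0.0005, 1))
  sp <- nmr_spectrum(ppm, y, 500.13)
  lw <- 0.003
  found <- vapply(c(1, 1.5, 2, 2.5, 4), function(w) {
    assign_peak(sp, 3.0 + 0.0012, w, lw, 1e-4)$status == "assigned"
  }, logical(1))
  # once assignable, wider windows keep finding it
  expect_true(all(found[which(found)[1]:length(found)]))
})

test_that("the full chain assigns every species close to ground truth", {
  models <- fx("models")
  for (seed in c(211, 212, 213)) {
    g <- generate_spectrum(synth_config(), seed = seed)
    p <- process_spectrum(g$spectrum, models)
    a <- p$assignments
    lw <- p$line_width_ppm
    for (i in seq_len(nrow(a))) {
      expect_equal(a$status[i] %in% c("assigned", "fallback_assigned"), TRUE,
                   label = paste(a$species[i], "status", a$status[i]))
      err <- abs(a$assigned[i] - g$truth$centers[[a$species[i]]])
      expect_lt(err, 2 * lw)
    }
  }
})

test_that("zero zinc yields below_detection for Zn systems only", {
  models <- fx("models")
  g <- generate_spectrum(synth_config(zn = 0), seed = 404)
  p <- process_spectrum(g$spectrum, models)
  a <- p$assignments
  st <- setNames(a$status, a$species)
  expect_equal(unname(st["zn_edta_singlet"]), "below_detection")
  expect_equal(unname(st["zn_edta_quartet"]), "below_detection")
  expect_equal(unname(st["ca_edta_singlet"]), "assigned")
  expect_equal(unname(st["mg_edta_singlet"]), "assigned")
})

test_that("suppressing the Ca singlet routes Mg through the wide fallback window", {
  models <- fx("models")
  g <- generate_spectrum(synth_config(), seed = 515)
  sp <- g$spectrum
  ct <- g$truth$centers[["ca_edta_singlet"]]
  idx <- which(abs(sp$ppm_axis - ct) < 0.02)
  sp$intensity[idx] <- median(sp$intensity[idx[1:5]])
  p <- process_spectrum(sp, models)
  a <- p$assignments
  row_mg <- a[a$species == "mg_edta_singlet", ]
  expect_equal(row_mg$status, "fallback_assigned")
  expect_equal(row_mg$window_lw, 2.5)
  expect_equal(row_mg$model, "FB_mg_s")
  expect_lt(abs(row_mg$assigned - g$truth$centers[["mg_edta_singlet"]]),
            2 * p$line_width_ppm)
})

test_that("assignment is anchored: perturbations outside windows change nothing", {
  models <- fx("models")
  g <- fx("sample1")
  p1 <- process_spectrum(g$spectrum, models)
  sp <- g$spectrum
  # large compact spurious feature far from every search window (8 ppm)
  bump <- abs(sp$ppm_axis - 8) < 0.3
  sp$intensity[bump] <- sp$intensity[bump] +
    5e5 * exp(-(sp$ppm_axis[bump] - 8)^2 / (2 * 0.05^2))
  p2 <- process_spectrum(sp, models)
  expect_identical(p1$assignments$assigned, p2$assignments$assigned)
  expect_identical(p1$assignments$status, p2$assignments$status)
})

test_that("model stores round-trip through JSON", {
  models <- fx("models")
  path <- withr::local_tempfile(fileext = ".json")
  write_shift_models(models, path)
  back <- read_shift_models(path)
  expect_equal(back$A$slope, models$A$slope, tolerance = 1e-12)
  expect_equal(back$C$rrmse, models$C$rrmse, tolerance = 1e-12)
  expect_s3_class(back$A, "shift_model")
})
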