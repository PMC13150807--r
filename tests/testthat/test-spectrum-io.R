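test_that("tsv spectra round-trip exactly and carry metadata", {
  sp <- nmr_spectrum(seq(10, 0, length.out = 257), rnorm(257),
                     field_mhz = 500.13, receiver_gain = 4, num_scans = 32,
                     label = "rt")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(sp, path, "tsv")
  back <- load_spectrum(path, "tsv", rg_normalize = FALSE)
  expect_identical(back$ppm_axis, sp$ppm_axis)
  expect_identical(back$intensity, sp$intensity)
  expect_equal(back$field_mhz, sp$field_mhz)
  expect_equal(back$num_scans, sp$num_scans)
})

test_that("receiver-gain normalization cancels the gain at load", {
  base <- seq(5, 0, length.out = 65)
  y <- sin(base)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(nmr_spectrum(base, y, 500.13, receiver_gain = 1), p1)
  write_spectrum(nmr_spectrum(base, 2 * y, 500.13, receiver_gain = 2), p2)
  s1 <- load_spectrum(p1, "tsv")
  s2 <- load_spectrum(p2, "tsv")
  expect_equal(s2$intensity, s1$intensity, tolerance = 1e-12)
  expect_equal(s2$receiver_gain, 1)
  expect_equal(s2$metadata$raw_receiver_gain, 2)
})

test_that("JCAMP-DX files round-trip", {
  sp <- nmr_spectrum(seq(9, 1, length.out = 128), rnorm(128), 600.13,
                     receiver_gain = 8, num_scans = 16)
  path <- withr::local_tempfile(fileext = ".jdx")
  write_spectrum(sp, path, "jcamp")
  back <- load_spectrum(path, "jcamp", rg_normalize = FALSE)
  expect_equal(back$ppm_axis, sp$ppm_axis, tolerance = 1e-12)
  expect_equal(back$intensity, sp$intensity, tolerance = 1e-12)
  expect_equal(back$field_mhz, 600.13)
  expect_equal(back$receiver_gain, 8)
})

test_that("Bruker-style fixture directory reads back with the recorded grid", {
  sp <- nmr_spectrum(seq(12, -2, length.out = 1024),
                     rnorm(1024, sd = 100), 500.13,
                     receiver_gain = 16, num_scans = 32)
  dir <- withr::local_tempdir()
  write_bruker_fixture(sp, dir)
  back <- load_spectrum(dir, "bruker_proc", rg_normalize = FALSE)
  expect_length(back$ppm_axis, 1024)    # axis length = parameter SI
  expect_equal(back$ppm_axis[1], 12)
  expect_equal(back$intensity, sp$intensity, tolerance = 1e-8)
  expect_equal(back$receiver_gain, 16)
  expect_equal(back$num_scans, 32L)
})

test_that("configuration errors are raised for unusable inputs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\t0.5", "0.5\t0.7", "0\t0.2"), path)
  expect_error(load_spectrum(path, "tsv"), "field_mhz")
  expect_silent(load_spectrum(path, "tsv", field_mhz = 500.13))
  expect_error(load_spectrum("no/such/file.tsv", "tsv"), "no such file")
  expect_error(nmr_spectrum(c(1, 2, 1.5), 1:3, 500), "monotone")
  expect_error(nmr_spectrum(1:4, 1:4, -1), "field_mhz")
})

test_that("noise estimation matches the sample sd and respects its region", {
  expect_equal(estimate_noise(flat_spectrum(4096)), 0)
  set.seed(42)
  n <- 65536
  sp <- nmr_spectrum(seq(14.5, -0.5, length.out = n), rnorm(n), 500.13)
  expect_equal(estimate_noise(sp), 1, tolerance = 0.05)
  idx <- which(sp$ppm_axis >= 13 & sp$ppm_axis <= 14)
  expect_equal(estimate_noise(sp), sd(sp$intensity[idx]))
  # invariant to signal entirely outside the region
  sp2 <- sp
  sp2$intensity[sp2$ppm_axis < 10] <- sp2$intensity[sp2$ppm_axis < 10] + 1e5
  expect_identical(estimate_noise(sp2), estimate_noise(sp))
  expect_error(estimate_noise(sp, c(20, 21)), "outside")
  expect_error(estimate_noise(sp, c(13, 13.001)), "fewer than 16")
})

test_that("scaling a spectrum scales noise by |k| and every bin by k", {
  set.seed(7)
  n <- 8192
  sp <- nmr_spectrum(seq(14.5, -0.5, length.out = n), rnorm(n), 500.13)
  k <- -3.7
  sk <- sp; sk$intensity <- k * sk$intensity
  expect_equal(estimate_noise(sk), abs(k) * estimate_noise(sp))
  b1 <- bin_and_center(list(sp), 0.1, region = c(0, 10), center = FALSE)
  b2 <- bin_and_center(list(sk), 0.1, region = c(0, 10), center = FALSE)
  expect_equal(b2$matrix, k * b1$matrix, tolerance = 1e-12)
})

test_that("binning arithmetic, alignment and centering behave as specified", {
  sp <- flat_spectrum(20000, value = 2, ppm = c(0, 10))
  b <- bin_and_center(list(sp), 0.02, region = c(0, 10), center = FALSE)
  expect_equal(ncol(b$matrix), 500)    # 10 ppm / 0.02 ppm
  # constant spectrum: every bin ~ constant x bin width
  expect_equal(unname(colMeans(b$matrix)), rep(2 * 0.02, 500),
               tolerance = 0.01)
  set.seed(1)
  spectra <- lapply(1:5, function(i)
    nmr_spectrum(seq(10, 0, length.out = 2048), rnorm(2048), 500.13))
  bc <- bin_and_center(spectra, 0.02, region = c(1, 9))
  expect_lt(max(abs(colMeans(bc$matrix))), 1e-10)
  expect_equal(length(bc$centers), ncol(bc$matrix))
  bad <- spectra
  bad[[2]]$field_mhz <- 600.13
  expect_error(bin_and_center(bad, 0.02), "share field_mhz")
})
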