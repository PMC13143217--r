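test_that("spectrum validation enforces the carrier invariants", {
  expect_s3_class(as_spectrum(400:500, runif(101)), "tbl_df")
  expect_error(as_spectrum(c(400, 400, 401), c(1, 2, 3)), "increasing")
  expect_error(as_spectrum(500, 1), "at least two")
  expect_error(as_spectrum(c(400, 500), c(1, NA)), "finite")
  expect_error(as_spectrum(c(100, 400), c(1, 1)), "250")
  # raw absorbance negatives from baseline noise are preserved
  expect_equal(as_spectrum(c(400, 500), c(-0.01, 1))$value[1], -0.01)
})

test_that("template peaks at 1 at lambda_max and is below 1 elsewhere", {
  for (lmax in c(360, 393, 436, 482, 545)) {
    spec <- govardovskii_absorbance(lmax)
    expect_equal(max(spec$value), 1)
    # the beta shoulder can pull the argmax slightly short of lambda_max
    expect_equal(peak_wavelength(spec), lmax, tolerance = 2 / lmax)
    # even the alpha band alone peaks a few tenths of a nm off lambda_max
    # at the short end of the range; that is a property of the template
    no_beta <- govardovskii_absorbance(lmax, beta_band = FALSE)
    expect_equal(peak_wavelength(no_beta), lmax, tolerance = 1 / lmax)
    away <- abs(spec$wavelength_nm - lmax) > 15
    expect_true(all(spec$value[away] < 1))
  }
  expect_error(govardovskii_absorbance(300), "330")
  expect_error(govardovskii_absorbance(700), "620")
})

test_that("template matches an independent hand evaluation of its closed form", {
  # value at 560 nm for a 500 nm pigment, alpha band only, computed from the
  # printed formula with independent arithmetic
  spec <- govardovskii_absorbance(500, beta_band = FALSE)
  v560 <- spec$value[abs(spec$wavelength_nm - 560) < 1e-9]
  expect_equal(v560, 0.2922045, tolerance = 1e-6)
})

test_that("beta band adds a short-wavelength shoulder only", {
  with_beta <- govardovskii_absorbance(545, beta_band = TRUE)
  without <- govardovskii_absorbance(545, beta_band = FALSE)
  short <- with_beta$wavelength_nm < 450
  expect_true(all(with_beta$value[short] >= without$value[short]))
  long <- with_beta$wavelength_nm > 545
  expect_equal(with_beta$value[long], without$value[long], tolerance = 1e-4)
})

test_that("long-limb 5% cutoff of the LW pigment sits near 643 nm", {
  lw <- govardovskii_absorbance(545)
  expect_equal(cutoff_wavelength(lw, 0.05, "long"), 643, tolerance = 3 / 643)
})

test_that("cutoff_wavelength interpolates exactly on a triangular spectrum", {
  wl <- seq(400, 600, 1)
  tri <- as_spectrum(wl, pmax(0, 1 - abs(wl - 500) / 100))
  # closed-form crossings of the two line segments
  expect_equal(cutoff_wavelength(tri, 0.045, "long"), 595.5)
  expect_equal(cutoff_wavelength(tri, 0.045, "short"), 404.5)
  expect_equal(cutoff_wavelength(tri, 1, "long"), 500)
})

test_that("cutoffs bracket the peak and move monotonically with lambda_max", {
  lams <- seq(400, 560, 40)
  longs <- shorts <- numeric(length(lams))
  for (i in seq_along(lams)) {
    spec <- govardovskii_absorbance(lams[i], beta_band = FALSE)
    longs[i] <- cutoff_wavelength(spec, 0.05, "long")
    shorts[i] <- cutoff_wavelength(spec, 0.25, "short")
    expect_gt(longs[i], lams[i])
    expect_lt(shorts[i], lams[i])
  }
  expect_true(all(diff(longs) > 0))
  expect_error(cutoff_wavelength(govardovskii_absorbance(545), 1e-9, "long"),
               "never falls")
})

test_that("normalize_peak scales to unit max and is idempotent", {
  spec <- as_spectrum(c(400, 450, 500), c(2, 4, 8))
  norm <- normalize_peak(spec)
  expect_equal(norm$value, c(0.25, 0.5, 1.0))
  expect_equal(normalize_peak(norm), norm)
  expect_error(normalize_peak(as_spectrum(c(400, 500), c(0, 0))), "positive")
})

test_that("resampling interpolates linearly and is idempotent on a grid", {
  two <- as_spectrum(c(400, 500), c(0, 1))
  expect_equal(resample_spectrum(two, c(425, 450))$value, c(0.25, 0.5))
  dense <- govardovskii_absorbance(482, seq(330, 700, 0.1))
  own <- resample_spectrum(dense, dense$wavelength_nm)
  expect_equal(own$value, dense$value)
  once <- resample_spectrum(dense, seq(350, 650, 1))
  twice <- resample_spectrum(once, seq(350, 650, 1))
  expect_equal(once, twice)
  # 1 nm resampling locates the peak within 1 nm of the 0.1 nm grid
  expect_equal(peak_wavelength(once), peak_wavelength(dense), tolerance = 1)
  expect_error(resample_spectrum(two, c(300, 450)), "extrapolation")
})

test_that("spectrum CSV round-trips through the two-column dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  spec <- govardovskii_absorbance(436, seq(350, 550, 5))
  write_spectrum_csv(spec, path)
  expect_equal(read_spectrum_csv(path), spec)
  # comment lines are tolerated
  writeLines(c("# instrument: synthetic", readLines(path)), path)
  expect_equal(read_spectrum_csv(path), spec)
})
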