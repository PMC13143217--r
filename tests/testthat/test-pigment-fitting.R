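test_that("preprocessing windows, floors and normalizes a replicate", {
  grid <- seq(300, 700, 1)
  clean <- govardovskii_absorbance(482, grid)
  out <- preprocess_replicate(clean, window = c(400, 600))
  expect_true(all(out$value >= 0))
  expect_equal(max(out$value), 1)
  # constant instrument offset leaves the preprocessed shape unchanged
  shifted <- clean
  shifted$value <- shifted$value + 0.1
  expect_equal(preprocess_replicate(shifted, c(400, 600)), out)
  noisy <- simulate_absorbance_replicates(482, n = 1, noise_sd = 0.05,
                                          seed = 4)
  pn <- preprocess_replicate(as_spectrum(noisy$wavelength_nm,
                                         noisy$absorbance))
  expect_gte(min(pn$value), 0)
  expect_equal(max(pn$value), 1)
  expect_error(preprocess_replicate(as_spectrum(c(400, 450, 500), c(1, 1, 1)),
                                    c(400, 500)),
               "flat")
})

test_that("noiseless templates are recovered exactly across the cone range", {
  grid <- seq(300, 700, 1)
  for (lmax in c(360, 393, 436, 482, 545)) {
    spec <- govardovskii_absorbance(lmax, grid)
    expect_equal(fit_lambda_max(spec), lmax, tolerance = 0.1 / lmax)
  }
})

test_that("fitting refuses featureless spectra", {
  flat <- as_spectrum(seq(400, 600, 1), rep(1, 201) + seq(0, 0.001, length.out = 201))
  expect_error(fit_lambda_max(flat), "minimum|flat")
})

test_that("the fit is unbiased at realistic measurement noise", {
  grid <- seq(300, 700, 1)
  tmpl <- govardovskii_absorbance(393, grid)$value
  withr::with_seed(7, {
    hats <- vapply(1:100, function(i) {
      fit_lambda_max(as_spectrum(grid, tmpl + rnorm(length(grid), 0, 0.02)))
    }, numeric(1))
  })
  expect_lt(abs(mean(hats) - 393), 1)
  expect_lt(sd(hats), 5)
})

test_that("bootstrap on identical replicates collapses to a zero-width CI", {
  grid <- seq(300, 700, 1)
  reps <- simulate_absorbance_replicates(436, n = 4, noise_sd = 0,
                                         grid = grid, seed = 1)
  fit <- bootstrap_lambda_max(reps, n_boot = 25, seed = 2)
  expect_equal(fit$ci_low, fit$ci_high)
  expect_equal(fit$ci_low, fit$lambda_max_hat, tolerance = 1e-6)
  expect_length(fit$bootstrap_estimates, 25)
})

test_that("bootstrap is deterministic under a fixed seed", {
  reps <- simulate_absorbance_replicates(545, n = 3, noise_sd = 0.02,
                                         seed = 11)
  a <- bootstrap_lambda_max(reps, n_boot = 30, seed = 5)
  b <- bootstrap_lambda_max(reps, n_boot = 30, seed = 5)
  expect_identical(a$bootstrap_estimates, b$bootstrap_estimates)
  c <- bootstrap_lambda_max(reps, n_boot = 30, seed = 6)
  expect_false(identical(a$bootstrap_estimates, c$bootstrap_estimates))
})

test_that("bootstrap point estimate ignores replicate order", {
  reps <- simulate_absorbance_replicates(482, n = 5, noise_sd = 0.02,
                                         seed = 21)
  shuffled <- reps
  shuffled$replicate_id <- dplyr::recode(reps$replicate_id,
                                         `1` = 4L, `2` = 5L, `3` = 1L,
                                         `4` = 2L, `5` = 3L)
  shuffled <- dplyr::arrange(shuffled, replicate_id, wavelength_nm)
  a <- bootstrap_lambda_max(reps, n_boot = 10, seed = 1)
  b <- bootstrap_lambda_max(shuffled, n_boot = 10, seed = 1)
  expect_equal(a$lambda_max_hat, b$lambda_max_hat, tolerance = 1e-9)
})

test_that("a single replicate falls back to the residual bootstrap", {
  reps <- simulate_absorbance_replicates(393, n = 1, noise_sd = 0.02,
                                         seed = 31)
  fit <- bootstrap_lambda_max(reps, n_boot = 50, seed = 3)
  expect_equal(fit$n_replicates, 1)
  expect_gt(fit$ci_high, fit$ci_low)
  expect_true(fit$ci_low <= fit$lambda_max_hat + 1 &&
                fit$ci_high >= fit$lambda_max_hat - 1)
  expect_error(bootstrap_lambda_max(reps, n_boot = 1, seed = 1), "n_boot")
})

test_that("CI width does not grow, on average, with more replicates", {
  # paired comparison on nested data: the first 3 replicates of each pool
  # against all 9, plain percentile so the interval width tracks the
  # bootstrap spread alone
  widths <- vapply(1:12, function(i) {
    pool <- simulate_absorbance_replicates(545, n = 9, noise_sd = 0.02,
                                           seed = 700 + i)
    sub <- pool[pool$replicate_id <= 3, ]
    f3 <- bootstrap_lambda_max(sub, n_boot = 60, seed = 800 + i,
                               ci_method = "percentile")
    f9 <- bootstrap_lambda_max(pool, n_boot = 60, seed = 800 + i,
                               ci_method = "percentile")
    c(f3$ci_high - f3$ci_low, f9$ci_high - f9$ci_low)
  }, numeric(2))
  expect_lt(mean(widths[2, ]), mean(widths[1, ]))
})

test_that("tidy/glance expose the bootstrap draws and fit summary", {
  reps <- simulate_absorbance_replicates(436, n = 3, noise_sd = 0.01,
                                         seed = 41, pigment = "SWS2")
  fit <- bootstrap_lambda_max(reps, n_boot = 20, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 20)
  expect_equal(td$lambda_max, fit$bootstrap_estimates)
  gl <- glance(fit)
  expect_equal(gl$pigment, "SWS2")
  expect_true(gl$ci_low <= gl$lambda_max && gl$lambda_max <= gl$ci_high)
  report <- fit_report(list(fit, fit))
  expect_equal(nrow(report), 2)
})

test_that("long-format absorbance CSV round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  reps <- simulate_absorbance_replicates(482, n = 2, noise_sd = 0.01,
                                         seed = 51, pigment = "Rh2")
  readr::write_csv(reps, path)
  back <- read_absorbance_csv(path)
  expect_equal(back$absorbance, reps$absorbance)
  fit <- bootstrap_lambda_max(back, n_boot = 10, seed = 1)
  expect_equal(fit$pigment_name, "Rh2")
})
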