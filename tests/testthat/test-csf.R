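test_that("Michelson contrast of luminance pairs follows the definition", {
  expect_equal(michelson_contrast(50, 50), 0)
  expect_equal(michelson_contrast(0, 80), 1)
  expect_equal(michelson_contrast(20, 80), 0.6)
  expect_error(michelson_contrast(80, 20), "i_max")
  expect_error(michelson_contrast(0, 0), "undefined")
})

test_that("the four-of-five rule accepts >= 4 reflex responses", {
  expect_true(reliable_response(c(TRUE, TRUE, TRUE, TRUE, FALSE)))
  expect_false(reliable_response(c(TRUE, TRUE, TRUE, FALSE, FALSE)))
  expect_true(reliable_response(rep(TRUE, 5)))
  expect_error(reliable_response(rep(TRUE, 4)), "5")
})

make_blocks <- function(levels, hits, id = "A", freq = 0.95) {
  purrr::map2_dfr(levels, hits, function(ct, h) {
    tibble::tibble(individual_id = id, spatial_frequency_cpd = freq,
                   contrast = ct,
                   response = c(rep(TRUE, h), rep(FALSE, 5 - h)))
  })
}

test_that("threshold is the lowest reliable contrast level", {
  trials <- make_blocks(c(0.99, 0.20, 0.06, 0.03), c(5, 5, 4, 2))
  pts <- csf_points(trials)
  expect_equal(pts$threshold_contrast, 0.06)
  expect_equal(pts$sensitivity, 1 / 0.06, tolerance = 1e-9)
  # boundary: everything reliable down to the minimum tested level
  all_ok <- make_blocks(default_contrast_ladder(), rep(5, 12))
  expect_equal(csf_points(all_ok)$threshold_contrast, 0.012)
  # degenerate: no reliable level is flagged, not dropped silently
  none <- make_blocks(c(0.99, 0.5), c(3, 2))
  out <- csf_points(none)
  expect_true(out$no_threshold)
  expect_true(is.na(out$threshold_contrast))
})

test_that("making a lower block reliable can only lower the threshold", {
  base <- make_blocks(c(0.99, 0.20, 0.06), c(5, 5, 3))
  improved <- make_blocks(c(0.99, 0.20, 0.06), c(5, 5, 4))
  expect_lte(csf_points(improved)$threshold_contrast,
             csf_points(base)$threshold_contrast)
})

test_that("sensitivity is the exact inverse of the threshold everywhere", {
  csf_true <- tibble::tibble(
    spatial_frequency_cpd = c(0.47, 0.85, 1.59),
    sensitivity = c(6, 16.67, 1.5))
  trials <- simulate_ocr_trials(csf_true, seed = 3)
  pts <- csf_points(trials)
  expect_equal(pts$sensitivity * pts$threshold_contrast,
               rep(1, nrow(pts)))
})

test_that("a deterministic observer's thresholds are the ladder values implied by its CSF", {
  ladder <- default_contrast_ladder()
  csf_true <- tibble::tibble(
    spatial_frequency_cpd = c(0.47, 0.56, 0.85, 1.06, 1.27, 1.59),
    sensitivity = c(5, 8, 16.67, 12, 5, 1.2))
  trials <- simulate_ocr_trials(csf_true, contrast_ladder = ladder,
                                lapse_rate = 0, seed = 9)
  pts <- csf_points(trials)
  expected <- vapply(csf_true$sensitivity, function(s) {
    min(ladder[ladder >= 1 / s])
  }, numeric(1))
  expect_equal(pts$threshold_contrast, expected)
})

test_that("csf_fit extracts peak and cut-off for one individual", {
  pts <- tibble::tibble(
    individual_id = "A",
    spatial_frequency_cpd = c(0.47, 0.85, 1.27, 1.59),
    threshold_contrast = c(0.2, 0.06, 0.25, 0.99),
    sensitivity = 1 / threshold_contrast,
    no_threshold = FALSE)
  csf <- csf_fit(pts)
  expect_equal(csf$peak_frequency_cpd, 0.85)
  expect_equal(csf$peak_sensitivity, 1 / 0.06)
  expect_gte(csf$cutoff_frequency_cpd, csf$peak_frequency_cpd)
  expect_error(csf_fit(dplyr::mutate(pts, individual_id = c("A", "A", "B", "B"))),
               "single individual")
})

test_that("cut-off frequency inverts a constructed log-log limb exactly", {
  # limb s(f) = (f/1.6)^-3 crosses sensitivity 1 at exactly 1.6 cpd
  pts <- tibble::tibble(
    individual_id = "A",
    spatial_frequency_cpd = c(0.8, 1.2),
    sensitivity = c(8, 2.3703703703703716),
    threshold_contrast = 1 / sensitivity,
    no_threshold = FALSE)
  csf <- csf_fit(pts)
  expect_equal(csf$cutoff_frequency_cpd, 1.6, tolerance = 1e-9)
  # endpoint hit: the last point already sits at sensitivity 1
  pts2 <- tibble::tibble(
    individual_id = "A",
    spatial_frequency_cpd = c(1.27, 1.59),
    sensitivity = c(4, 1),
    threshold_contrast = 1 / sensitivity,
    no_threshold = FALSE)
  expect_equal(csf_fit(pts2)$cutoff_frequency_cpd, 1.59)
  # flat CSF entirely below sensitivity 1 on one point: no cutoff
  pts3 <- tibble::tibble(
    individual_id = "A",
    spatial_frequency_cpd = 0.85,
    sensitivity = 16.67,
    threshold_contrast = 1 / sensitivity,
    no_threshold = FALSE)
  expect_true(is.na(csf_fit(pts3)$cutoff_frequency_cpd))
})

test_that("group summary averages peaks and matched-frequency curves", {
  freqs <- c(0.47, 0.56, 0.85, 1.06, 1.27, 1.59)
  trials <- dplyr::bind_rows(
    simulate_ocr_trials(
      tibble::tibble(spatial_frequency_cpd = freqs,
                     sensitivity = c(5, 8, 16.67, 12, 5, 1.2)),
      individual_id = "A", seed = 1),
    simulate_ocr_trials(
      tibble::tibble(spatial_frequency_cpd = freqs,
                     sensitivity = c(4, 6, 12, 16.67, 8, 1.3)),
      individual_id = "B", seed = 2))
  csfs <- fit_csfs(trials)
  summary <- csf_summary(csfs)
  # individual optimal frequencies recovered at 0.85 and 1.06 cpd
  expect_equal(sort(summary$per_individual$peak_frequency_cpd),
               c(0.85, 1.06))
  expect_equal(summary$mean_peak_frequency_cpd, 0.955)
  # both observers threshold at the 0.06 ladder level at their peak
  expect_equal(summary$mean_peak_sensitivity, 1 / 0.06, tolerance = 1e-9)
  expect_equal(summary$min_brightness_difference, 0.06, tolerance = 1e-9)
  expect_equal(nrow(summary$mean_curve), length(freqs))
  # single individual: group equals individual
  solo <- csf_summary(csfs[["A"]])
  expect_equal(solo$mean_peak_frequency_cpd, 0.85)
  expect_error(csf_summary(list()), "at least one")
})

test_that("trial CSVs round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".csv")
  trials <- simulate_ocr_trials(
    tibble::tibble(spatial_frequency_cpd = c(0.85, 1.59),
                   sensitivity = c(16.67, 1.2)), seed = 5)
  readr::write_csv(trials, path)
  back <- read_trials_csv(path)
  expect_equal(csf_points(back), csf_points(trials))
})
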