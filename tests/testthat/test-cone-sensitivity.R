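test_that("C-type lambda_mid follows the affine relation", {
  expect_equal(c_type_lambda_mid(436), 432.52)
  # the measured SWS2 CI endpoints bracket the published 430-434 nm range
  expect_equal(c_type_lambda_mid(433), 430.06)
  expect_equal(c_type_lambda_mid(439), 434.98)
  # affine identity: f(a) + f(b) == f(a + b) + 75 evaluated off-range-safe
  expect_equal(c_type_lambda_mid(430) + c_type_lambda_mid(440),
               0.82 * (430 + 440) + 150)
  expect_error(c_type_lambda_mid(500), "range")
})

test_that("droplet transmission is a logistic cut-on with T-type identity", {
  grid <- seq(350, 700, 0.5)
  t_type <- droplet_transmission("T", grid = grid)
  expect_true(all(t_type$value == 1))
  c_type <- droplet_transmission("C", lambda_mid = 432.52, grid = grid)
  at_mid <- c_type$value[abs(c_type$wavelength_nm - 432.5) < 0.3]
  expect_equal(at_mid[1], 0.5, tolerance = 1e-2)
  # hand evaluation of the logistic: Y-type at 532 with mid 523, k = 0.12
  y <- droplet_transmission("Y", lambda_mid = 523, k = 0.12, grid = 523:540)
  expect_equal(y$value[y$wavelength_nm == 532], 0.7464940, tolerance = 1e-6)
  expect_true(all(diff(c_type$value) >= 0))
  transition <- c_type$value[c_type$wavelength_nm > 390 &
                               c_type$wavelength_nm < 480]
  expect_true(all(diff(transition) > 0))
  expect_error(droplet_transmission("Y"), "lambda_mid")
  expect_error(droplet_transmission("Y", lambda_mid = 523, k = -1), "positive")
})

test_that("effective sensitivities reproduce the modelled cone peaks", {
  # T-type droplet is an identity filter
  sws1 <- effective_sensitivity(393, "T")
  expect_equal(sws1$peak_nm, 393, tolerance = 0.5 / 393)
  # C/Y/R filtering red-shifts the peaks to the published values
  sws2 <- effective_sensitivity(436, "C", lambda_mid = "auto", k = 0.15)
  expect_equal(sws2$peak_nm, 449, tolerance = 3 / 449)
  rh2 <- effective_sensitivity(482, "Y", lambda_mid = 523, k = 0.12)
  expect_equal(rh2$peak_nm, 532, tolerance = 3 / 532)
  lw <- effective_sensitivity(545, "R", lambda_mid = 586, k = 0.12)
  expect_equal(lw$peak_nm, 595, tolerance = 3 / 595)
  # summary invariant: lower cutoff < peak < upper cutoff, values in [0, 1]
  for (cone in list(sws2, rh2, lw)) {
    expect_lt(cone$lower_cutoff_nm, cone$peak_nm)
    expect_gt(cone$upper_cutoff_nm, cone$peak_nm)
    expect_true(all(cone$sensitivity$value >= 0 &
                      cone$sensitivity$value <= 1))
  }
})

test_that("long-pass filtering never blue-shifts the peak", {
  for (lmax in c(450, 482, 545)) {
    for (mid in c(lmax - 10, lmax + 20, lmax + 41)) {
      eff <- effective_sensitivity(lmax, "Y", lambda_mid = mid, k = 0.12)
      expect_gte(eff$peak_nm, lmax - 0.2)
    }
  }
})

test_that("droplet filtering leaves the long-wavelength limb unchanged", {
  pig <- govardovskii_absorbance(545)
  eff <- effective_sensitivity(545, "R", lambda_mid = 586, k = 0.12)
  # the cutoff is referenced to the pigment peak, so attenuation by the
  # droplet must not move it off the pigment's own 5% crossing
  expect_equal(eff$upper_cutoff_nm, cutoff_wavelength(pig, 0.05, "long"),
               tolerance = 1 / 643)
})

test_that("the cone summary table covers the full black grouse set", {
  tab <- cone_sensitivity_table()
  expect_equal(tab$cone, c("SWS1", "SWS2", "Rh2", "LW"))
  expect_equal(tab$peak_nm, c(393, 449, 532, 595), tolerance = 3 / 393)
  expect_true(all(tab$upper5_nm > tab$peak_nm))
})

test_that("perception range upper bound is the LW pigment 5% cutoff", {
  pr <- perception_range(c(SWS1 = 393, SWS2 = 436, Rh2 = 482, LW = 545))
  expect_equal(pr$upper_nm, 643, tolerance = 3 / 643)
  # with the beta band the SWS1 short limb never reaches 5% within the grid
  expect_true(is.na(pr$lower_nm))
  pr_nb <- perception_range(c(SWS1 = 393, SWS2 = 436, Rh2 = 482, LW = 545),
                            beta_band = FALSE)
  expect_false(is.na(pr_nb$lower_nm))
  expect_lt(pr_nb$lower_nm, 393)
  expect_error(perception_range(c(SWS1 = 393)), "four")
})

test_that("shifting the LW pigment shifts the upper cutoff by a similar amount", {
  base <- perception_range(c(SWS1 = 393, SWS2 = 436, Rh2 = 482, LW = 545))
  up <- perception_range(c(SWS1 = 393, SWS2 = 436, Rh2 = 482, LW = 555))
  shift <- up$upper_nm - base$upper_nm
  expect_gt(shift, 8)
  expect_lt(shift, 14)
})
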