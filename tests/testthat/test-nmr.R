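test_that("calibration on an exact line recovers it with zero residual", {
  x <- c(5, 10, 25, 50, 100)
  cal <- fit_calibration(x, 2 * x)
  expect_equal(cal$slope, 2, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-10)
  expect_equal(cal$residual_sd, 0, tolerance = 1e-10)
  expect_equal(cal$r, 1)
  expect_error(fit_calibration(rep(5, 4), 1:4), "identical")
  expect_error(fit_calibration(1:2, 1:2), ">= 3")
})

test_that("noisy calibration recovers the slope within its own 95% CI", {
  pts <- generate_calibration_fixture(slope = 0.002, intercept = 0,
                                      noise_sd = 0.001,
                                      levels = c(5, 10, 15, 20, 25, 30),
                                      seed = 7)
  cal <- fit_calibration(pts$concentration, pts$response)
  half <- qt(0.975, cal$n - 2) * cal$residual_sd /
    sqrt(sum((pts$concentration - mean(pts$concentration))^2))
  expect_lt(abs(cal$slope - 0.002), half + 1e-12)
})

test_that("the wide-range assay fixture is linear with R > 0.999", {
  rep <- nmr_validation_report(seed = 1)
  expect_gt(rep$calibration$r, 0.999)
  expect_equal(rep$calibration$range, c(5, 10000))
})

test_that("regression-rule LOD/LOQ follow the residual-SD formula exactly", {
  x <- c(5, 10, 15, 20, 25)
  cal <- fit_calibration(x, 2 * x)          # zero residual
  expect_equal(unname(lod_loq_from_regression(cal)), c(0, 0))

  pts <- generate_calibration_fixture(0.002, 0, 0.001, c(5, 10, 15, 20, 25),
                                      replicates = 3, seed = 9)
  cal2 <- fit_calibration(pts$concentration, pts$response)
  ll <- lod_loq_from_regression(cal2)
  expect_equal(unname(ll["lod"] / ll["loq"]), 3.3 / 10, tolerance = 1e-12)
  # brute-force definition: smallest concentration whose predicted signal
  # exceeds k * s_{y/x} above the intercept
  brute <- uniroot(function(c0) cal2$intercept + cal2$slope * c0 -
                     (cal2$intercept + 3.3 * cal2$residual_sd),
                   c(0, 100), tol = 1e-12)$root
  expect_equal(unname(ll["lod"]), brute, tolerance = 1e-8)
  # the near-LOD fixture is tuned to residual_sd/slope ~ 0.5 -> LOD ~ 1.6
  expect_lt(abs(ll["lod"] - 1.65), 1.2)

  cal_bad <- cal2; cal_bad$slope <- -1
  expect_error(lod_loq_from_regression(cal_bad), "slope")
})

test_that("SNR-rule LOD/LOQ on a constructed trace with known SNR", {
  tr <- generate_spectrum_trace(0.5, amplitude = 30, width = 0.005,
                                noise_sd = 0.5, seed = 10)
  res <- lod_loq_from_snr(tr$intensity, tr$signal_window, tr$noise_window,
                          concentration = 30)
  expect_lt(abs(res$snr - 30) / 30, 0.25)
  expect_equal(res$lod, 3 * 30 / res$snr)
  expect_equal(res$loq, 10 * 30 / res$snr)
  expect_false(res$flag)

  # scale invariance: doubling concentration and amplitude together
  tr2 <- generate_spectrum_trace(0.5, amplitude = 60, width = 0.005,
                                 noise_sd = 0.5, seed = 10)
  res2 <- lod_loq_from_snr(tr2$intensity, tr2$signal_window,
                           tr2$noise_window, concentration = 60)
  expect_equal(res2$lod, res$lod, tolerance = 0.1)

  # a noise window with zero SD flags and reports zero limits
  res0 <- lod_loq_from_snr(c(rep(0, 32), 5, rep(0, 31)), 30:36, 1:20, 30)
  expect_true(res0$flag)
  expect_equal(res0$lod, 0)
  expect_error(lod_loq_from_snr(1:10, 1:5, 4:8, 1), "disjoint")
})

test_that("recovery and CV follow their definitions and unit invariance", {
  rec <- recovery_and_precision(c(99, 104, 115, 108) / 100 * 1000,
                                rep(1000, 4))
  expect_equal(rec$recovery, c(99, 104, 115, 108))
  expect_equal(rec$mean_recovery, 106.5)

  exact <- recovery_and_precision(5 + c(10, 20), c(10, 20), baseline = 5)
  expect_equal(exact$recovery, c(100, 100))

  r1 <- recovery_and_precision(c(12, 13), c(10, 11), baseline = 2,
                               replicates = c(9, 9, 9))
  r2 <- recovery_and_precision(1e3 * c(12, 13), 1e3 * c(10, 11),
                               baseline = 2e3, replicates = 1e3 * c(9, 9, 9))
  expect_equal(r1$recovery, r2$recovery)
  expect_equal(r1$cv, 0)
  expect_error(recovery_and_precision(1, 0), "> 0")
})

test_that("paired method comparison reproduces the assay cross-check", {
  tab <- read_method_comparison()
  expect_equal(nrow(tab), 15)
  expect_equal(sum(is.na(tab$nmr)), 5)

  cmp <- method_comparison(tab$nmr, tab$hplc, nd_policy = "as_zero")
  expect_equal(cmp$n, 15)
  expect_equal(cmp$r, 0.98, tolerance = 0.005)
  expect_true(cmp$slope_ci_contains_1)
  expect_true(cmp$intercept_ci_contains_0)

  cmp_drop <- method_comparison(tab$nmr, tab$hplc, nd_policy = "drop")
  expect_equal(cmp_drop$n, 10)
  expect_equal(cmp_drop$r, 0.85, tolerance = 0.005)

  # exact identity: confint warns about the zero-residual fit
  same <- suppressWarnings(method_comparison(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(same$r, 1)
  expect_equal(same$slope, 1, tolerance = 1e-12)
  expect_equal(same$intercept, 0, tolerance = 1e-12)

  # symmetry of r in the two methods
  cmp_ba <- method_comparison(tab$hplc, tab$nmr, nd_policy = "as_zero")
  expect_equal(cmp_ba$r, cmp$r, tolerance = 1e-12)

  expect_error(method_comparison(c(1, NA, NA, NA), c(1, NA, NA, NA),
                                 nd_policy = "drop"), "3 usable")
})
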