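test_that("sample table respects incidence, units and determinism", {
  gens <- default_agent_generators()
  tab <- generate_sample_table(54, gens, seed = 1)
  expect_equal(nrow(tab), 54 * length(gens))
  expect_true(all(tab$value >= 0))
  expect_identical(tab, generate_sample_table(54, gens, seed = 1))

  units <- unique(tab[c("analyte", "unit")])
  expect_equal(units$unit[units$analyte == "nicotine"], "mg/ml")
  expect_equal(units$unit[units$analyte == "glycerol"], "g/100g")
  expect_equal(units$unit[units$analyte == "thujone"], "mg/L")

  gens$nicotine$incidence <- 0
  tab0 <- generate_sample_table(54, gens, seed = 2)
  expect_true(all(tab0$value[tab0$analyte == "nicotine"] == 0))

  gens$nicotine$incidence <- 2
  expect_error(generate_sample_table(5, gens), "incidence")
})

test_that("positive fraction stays inside binomial bounds over seeds", {
  gen <- list(nicotine = list(
    incidence = 0.65,
    spec = risk_truncate(risk_normal(16.9, 10), lower = 0),
    unit = "mg/ml"))
  p_hat <- vapply(1:20, function(s) {
    tab <- generate_sample_table(54, gen, seed = s)
    mean(tab$value > 0)
  }, 0)
  se <- sqrt(0.65 * 0.35 / 54)
  expect_lt(abs(mean(p_hat) - 0.65), 2 * se / sqrt(20) + 0.02)
  expect_true(all(abs(p_hat - 0.65) < 4 * se))
})

test_that("generated low-incidence analytes flow into the resample strategy", {
  gen <- list(thujone = list(incidence = 2 / 54,
                             spec = risk_resample(c(178, 183)),
                             unit = "mg/L"))
  tab <- generate_sample_table(54, gen, seed = 5)
  res <- select_best_fit(tab$value)
  expect_equal(res$strategy, "resample")
  expect_true(all(res$spec$params$values %in% c(0, 178, 183)))
})

test_that("label discordance matches the requested rates and audits back", {
  tab <- generate_sample_table(54, seed = 42)
  lab <- generate_label_metadata(tab, seed = 43)
  audit <- audit_labels(lab)
  nic <- lab[lab$analyte == "nicotine", ]
  n_zero <- sum(nic$value == 0)
  expect_equal(audit$false_containing, 1)
  expect_equal(audit$false_free,
               round((n_zero - 1) * (5 / 23) / (1 - 5 / 23)))
  expect_equal(audit$declared_free, (n_zero - 1) + audit$false_free)

  concordant <- generate_label_metadata(tab, false_free_rate = 0,
                                        false_containing_count = 0,
                                        seed = 44)
  a2 <- audit_labels(concordant)
  expect_equal(a2$false_free, 0)
  expect_equal(a2$false_containing, 0)
  expect_error(generate_label_metadata(tab[tab$analyte == "glycerol", ]),
               "nicotine")
})

test_that("synthetic resample vectors reproduce the reported moments", {
  # thujone is exactly known; the other two are synthetic reconstructions
  tj <- c(rep(0, 52), synthetic_positive_values("thujone"))
  expect_equal(mean(tj), 6.7, tolerance = 0.01)

  pd <- c(rep(0, 47), synthetic_positive_values("propanediol_13"))
  expect_equal(mean(pd), 0.60, tolerance = 0.01)
  expect_equal(sd(pd), 1.7, tolerance = 0.01)

  ev <- c(rep(0, 40), synthetic_positive_values("ethyl_vanillin"))
  expect_equal(mean(ev), 30, tolerance = 0.001)
  expect_equal(sd(ev), 68, tolerance = 0.001)
  expect_equal(range(synthetic_positive_values("ethyl_vanillin")),
               c(7.7, 335))
})

test_that("noiseless fixtures are recovered exactly by the fitters", {
  pts <- generate_calibration_fixture(0.002, 0.1, 0, c(5, 10, 25), 2,
                                      seed = 1)
  cal <- fit_calibration(pts$concentration, pts$response)
  expect_equal(cal$slope, 0.002, tolerance = 1e-12)
  expect_equal(cal$intercept, 0.1, tolerance = 1e-12)

  pts2 <- generate_calibration_fixture(0.002, 0, 0.0005,
                                       seq(5, 25, by = 2), 20, seed = 2)
  cal2 <- fit_calibration(pts2$concentration, pts2$response)
  expect_lt(abs(cal2$residual_sd - 5e-4) / 5e-4, 0.2)
  expect_error(generate_calibration_fixture(1, 0, 0, numeric(0)),
               "non-empty")
})

test_that("spectrum traces have the designed peak and SNR", {
  tr0 <- generate_spectrum_trace(0.4, 30, 0.01, 0, n_points = 1001)
  expect_equal(max(tr0$intensity), 30, tolerance = 1e-6)
  expect_equal(tr0$x[which.max(tr0$intensity)], 0.4, tolerance = 1e-3)

  tr <- generate_spectrum_trace(0.5, 30, 0.005, 0.5, n_points = 4096,
                                seed = 3)
  snr <- max(tr$intensity[tr$signal_window]) /
    (2 * sd(tr$intensity[tr$noise_window]))
  expect_lt(abs(snr - 30) / 30, 0.25)

  flat <- generate_spectrum_trace(0.5, 0, 0.005, 0.5, seed = 4)
  res <- lod_loq_from_snr(flat$intensity, flat$signal_window,
                          flat$noise_window, 30)
  expect_lt(res$snr, 3)
})

test_that("generate -> fit -> simulate round trip recovers the study summary", {
  # distributions refitted from one n = 54 synthetic table: means within
  # +/-25% of the pass-through values (small-sample fitting noise)
  tab <- generate_sample_table(54, seed = 901)
  fits <- fit_sample_table(tab)
  for (a in c("nicotine", "glycerol")) {
    spec_fit <- fits[[a]]$spec
    spec_true <- study_specs()[[a]]
    m_fit <- simulate_exposure(exposure_model(a, spec_fit), 5000,
                               seed = 902)
    m_true <- simulate_exposure(exposure_model(a, spec_true), 5000,
                                seed = 902)
    expect_lt(abs(mean(m_fit$exposure) - mean(m_true$exposure)) /
                mean(m_true$exposure), 0.25, label = a)
  }
})
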