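test_that("quantile function matches closed forms and truncation floors", {
  expect_equal(dist_quantile(risk_uniform(6, 81), 0.5), 43.5)

  tri <- risk_truncate(risk_triang(-18.939, 91.8, 100.45), lower = 0)
  expect_gte(dist_quantile(tri, 1e-9), 0)
  expect_lt(dist_quantile(tri, 1e-9), 1e-3)

  # log-logistic median is location + scale; cross-check by numeric CDF
  # inversion, independent of the quantile implementation
  ll <- risk_loglogistic(-0.40204, 5.15, 1.8215)
  expect_equal(dist_quantile(ll, 0.5), -0.40204 + 5.15, tolerance = 1e-10)
  inv <- uniroot(function(x) dist_cdf(ll, x) - 0.5, c(-0.4, 100),
                 tol = 1e-12)$root
  expect_equal(dist_quantile(ll, 0.5), inv, tolerance = 1e-8)

  expect_error(dist_quantile(ll, 0), "strictly between")
  expect_error(dist_quantile(ll, 1.2), "strictly between")
})

test_that("quantile is monotone in u across random specs", {
  set.seed(101)
  u <- sort(runif(60, 1e-6, 1 - 1e-6))
  for (i in 1:25) {
    spec <- random_spec()
    q <- dist_quantile(spec, u)
    expect_true(all(diff(q) >= 0), info = spec$family)
  }
})

test_that("constructor invariants are enforced", {
  expect_error(risk_normal(0, -1), "sd > 0")
  expect_error(risk_triang(5, 2, 10), "min <= mode <= max")
  expect_error(risk_uniform(3, 3), "min < max")
  expect_error(risk_loglogistic(0, -1, 2), "scale > 0")
  expect_error(risk_truncate(risk_normal(0, 1), lower = 2, upper = 1),
               "lower < upper")
  expect_error(risk_truncate(risk_uniform(0, 1), lower = 5),
               "zero probability mass")
})

test_that("normal_from_quantiles solves the two-quantile equations", {
  p <- normal_from_quantiles(0.25, 3, 0.75, 5)
  expect_equal(unname(p["mean"]), 4)
  expect_equal(unname(p["sd"]), 2 / (2 * qnorm(0.75)), tolerance = 1e-12)
  expect_equal(unname(p["sd"]), 1.4826, tolerance = 1e-4)

  p2 <- normal_from_quantiles(0.05, -1.6449, 0.95, 1.6449)
  expect_equal(unname(p2["mean"]), 0, tolerance = 1e-12)
  expect_equal(unname(p2["sd"]), 1, tolerance = 1e-4)

  expect_error(normal_from_quantiles(0.25, 5, 0.75, 5), "q_lo < q_hi")
  # solved quantiles round-trip through the distribution itself
  d <- risk_normal_alt(0.25, 3, 0.75, 5)
  expect_equal(dist_quantile(d, 0.25), 3, tolerance = 1e-10)
  expect_equal(dist_quantile(d, 0.75), 5, tolerance = 1e-10)
})

test_that("analytic means match closed forms and numeric integration", {
  expect_equal(analytic_mean(risk_triang(-18.939, 91.8, 100.45)),
               (-18.939 + 91.8 + 100.45) / 3, tolerance = 1e-12)

  # truncated normal: mu + sigma * phi(a) / (1 - Phi(a)), checked against
  # numeric integration of the quantile function
  tn <- risk_truncate(risk_normal(11.023, 13.134), lower = 0)
  a <- (0 - 11.023) / 13.134
  expect_equal(analytic_mean(tn),
               11.023 + 13.134 * dnorm(a) / (1 - pnorm(a)),
               tolerance = 1e-10)
  expect_equal(analytic_mean(tn), 15.632, tolerance = 1e-3)
  expect_equal(analytic_mean(tn), dist_mean(tn, method = "numeric"),
               tolerance = 1e-6)

  wb <- risk_weibull(1.8104, 44.812, shift = -2.8327)
  expect_equal(analytic_mean(wb),
               44.812 * gamma(1 + 1 / 1.8104) - 2.8327, tolerance = 1e-12)
  expect_equal(analytic_mean(wb), 37.0, tolerance = 0.01)
  expect_equal(analytic_mean(wb), mean(dist_sample(wb, 2e5, seed = 7)),
               tolerance = 0.01)

  # divergent-mean log-logistic is unavailable
  expect_true(is.na(analytic_mean(risk_loglogistic(0, 1, 0.9))))
  # truncated empirical keeps only in-bounds values
  emp <- risk_truncate(risk_resample(c(-5, 0, 10, 20)), lower = 0)
  expect_equal(analytic_mean(emp), 10)
})

test_that("LHS places exactly one draw per stratum and respects truncation", {
  n <- 500
  spec <- risk_truncate(risk_normal(11.023, 13.134), lower = 0)
  x <- dist_sample(spec, n, seed = 11, method = "lhs")
  expect_true(all(x >= 0))
  # map draws back to strata through the CDF: each stratum hit exactly once
  u <- dist_cdf(spec, x)
  strata <- ceiling(u * n)
  expect_setequal(strata, seq_len(n))

  x2 <- dist_sample(risk_normal(73.9, 12), 1e4, seed = 3, method = "lhs")
  se <- 12 / sqrt(1e4)
  expect_lt(abs(mean(x2) - 73.9), 3 * se)
})

test_that("LHS sample mean matches analytic mean within 1% for closed-form specs", {
  specs <- list(
    risk_truncate(risk_normal(11.023, 13.134), lower = 0),
    risk_weibull(1.8104, 44.812, shift = -2.8327),
    risk_triang(-18.939, 91.8, 100.45),
    risk_uniform(6, 81),
    risk_resample(thujone_vector())
  )
  for (i in seq_along(specs)) {
    m <- analytic_mean(specs[[i]])
    x <- dist_sample(specs[[i]], 1e5, seed = 20 + i, method = "lhs")
    expect_lt(abs(mean(x) - m) / m, 0.01)
  }
})

test_that("inverse-CDF truncation agrees in distribution with rejection sampling", {
  spec <- risk_truncate(risk_normal(11.023, 13.134), lower = 0)
  x <- dist_sample(spec, 1e4, seed = 31, method = "srs")
  set.seed(32)
  rej <- numeric(0)
  while (length(rej) < 1e4) {
    y <- rnorm(2e4, 11.023, 13.134)
    rej <- c(rej, y[y >= 0])
  }
  rej <- rej[1:1e4]
  expect_gt(suppressWarnings(ks.test(x, rej)$p.value), 0.01)
})

test_that("empirical resampling draws only observed values, zeros included", {
  spec <- risk_resample(thujone_vector())
  x <- dist_sample(spec, 1e4, seed = 5)
  expect_true(all(x %in% c(0, 178, 183)))
  expect_gt(mean(x == 0), 0.9)
})

test_that("sampling is reproducible under a fixed seed and leaves RNG state alone", {
  spec <- risk_uniform(6, 81)
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  x1 <- dist_sample(spec, 100, seed = 4, method = "lhs")
  after <- runif(1)
  x2 <- dist_sample(spec, 100, seed = 4, method = "lhs")
  expect_identical(x1, x2)
  expect_identical(before, after)
  expect_error(dist_sample(spec, 10, method = "bogus"))
})

test_that("specs round-trip through the YAML config dialect", {
  specs <- study_specs()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_risk_config(specs, path)
  back <- read_risk_config(path)
  expect_identical(names(back), names(specs))
  u <- c(0.05, 0.3, 0.5, 0.9, 0.99)
  for (a in names(specs))
    expect_equal(dist_quantile(back[[a]], u), dist_quantile(specs[[a]], u),
                 tolerance = 1e-12, info = a)
  # the two-quantile normal family survives the dialect too
  alt <- risk_truncate(risk_normal_alt(0.25, 3, 0.75, 5), lower = 0)
  cfg <- list(family = "normal_from_quantiles",
              params = c(0.25, 3, 0.75, 5), truncate = list(0, NULL))
  expect_equal(dist_quantile(risk_dist_from_config(cfg), u),
               dist_quantile(alt, u), tolerance = 1e-12)
})
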