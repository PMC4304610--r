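# Shared fixtures: the study's printed concentration risk functions and a
# generator of random valid specs for property-style tests.

study_specs <- function() load_agent_specs()

study_models <- function() {
  specs <- study_specs()
  lapply(names(specs), function(a) exposure_model(a, specs[[a]])) |>
    stats::setNames(names(specs))
}

# thujone: two detects (183, 178 mg/L) among 54 samples, non-detects as zero
thujone_vector <- function() c(rep(0, 52), 183, 178)

random_spec <- function() {
  fam <- sample(c("normal", "weibull_shifted", "triangular", "loglogistic",
                  "uniform", "empirical_resample"), 1)
  spec <- switch(fam,
    normal = risk_normal(runif(1, -5, 20), runif(1, 0.5, 15)),
    weibull_shifted = risk_weibull(runif(1, 0.8, 3), runif(1, 1, 50),
                                   shift = runif(1, -5, 5)),
    triangular = {
      a <- runif(1, -20, 0); b <- a + runif(1, 5, 100)
      risk_triang(a, runif(1, a, b), b)
    },
    loglogistic = risk_loglogistic(runif(1, -2, 2), runif(1, 0.5, 10),
                                   runif(1, 1.1, 4)),
    uniform = {
      a <- runif(1, -10, 10); risk_uniform(a, a + runif(1, 1, 50))
    },
    empirical_resample = risk_resample(c(rep(0, sample(0:10, 1)),
                                         runif(sample(3:20, 1), 0, 100)))
  )
  if (runif(1) < 0.5) spec <- risk_truncate(spec, lower = 0)
  spec
}
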