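# Latin-Hypercube Monte-Carlo propagation of four input risk functions
# through the daily exposure formula
#   exposure = concentration * liquid amount * (vaporized % / 100) / bodyweight
# in mg/kg bw/day.

CONC_UNITS <- c("mg/ml", "g/100g", "mg/L")

#' Convert a concentration to mg/ml
#'
#' `mg/ml` passes through; `g/100g` multiplies by `10 * density` (the liquid
#' density defaults to 1 g/ml); `mg/L` divides by 1000.
#'
#' @param value Numeric concentration value(s).
#' @param unit One of `"mg/ml"`, `"g/100g"`, `"mg/L"`.
#' @param density Liquid density in g/ml used for the mass-fraction
#'   conversion (default 1).
#' @return Concentration in mg/ml.
#' @export
convert_concentration <- function(value, unit, density = 1) {
  unit <- gsub("\\s", "", unit)
  if (!unit %in% CONC_UNITS)
    stop("unsupported concentration unit: ", unit, call. = FALSE)
  switch(unit,
         "mg/ml" = value,
         "g/100g" = value * 10 * density,
         "mg/L" = value / 1000)
}

#' Default exposure-factor distributions
#'
#' The three behavioural/physiological inputs of the exposure model:
#' daily liquid consumption (ml/day) as a normal solved from its 25th
#' percentile 3 ml and 75th percentile 5 ml; vaporized percentage as
#' Uniform(6, 81) %; bodyweight as Normal(73.9, 12) kg.  All are truncated
#' below at 0, since negative values are physically impossible.
#'
#' @return Named list of three [risk_dist] objects (`amount`,
#'   `vaporization`, `bodyweight`).
#' @export
default_exposure_factors <- function() {
  list(
    amount = risk_truncate(risk_normal_alt(0.25, 3, 0.75, 5,
                                           unit = "ml/day"), lower = 0),
    vaporization = risk_uniform(6, 81, unit = "%"),
    bodyweight = risk_truncate(risk_normal(73.9, 12, unit = "kg"), lower = 0)
  )
}

#' Construct an exposure model
#'
#' Bundles the concentration risk function (with its unit) and the three
#' exposure factors for one agent.
#'
#' @param agent Agent name.
#' @param concentration A [risk_dist] for the concentration of the agent in
#'   the liquid.
#' @param unit Concentration unit; defaults to the spec's own unit.
#' @param factors Named list with `amount`, `vaporization`, `bodyweight`
#'   risk distributions (default [default_exposure_factors()]).
#' @param density Liquid density for the `g/100g` conversion.
#' @return Object of class `exposure_model`.
#' @export
exposure_model <- function(agent, concentration, unit = NULL,
                           factors = default_exposure_factors(),
                           density = 1) {
  stopifnot(inherits(concentration, "risk_dist"))
  unit <- unit %||% concentration$unit
  if (is.null(unit) || is.na(unit))
    stop("concentration unit required", call. = FALSE)
  unit <- gsub("\\s", "", unit)
  if (!unit %in% CONC_UNITS)
    stop("unsupported concentration unit: ", unit, call. = FALSE)
  if (!all(c("amount", "vaporization", "bodyweight") %in% names(factors)))
    stop("factors must provide amount, vaporization, bodyweight",
         call. = FALSE)
  structure(list(agent = agent, concentration = concentration, unit = unit,
                 amount = factors$amount,
                 vaporization = factors$vaporization,
                 bodyweight = factors$bodyweight, density = density),
            class = "exposure_model")
}

#' @export
print.exposure_model <- function(x, ...) {
  cat(sprintf("<exposure_model %s (concentration in %s)>\n", x$agent, x$unit))
  invisible(x)
}

#' Simulate the exposure distribution of an agent
#'
#' Draws the four inputs independently (for LHS, the stratum permutation is
#' independent per input), converts the concentration to mg/ml, and computes
#' the per-iteration exposure
#' `concentration * amount * (vaporization/100) / bodyweight` in
#' mg/kg bw/day.  Reproducible for a fixed `(model, n, seed, method)`.
#'
#' @param model An [exposure_model()].
#' @param n Number of Monte-Carlo iterations (default 10000).
#' @param seed Optional integer seed.
#' @param method `"lhs"` (default) or `"srs"`.
#' @return Data frame of class `exposure_sim` with columns `concentration`
#'   (mg/ml), `amount`, `vaporization`, `bodyweight`, `exposure`, and
#'   attributes `agent`, `n`, `seed`, `method`.
#' @export
simulate_exposure <- function(model, n = 10000, seed = NULL,
                              method = c("lhs", "srs")) {
  stopifnot(inherits(model, "exposure_model"), n >= 1)
  method <- match.arg(method)
  draws <- with_seed(seed, {
    one <- function(spec) {
      u <- switch(method, lhs = lhs_uniforms(n), srs = stats::runif(n))
      dist_quantile(spec, u)
    }
    list(c = one(model$concentration), a = one(model$amount),
         v = one(model$vaporization), bw = one(model$bodyweight))
  })
  conc <- convert_concentration(draws$c, model$unit, model$density)
  out <- data.frame(concentration = conc, amount = draws$a,
                    vaporization = draws$v, bodyweight = draws$bw)
  out$exposure <- out$concentration * out$amount *
    (out$vaporization / 100) / out$bodyweight
  attr(out, "agent") <- model$agent
  attr(out, "n") <- n
  attr(out, "seed") <- seed
  attr(out, "method") <- method
  class(out) <- c("exposure_sim", "data.frame")
  out
}

#' Summary statistics of a simulated exposure distribution
#'
#' Arithmetic mean, sample SD, and empirical median / 5th / 95th percentiles
#' (inverse-ECDF, quantile type 1) of the per-iteration exposures.
#'
#' @param sim An `exposure_sim` data frame (or a bare numeric vector of
#'   exposures).
#' @return Named numeric vector `mean`, `sd`, `median`, `p5`, `p95`.
#' @export
summarize_exposure <- function(sim) {
  x <- if (is.data.frame(sim)) sim$exposure else as.numeric(sim)
  if (length(x) < 1) stop("empty simulation result", call. = FALSE)
  q <- stats::quantile(x, c(0.5, 0.05, 0.95), type = 1, names = FALSE)
  c(mean = mean(x), sd = stats::sd(x), median = q[1], p5 = q[2], p95 = q[3])
}

#' Analytic mean exposure by independence factorisation
#'
#' For independent inputs the mean exposure factorises as
#' `E[c] * E[a] * E[v]/100 * E[1/bw]` (concentration converted to mg/ml).
#' Used as the closed-form / numeric-integration oracle for the Monte-Carlo
#' engine.
#'
#' @param model An [exposure_model()].
#' @return Mean exposure in mg/kg bw/day.
#' @export
analytic_mean_exposure <- function(model) {
  stopifnot(inherits(model, "exposure_model"))
  e_c <- convert_concentration(dist_mean(model$concentration), model$unit,
                               model$density)
  e_c * dist_mean(model$amount) * (dist_mean(model$vaporization) / 100) *
    dist_expect(model$bodyweight, function(x) 1 / x)
}
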