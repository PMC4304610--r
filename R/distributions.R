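# Risk-function distribution objects: parametric or empirical distributions
# with optional shift and truncation, in the parameter dialect used by
# spreadsheet risk-analysis tools (RiskNormal, RiskWeibull + RiskShift,
# RiskTriang, RiskLoglogistic, RiskUniform, RiskNormalAlt, RiskResample).

RISK_FAMILIES <- c("normal", "weibull_shifted", "triangular", "loglogistic",
                   "uniform", "empirical_resample")

new_risk_dist <- function(family, params, shift = 0, lower = NULL,
                          upper = NULL, unit = NA_character_) {
  structure(
    list(family = family, params = params, shift = shift,
         lower = lower, upper = upper, unit = unit),
    class = "risk_dist"
  )
}

#' Risk-function distribution constructors
#'
#' Build distribution objects used as model inputs in probabilistic exposure
#' assessment: a parametric family (or an empirical resampling distribution),
#' optionally shifted along the axis and truncated to an interval.  The
#' parameterisation follows the conventions of spreadsheet risk-analysis
#' software: `risk_loglogistic()` is the three-parameter log-logistic with
#' CDF \eqn{F(x) = 1 / (1 + ((x - \gamma)/\beta)^{-\alpha})} for
#' \eqn{x > \gamma} (location \eqn{\gamma}, scale \eqn{\beta}, shape
#' \eqn{\alpha}); `risk_weibull()` takes shape and scale plus an additive
#' shift; `risk_normal_alt()` solves for the unique normal distribution with
#' two given quantiles.
#'
#' @param mean,sd Normal mean and standard deviation (`sd > 0`).
#' @param shape,scale Weibull or log-logistic shape and scale (both `> 0`).
#' @param shift Additive offset applied to the distribution (default 0).
#' @param min,mode,max Triangular parameters, `min <= mode <= max`;
#'   for `risk_uniform()`, `min < max`.
#' @param location Log-logistic location (lower support bound).
#' @param p_lo,q_lo,p_hi,q_hi Two probability/quantile pairs with
#'   `0 < p_lo < p_hi < 1` and `q_lo < q_hi`.
#' @param values Numeric vector resampled with replacement (uniform weights);
#'   non-detects are stored as literal zeros.
#' @param unit Optional unit string carried along (e.g. `"mg/ml"`).
#'
#' @return An object of class `risk_dist`.
#' @seealso [risk_truncate()], [dist_quantile()], [dist_sample()],
#'   [dist_mean()]
#' @examples
#' d <- risk_truncate(risk_normal(11.023, 13.134), lower = 0)
#' dist_mean(d)
#' dist_quantile(risk_uniform(6, 81), 0.5)
#' @name risk_dist
NULL

#' @rdname risk_dist
#' @export
risk_normal <- function(mean, sd, unit = NA_character_) {
  if (!is.finite(mean) || !is.finite(sd) || sd <= 0)
    stop("normal requires finite mean and sd > 0", call. = FALSE)
  new_risk_dist("normal", list(mean = mean, sd = sd), unit = unit)
}

#' @rdname risk_dist
#' @export
risk_weibull <- function(shape, scale, shift = 0, unit = NA_character_) {
  if (shape <= 0 || scale <= 0)
    stop("weibull requires shape > 0 and scale > 0", call. = FALSE)
  new_risk_dist("weibull_shifted", list(shape = shape, scale = scale),
                shift = shift, unit = unit)
}

#' @rdname risk_dist
#' @export
risk_triang <- function(min, mode, max, unit = NA_character_) {
  if (!(min <= mode && mode <= max) || min == max)
    stop("triangular requires min <= mode <= max with min < max",
         call. = FALSE)
  new_risk_dist("triangular", list(min = min, mode = mode, max = max),
                unit = unit)
}

#' @rdname risk_dist
#' @export
risk_loglogistic <- function(location, scale, shape, unit = NA_character_) {
  if (scale <= 0 || shape <= 0)
    stop("loglogistic requires scale > 0 and shape > 0", call. = FALSE)
  new_risk_dist("loglogistic",
                list(location = location, scale = scale, shape = shape),
                unit = unit)
}

#' @rdname risk_dist
#' @export
risk_uniform <- function(min, max, unit = NA_character_) {
  if (!(min < max))
    stop("uniform requires min < max", call. = FALSE)
  new_risk_dist("uniform", list(min = min, max = max), unit = unit)
}

#' @rdname risk_dist
#' @export
risk_resample <- function(values, unit = NA_character_) {
  values <- as.numeric(values)
  if (length(values) < 1 || anyNA(values))
    stop("empirical_resample requires a non-empty numeric vector",
         call. = FALSE)
  new_risk_dist("empirical_resample", list(values = values), unit = unit)
}

#' Solve normal parameters from two quantiles
#'
#' Returns the unique `(mu, sigma)` whose `p_lo` and `p_hi` quantiles equal
#' `q_lo` and `q_hi` — the "alternative parameterisation" normal used for the
#' daily liquid-consumption input (25th percentile 3 ml, 75th percentile
#' 5 ml).
#'
#' @inheritParams risk_dist
#' @return Named numeric vector `c(mean, sd)`.
#' @export
#' @examples
#' normal_from_quantiles(0.25, 3, 0.75, 5)  # mean 4, sd ~1.4826
normal_from_quantiles <- function(p_lo, q_lo, p_hi, q_hi) {
  if (!(p_lo > 0 && p_lo < p_hi && p_hi < 1))
    stop("require 0 < p_lo < p_hi < 1", call. = FALSE)
  if (!(q_lo < q_hi))
    stop("require q_lo < q_hi", call. = FALSE)
  z_lo <- stats::qnorm(p_lo)
  z_hi <- stats::qnorm(p_hi)
  sigma <- (q_hi - q_lo) / (z_hi - z_lo)
  mu <- q_lo - sigma * z_lo
  c(mean = mu, sd = sigma)
}

#' @rdname risk_dist
#' @export
risk_normal_alt <- function(p_lo, q_lo, p_hi, q_hi, unit = NA_character_) {
  p <- normal_from_quantiles(p_lo, q_lo, p_hi, q_hi)
  risk_normal(p[["mean"]], p[["sd"]], unit = unit)
}

#' Truncate or shift a risk distribution
#'
#' `risk_truncate()` restricts a distribution to `[lower, upper]` (either side
#' may be `NULL` for one-sided truncation, as in `RiskTruncate(0;)`).
#' Truncation is implemented exactly by restricting the inverse CDF to
#' `[F(lower), F(upper)]`; no rejection loop.  The shift is applied before
#' truncation, so truncation bounds refer to the shifted variable.
#' `risk_shift()` adds an offset to the distribution's axis.
#'
#' @param spec A `risk_dist`.
#' @param lower,upper Truncation bounds; `NULL` leaves that side open.
#' @param shift Offset to add.
#' @return The modified `risk_dist`.
#' @export
risk_truncate <- function(spec, lower = NULL, upper = NULL) {
  stopifnot(inherits(spec, "risk_dist"))
  if (!is.null(lower) && !is.null(upper) && lower >= upper)
    stop("truncation requires lower < upper", call. = FALSE)
  spec$lower <- lower
  spec$upper <- upper
  plo <- if (is.null(lower)) 0 else p_shifted(spec, lower)
  phi <- if (is.null(upper)) 1 else p_shifted(spec, upper)
  if (phi - plo <= 0)
    stop("truncated support has zero probability mass", call. = FALSE)
  spec
}

#' @rdname risk_truncate
#' @export
risk_shift <- function(spec, shift) {
  stopifnot(inherits(spec, "risk_dist"))
  spec$shift <- spec$shift + shift
  spec
}

#' @export
print.risk_dist <- function(x, ...) {
  pars <- x$params
  if (x$family == "empirical_resample") {
    pars <- sprintf("n = %d values", length(pars$values))
  } else {
    pars <- paste(sprintf("%s = %g", names(pars), unlist(pars)),
                  collapse = ", ")
  }
  cat(sprintf("<risk_dist %s(%s)%s%s%s>\n", x$family, pars,
              if (x$shift != 0) sprintf(" shift %g", x$shift) else "",
              if (!is.null(x$lower) || !is.null(x$upper))
                sprintf(" truncated [%s, %s]",
                        if (is.null(x$lower)) "-Inf" else format(x$lower),
                        if (is.null(x$upper)) "Inf" else format(x$upper))
              else "",
              if (!is.na(x$unit)) paste0(" [", x$unit, "]") else ""))
  invisible(x)
}

# ---- internal base quantile / CDF (shift applied, truncation NOT applied) ----

q_shifted <- function(spec, u) {
  p <- spec$params
  base <- switch(spec$family,
    normal = stats::qnorm(u, p$mean, p$sd),
    weibull_shifted = stats::qweibull(u, p$shape, p$scale),
    triangular = qtriang(u, p$min, p$mode, p$max),
    loglogistic = p$location + p$scale * (u / (1 - u))^(1 / p$shape),
    uniform = stats::qunif(u, p$min, p$max),
    empirical_resample = {
      v <- sort(p$values)
      n <- length(v)
      v[pmin(pmax(ceiling(u * n), 1L), n)]   # type-1 inverse ECDF
    },
    stop("unknown family: ", spec$family, call. = FALSE)
  )
  base + spec$shift
}

p_shifted <- function(spec, x) {
  x <- x - spec$shift
  p <- spec$params
  switch(spec$family,
    normal = stats::pnorm(x, p$mean, p$sd),
    weibull_shifted = stats::pweibull(x, p$shape, p$scale),
    triangular = ptriang(x, p$min, p$mode, p$max),
    loglogistic = {
      out <- numeric(length(x))
      pos <- x > p$location
      out[pos] <- 1 / (1 + ((x[pos] - p$location) / p$scale)^(-p$shape))
      out
    },
    uniform = stats::punif(x, p$min, p$max),
    empirical_resample = stats::ecdf(p$values)(x),
    stop("unknown family: ", spec$family, call. = FALSE)
  )
}

# triangular quantile / CDF / density (not in base stats)
qtriang <- function(u, a, m, b) {
  fm <- (m - a) / (b - a)
  ifelse(u < fm,
         a + sqrt(u * (b - a) * (m - a)),
         b - sqrt((1 - u) * (b - a) * (b - m)))
}

ptriang <- function(x, a, m, b) {
  out <- numeric(length(x))
  out[x >= b] <- 1
  lo <- x > a & x <= m
  hi <- x > m & x < b
  out[lo] <- (x[lo] - a)^2 / ((b - a) * (m - a))
  out[hi] <- 1 - (b - x[hi])^2 / ((b - a) * (b - m))
  out
}

dtriang <- function(x, a, m, b) {
  out <- numeric(length(x))
  lo <- x >= a & x <= m & m > a
  hi <- x > m & x <= b & b > m
  out[lo] <- 2 * (x[lo] - a) / ((b - a) * (m - a))
  out[hi] <- 2 * (b - x[hi]) / ((b - a) * (b - m))
  out
}

# log-logistic density in the 3-parameter dialect
dllog3 <- function(x, location, scale, shape) {
  out <- numeric(length(x))
  pos <- x > location
  z <- (x[pos] - location) / scale
  out[pos] <- (shape / scale) * z^(shape - 1) / (1 + z^shape)^2
  out
}

trunc_range <- function(spec) {
  plo <- if (is.null(spec$lower)) 0 else p_shifted(spec, spec$lower)
  phi <- if (is.null(spec$upper)) 1 else p_shifted(spec, spec$upper)
  c(plo, phi)
}

#' Quantile function of a risk distribution
#'
#' Inverse CDF of the shifted, truncated distribution; the backbone of all
#' sampling in the package.  Monotone non-decreasing in `u`; values respect
#' the truncation bounds exactly.
#'
#' @param spec A `risk_dist`.
#' @param u Probabilities strictly inside (0, 1).
#' @return Numeric vector of quantiles.
#' @export
dist_quantile <- function(spec, u) {
  stopifnot(inherits(spec, "risk_dist"))
  if (any(u <= 0) || any(u >= 1))
    stop("u must be strictly between 0 and 1", call. = FALSE)
  tr <- trunc_range(spec)
  x <- q_shifted(spec, tr[1] + u * (tr[2] - tr[1]))
  if (!is.null(spec$lower)) x <- pmax(x, spec$lower)
  if (!is.null(spec$upper)) x <- pmin(x, spec$upper)
  x
}

#' Cumulative distribution function of a risk distribution
#'
#' @inheritParams dist_quantile
#' @param x Numeric vector of evaluation points.
#' @return CDF values in `[0, 1]`, accounting for shift and truncation.
#' @export
dist_cdf <- function(spec, x) {
  stopifnot(inherits(spec, "risk_dist"))
  tr <- trunc_range(spec)
  p <- (p_shifted(spec, x) - tr[1]) / (tr[2] - tr[1])
  p <- pmin(pmax(p, 0), 1)
  if (!is.null(spec$lower)) p[x < spec$lower] <- 0
  if (!is.null(spec$upper)) p[x >= spec$upper] <- 1
  p
}

# ---- moments ----

#' Mean of a risk distribution
#'
#' `analytic_mean()` returns the closed-form mean of the shifted, truncated
#' distribution where one exists (normal with or without truncation, uniform,
#' untruncated triangular / Weibull / log-logistic with shape > 1, empirical
#' with or without truncation) and `NA` otherwise.  A log-logistic with shape
#' `<= 1` has a divergent mean and returns `NA` as well.  `dist_mean()` falls
#' back to high-accuracy numeric integration of the quantile function over
#' (0, 1) when no closed form exists.  `dist_expect()` computes
#' \eqn{E[g(X)]} the same way (used e.g. for `E[1/bodyweight]`).
#'
#' @param spec A `risk_dist`.
#' @return A single numeric value (`NA` from `analytic_mean()` when no closed
#'   form is available).
#' @export
analytic_mean <- function(spec) {
  stopifnot(inherits(spec, "risk_dist"))
  p <- spec$params
  has_trunc <- !is.null(spec$lower) || !is.null(spec$upper)
  m <- switch(spec$family,
    normal = {
      if (!has_trunc) p$mean
      else {
        # two-sided truncated normal on the shifted variable
        a <- if (is.null(spec$lower)) -Inf else
          (spec$lower - spec$shift - p$mean) / p$sd
        b <- if (is.null(spec$upper)) Inf else
          (spec$upper - spec$shift - p$mean) / p$sd
        z <- stats::pnorm(b) - stats::pnorm(a)
        p$mean + p$sd * (stats::dnorm(a) - stats::dnorm(b)) / z
      }
    },
    uniform = {
      lo <- max(p$min + spec$shift, spec$lower %||% -Inf)
      hi <- min(p$max + spec$shift, spec$upper %||% Inf)
      return((lo + hi) / 2)
    },
    triangular = if (has_trunc) NA_real_ else (p$min + p$mode + p$max) / 3,
    weibull_shifted = if (has_trunc) NA_real_ else
      p$scale * gamma(1 + 1 / p$shape),
    loglogistic = {
      if (has_trunc || p$shape <= 1) NA_real_
      else {
        t <- pi / p$shape
        p$location + p$scale * t / sin(t)
      }
    },
    empirical_resample = {
      v <- p$values + spec$shift
      if (!is.null(spec$lower)) v <- v[v >= spec$lower]
      if (!is.null(spec$upper)) v <- v[v <= spec$upper]
      return(mean(v))
    }
  )
  if (is.na(m)) NA_real_ else m + spec$shift
}

#' @rdname analytic_mean
#' @param method `"auto"` (analytic where available, else numeric),
#'   `"analytic"`, or `"numeric"`.
#' @export
dist_mean <- function(spec, method = c("auto", "analytic", "numeric")) {
  method <- match.arg(method)
  if (method != "numeric") {
    m <- analytic_mean(spec)
    if (!is.na(m) || method == "analytic") return(m)
  }
  # survival-function form E[X] = int_0^Inf (1-F) - int_-Inf^0 F: smooth in
  # x even where the quantile has an (integrable) singularity in u
  pos <- stats::integrate(function(x) 1 - dist_cdf(spec, x), 0, Inf,
                          rel.tol = 1e-10)$value
  neg <- stats::integrate(function(x) dist_cdf(spec, x), -Inf, 0,
                          rel.tol = 1e-10)$value
  pos - neg
}

#' @rdname analytic_mean
#' @param g A vectorised function of the sampled value.
#' @export
dist_expect <- function(spec, g) {
  stopifnot(inherits(spec, "risk_dist"))
  # integrate over probability: quantile endpoints can be unbounded (or sit
  # exactly on a truncation bound where g may blow up), so shave 1e-9 of
  # tail mass off each side
  eps <- 1e-9
  stats::integrate(function(u) g(dist_quantile(spec, u)), eps, 1 - eps,
                   rel.tol = 1e-10, subdivisions = 2000L)$value
}

# ---- sampling ----

# evaluate expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Latin Hypercube uniforms: exactly one draw in each stratum
# [(i-1)/n, i/n), with stratum order randomly permuted.
lhs_uniforms <- function(n) {
  (sample.int(n) - stats::runif(n)) / n
}

#' Draw samples from a risk distribution
#'
#' Simple random sampling (`"srs"`) inverts independent uniforms; Latin
#' Hypercube sampling (`"lhs"`) places exactly one inverted uniform in each of
#' the `n` equal-probability strata, in randomly permuted order.  Truncation
#' is respected exactly for every draw (inverse-CDF restriction, no
#' rejection).
#'
#' @param spec A `risk_dist`.
#' @param n Number of draws (`>= 1`).
#' @param seed Optional integer seed; when given, the caller's RNG state is
#'   left untouched and results are reproducible.
#' @param method `"lhs"` (default) or `"srs"`.
#' @return Numeric vector of length `n`.
#' @export
dist_sample <- function(spec, n, seed = NULL, method = c("lhs", "srs")) {
  stopifnot(inherits(spec, "risk_dist"), n >= 1)
  method <- match.arg(method)
  with_seed(seed, {
    u <- switch(method,
                lhs = lhs_uniforms(n),
                srs = stats::runif(n))
    dist_quantile(spec, u)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- serialization ----

#' Serialise risk distributions to and from configuration lists
#'
#' The configuration form mirrors the textual dialect of the risk functions:
#' a family name, an ordered parameter vector, an optional shift and an
#' optional `truncate: [lower, upper]` pair with `NULL`/`.na` for an open
#' side.  `write_risk_config()` / `read_risk_config()` round-trip a named list
#' of specs through a YAML file.
#'
#' @param spec A `risk_dist`; `config` a list as produced by
#'   `as_risk_config()`.
#' @return `as_risk_config()` a plain list; `risk_dist_from_config()` a
#'   `risk_dist`; `read_risk_config()` a named list of `risk_dist`.
#' @export
as_risk_config <- function(spec) {
  stopifnot(inherits(spec, "risk_dist"))
  cfg <- list(family = spec$family,
              params = if (spec$family == "empirical_resample")
                spec$params$values else unname(unlist(spec$params)))
  if (spec$shift != 0) cfg$shift <- spec$shift
  if (!is.null(spec$lower) || !is.null(spec$upper))
    cfg$truncate <- list(spec$lower, spec$upper)
  if (!is.na(spec$unit)) cfg$unit <- spec$unit
  cfg
}

#' @rdname as_risk_config
#' @export
risk_dist_from_config <- function(config) {
  fam <- config$family
  pr <- as.numeric(unlist(config$params))
  unit <- config$unit %||% NA_character_
  spec <- switch(fam,
    normal = risk_normal(pr[1], pr[2], unit = unit),
    normal_from_quantiles = risk_normal_alt(pr[1], pr[2], pr[3], pr[4],
                                            unit = unit),
    weibull_shifted = risk_weibull(pr[1], pr[2], unit = unit),
    triangular = risk_triang(pr[1], pr[2], pr[3], unit = unit),
    loglogistic = risk_loglogistic(pr[1], pr[2], pr[3], unit = unit),
    uniform = risk_uniform(pr[1], pr[2], unit = unit),
    empirical_resample = risk_resample(pr, unit = unit),
    stop("unknown family in config: ", fam, call. = FALSE)
  )
  if (!is.null(config$shift)) spec <- risk_shift(spec, config$shift)
  tr <- config$truncate
  if (!is.null(tr)) {
    getb <- function(i) {
      b <- tr[[i]]
      if (is.null(b) || length(b) == 0 || is.na(b)) NULL else as.numeric(b)
    }
    spec <- risk_truncate(spec, lower = getb(1),
                          upper = if (length(tr) >= 2) getb(2) else NULL)
  }
  spec
}

#' @rdname as_risk_config
#' @param specs Named list of `risk_dist` objects.
#' @param path File path for the YAML configuration.
#' @export
write_risk_config <- function(specs, path) {
  yaml::write_yaml(lapply(specs, as_risk_config), path)
  invisible(path)
}

#' @rdname as_risk_config
#' @export
read_risk_config <- function(path) {
  lapply(yaml::read_yaml(path), risk_dist_from_config)
}
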