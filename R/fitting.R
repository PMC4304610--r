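# Distribution fitting with Kolmogorov-Smirnov model selection, plus the
# empirical-resampling fallback used when an analyte's incidence is too low
# for parametric fitting.  Non-detects enter the fits as literal zeros.

FIT_CANDIDATES <- c("normal", "weibull_shifted", "triangular",
                    "loglogistic", "uniform")

#' Fit one parametric family to a concentration vector
#'
#' Maximum-likelihood estimation for the supported families; the shifted
#' Weibull and three-parameter log-logistic are fitted over their shift /
#' location parameter as well (bounded above by the sample minimum), the
#' triangular by constrained maximum likelihood over (min, mode, max) with
#' the minimum allowed to go negative.  Non-detect zeros are ordinary data
#' points.  The returned spec carries lower truncation at 0 for use in
#' exposure simulation; the likelihood itself is untruncated.
#'
#' @param data Numeric vector (>= 3 finite non-negative values, zeros
#'   included for non-detects).
#' @param family One of `"normal"`, `"weibull_shifted"`, `"triangular"`,
#'   `"loglogistic"`, `"uniform"`.
#' @param unit Optional unit string attached to the result.
#' @return A [risk_dist] object truncated below at 0.
#' @export
fit_family <- function(data, family, unit = NA_character_) {
  data <- as.numeric(data)
  if (sum(is.finite(data)) < 3 || any(data < 0, na.rm = TRUE))
    stop("need >= 3 finite non-negative values", call. = FALSE)
  data <- data[is.finite(data)]
  if (stats::sd(data) == 0)
    stop("degenerate fit: all data values identical", call. = FALSE)
  family <- match.arg(family, FIT_CANDIDATES)
  spec <- switch(family,
    normal = fit_normal(data),
    uniform = fit_uniform(data),
    weibull_shifted = fit_weibull_shifted(data),
    triangular = fit_triangular(data),
    loglogistic = fit_loglogistic(data)
  )
  spec$unit <- unit
  risk_truncate(spec, lower = 0)
}

fit_normal <- function(x) {
  # MLE: sample mean, sigma with n denominator
  risk_normal(mean(x), sqrt(mean((x - mean(x))^2)))
}

fit_uniform <- function(x) risk_uniform(min(x), max(x))

fit_weibull_shifted <- function(x) {
  nll <- function(par) {
    shift <- min(x) - exp(par[1])
    d <- suppressWarnings(stats::dweibull(x - shift, exp(par[2]),
                                          exp(par[3])))
    if (any(d <= 0) || any(!is.finite(d))) return(1e10)
    -sum(log(d))
  }
  init <- c(log(stats::sd(x) / 2), log(1.2), log(mean(x) - min(x) + stats::sd(x) / 2))
  fit <- stats::optim(init, nll, control = list(maxit = 2000))
  risk_weibull(exp(fit$par[2]), exp(fit$par[3]),
               shift = min(x) - exp(fit$par[1]))
}

fit_triangular <- function(x) {
  rx <- range(x)
  nll <- function(par) {
    a <- rx[1] - exp(par[1])
    b <- rx[2] + exp(par[2])
    m <- a + (b - a) * stats::plogis(par[3])
    d <- dtriang(x, a, m, b)
    if (any(d <= 0) || any(!is.finite(d))) return(1e10)
    -sum(log(d))
  }
  span <- diff(rx)
  init <- c(log(span / 10), log(span / 10),
            stats::qlogis(min(max((mean(x) * 3 - rx[1] - rx[2] - rx[1]) /
                                    (3 * span), 0.05), 0.95)))
  fit <- stats::optim(init, nll, control = list(maxit = 5000))
  a <- rx[1] - exp(fit$par[1])
  b <- rx[2] + exp(fit$par[2])
  risk_triang(a, a + (b - a) * stats::plogis(fit$par[3]), b)
}

fit_loglogistic <- function(x) {
  nll <- function(par) {
    loc <- min(x) - exp(par[1])
    d <- dllog3(x, loc, exp(par[2]), exp(par[3]))
    if (any(d <= 0) || any(!is.finite(d))) return(1e10)
    -sum(log(d))
  }
  init <- c(log(stats::sd(x) / 2 + 1e-6), log(stats::median(x) - min(x) +
                                                stats::sd(x) / 2), log(1.5))
  fit <- stats::optim(init, nll, control = list(maxit = 5000))
  risk_loglogistic(min(x) - exp(fit$par[1]), exp(fit$par[2]),
                   exp(fit$par[3]))
}

#' Kolmogorov-Smirnov statistic between data and a risk distribution
#'
#' Sup-norm distance between the empirical CDF and the spec's CDF,
#' `max_i max(i/n - F(x_(i)), F(x_(i)) - (i-1)/n)`.  Computed with the
#' plugged-in (estimated) parameters and used for ranking candidate fits,
#' not for hypothesis testing.
#'
#' @param data Non-empty numeric vector.
#' @param spec A [risk_dist].
#' @return The KS statistic in `[0, 1]`.
#' @export
ks_statistic <- function(data, spec) {
  x <- sort(as.numeric(data))
  n <- length(x)
  if (n < 1) stop("data must be non-empty", call. = FALSE)
  f <- dist_cdf(spec, x)
  max(seq_len(n) / n - f, f - (seq_len(n) - 1) / n)
}

#' Fit candidate families and select the best by KS statistic
#'
#' When the fraction of positive (detected) values falls below
#' `min_positive_fraction`, parametric fitting is abandoned in favour of
#' empirical resampling of the full data vector (zeros included), mirroring
#' how low-incidence analytes are handled in the source assessment.
#' Otherwise every candidate family is fitted and the family with the
#' smallest KS statistic wins.  The KS ranking is computed against the
#' untruncated fitted distributions (the data contain literal zeros); the
#' selected spec is returned with lower truncation at 0 for simulation.
#'
#' @param data Concentration vector including zeros for non-detects.
#' @param candidates Character vector of families to try.
#' @param min_positive_fraction Incidence threshold below which resampling is
#'   used (default 0.30).
#' @param unit Optional unit string.
#' @return An object of class `fit_result`: list with `spec`, `ks_statistic`,
#'   `family_rank` (data.frame of family and KS, ascending), `strategy`
#'   (`"parametric"` or `"resample"`).
#' @export
select_best_fit <- function(data, candidates = FIT_CANDIDATES,
                            min_positive_fraction = 0.30,
                            unit = NA_character_) {
  data <- as.numeric(data)
  if (length(candidates) < 1) stop("no candidate families", call. = FALSE)
  pos_frac <- mean(data > 0)
  if (pos_frac < min_positive_fraction) {
    spec <- risk_resample(data, unit = unit)
    res <- list(spec = spec,
                ks_statistic = ks_statistic(data, spec),
                family_rank = data.frame(family = "empirical_resample",
                                         ks = ks_statistic(data, spec)),
                strategy = "resample", positive_fraction = pos_frac)
    class(res) <- "fit_result"
    return(res)
  }
  fits <- list()
  ks <- numeric(0)
  errs <- character(0)
  for (fam in candidates) {
    f <- tryCatch(fit_family(data, fam, unit = unit), error = function(e) e)
    if (inherits(f, "error")) {
      errs <- c(errs, sprintf("%s: %s", fam, conditionMessage(f)))
      next
    }
    untrunc <- f
    untrunc$lower <- NULL
    fits[[fam]] <- f
    ks[fam] <- ks_statistic(data, untrunc)
  }
  if (length(fits) == 0)
    stop("all candidate fits failed: ", paste(errs, collapse = "; "),
         call. = FALSE)
  ord <- order(ks)
  best <- names(ks)[ord[1]]
  res <- list(spec = fits[[best]],
              ks_statistic = unname(ks[best]),
              family_rank = data.frame(family = names(ks)[ord],
                                       ks = unname(ks[ord]),
                                       row.names = NULL),
              strategy = "parametric", positive_fraction = pos_frac)
  class(res) <- "fit_result"
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result strategy = %s, positive fraction = %.2f>\n",
              x$strategy, x$positive_fraction))
  print(x$spec)
  if (x$strategy == "parametric") {
    cat("family ranking (KS ascending):\n")
    print(x$family_rank, row.names = FALSE)
  }
  invisible(x)
}

#' Fit every analyte in a long-format concentration table
#'
#' @param table Data frame with columns `sample_id`, `analyte`, `value`,
#'   `unit` (as produced by [generate_sample_table()]).
#' @inheritParams select_best_fit
#' @return Named list of `fit_result`, one per analyte.
#' @export
fit_sample_table <- function(table, candidates = FIT_CANDIDATES,
                             min_positive_fraction = 0.30) {
  stopifnot(all(c("analyte", "value") %in% names(table)))
  out <- lapply(split(table, table$analyte), function(d) {
    select_best_fit(d$value, candidates, min_positive_fraction,
                    unit = if ("unit" %in% names(d)) d$unit[1] else NA)
  })
  out[unique(table$analyte)]
}
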