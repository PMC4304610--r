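# Method-validation statistics for internal-reference quantitative NMR:
# calibration lines, LOD/LOQ by the regression-residual and signal-to-noise
# rules, recovery/precision, and paired cross-method comparison.

#' Fit a calibration line
#'
#' Ordinary least squares of intensity ratio (analyte integral over the
#' internal reference, TSP or TMS) on concentration.  Reports the slope,
#' intercept, residual standard deviation `s_{y/x}` (n - 2 denominator) and
#' Pearson correlation.
#'
#' @param concentration Numeric concentrations (>= 3 points, >= 2 distinct).
#' @param response Numeric intensity ratios, same length.
#' @return Object of class `calibration`: list with `slope`, `intercept`,
#'   `residual_sd`, `r`, `n`, `range`.
#' @export
fit_calibration <- function(concentration, response) {
  x <- as.numeric(concentration)
  y <- as.numeric(response)
  if (length(x) < 3 || length(x) != length(y))
    stop("need >= 3 paired calibration points", call. = FALSE)
  if (length(unique(x)) < 2)
    stop("all concentrations identical", call. = FALSE)
  fit <- stats::lm(y ~ x)
  rsd <- sqrt(sum(stats::residuals(fit)^2) / (length(x) - 2))
  res <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              residual_sd = rsd,
              r = stats::cor(x, y),
              n = length(x),
              range = range(x))
  class(res) <- "calibration"
  res
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf(
    "<calibration n = %d, range %g-%g: slope %.5g, intercept %.5g, s(y/x) %.4g, R %.4f>\n",
    x$n, x$range[1], x$range[2], x$slope, x$intercept, x$residual_sd, x$r))
  invisible(x)
}

#' LOD and LOQ from the calibration residuals
#'
#' Detection and quantification limits from the residual standard deviation
#' of the regression line: `LOD = k_lod * s_{y/x} / slope` and
#' `LOQ = k_loq * s_{y/x} / slope`, with the conventional multipliers 3.3
#' and 10.
#'
#' @param cal A [fit_calibration()] result.
#' @param k_lod,k_loq Multipliers (defaults 3.3 and 10).
#' @return Named vector `c(lod, loq)` in concentration units.
#' @export
lod_loq_from_regression <- function(cal, k_lod = 3.3, k_loq = 10) {
  stopifnot(inherits(cal, "calibration"))
  if (cal$slope <= 0) stop("calibration slope must be > 0", call. = FALSE)
  c(lod = k_lod * cal$residual_sd / cal$slope,
    loq = k_loq * cal$residual_sd / cal$slope)
}

#' LOD and LOQ from a spectral signal-to-noise ratio
#'
#' SNR is the peak amplitude in the signal window over twice the standard
#' deviation of the noise window (the factor 2 mirrors the common
#' peak-to-peak noise convention of spectrometer software); the limits are
#' the concentrations at which SNR would reach 3 and 10:
#' `LOD = 3 * concentration / SNR`, `LOQ = 10 * concentration / SNR`.
#'
#' @param trace Numeric intensity series.
#' @param signal_window,noise_window Disjoint index vectors into `trace`.
#' @param concentration Concentration (mg/L) of the analyte producing the
#'   signal.
#' @param noise_multiplier Factor on the noise SD (default 2).
#' @return List with `snr`, `lod`, `loq`, and `flag` (`TRUE` when the noise
#'   SD is zero, in which case the limits are reported as 0).
#' @export
lod_loq_from_snr <- function(trace, signal_window, noise_window,
                             concentration, noise_multiplier = 2) {
  if (length(signal_window) == 0 || length(noise_window) == 0 ||
      length(intersect(signal_window, noise_window)) > 0)
    stop("signal and noise windows must be non-empty and disjoint",
         call. = FALSE)
  amp <- max(trace[signal_window])
  nsd <- stats::sd(trace[noise_window])
  if (nsd == 0)
    return(list(snr = Inf, lod = 0, loq = 0, flag = TRUE))
  snr <- amp / (noise_multiplier * nsd)
  list(snr = snr, lod = 3 * concentration / snr,
       loq = 10 * concentration / snr, flag = FALSE)
}

#' Recovery and precision of a quantitation method
#'
#' Standard-addition recovery per spiking level,
#' `100 * (measured - baseline) / spiked`, with their arithmetic mean; and
#' the coefficient of variation `100 * sd / mean` of repeated measurements.
#'
#' @param measured Measured totals after spiking.
#' @param spiked Spiked amounts (same units, all `> 0`).
#' @param baseline Un-spiked sample content (default 0).
#' @param replicates Optional vector of repeat measurements for the CV.
#' @return List with `recovery` (per level, %), `mean_recovery` (%), and
#'   `cv` (%, `NA` when no replicates given).
#' @export
recovery_and_precision <- function(measured, spiked, baseline = 0,
                                   replicates = NULL) {
  if (any(spiked <= 0)) stop("spiked amounts must be > 0", call. = FALSE)
  if (length(measured) != length(spiked))
    stop("measured and spiked lengths differ", call. = FALSE)
  rec <- 100 * (measured - baseline) / spiked
  cv <- if (is.null(replicates)) NA_real_
        else 100 * stats::sd(replicates) / mean(replicates)
  list(recovery = rec, mean_recovery = mean(rec), cv = cv)
}

#' Paired comparison of two quantitation methods
#'
#' Pearson correlation and ordinary least squares of method B on method A
#' with 95% confidence intervals on slope and intercept.  The methods are
#' judged free of proportional / systematic differences when the slope CI
#' contains 1 and the intercept CI contains 0.  Non-detects (`NA` values)
#' are either set to zero (`"as_zero"`, the default — both methods agreeing
#' on "not detected" is informative agreement) or dropped pairwise
#' (`"drop"`).
#'
#' @param a,b Numeric vectors; `NA` marks a non-detect.
#' @param nd_policy `"as_zero"` or `"drop"`.
#' @return Object of class `method_comparison`: list with `r`, `slope`,
#'   `intercept`, `slope_ci`, `intercept_ci`, `slope_ci_contains_1`,
#'   `intercept_ci_contains_0`, `n`, `nd_policy`.
#' @export
method_comparison <- function(a, b, nd_policy = c("as_zero", "drop")) {
  nd_policy <- match.arg(nd_policy)
  if (length(a) != length(b)) stop("a and b lengths differ", call. = FALSE)
  if (nd_policy == "as_zero") {
    a[is.na(a)] <- 0
    b[is.na(b)] <- 0
  } else {
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]
    b <- b[keep]
  }
  if (length(a) < 3)
    stop("fewer than 3 usable pairs after non-detect policy", call. = FALSE)
  fit <- stats::lm(b ~ a)
  ci <- stats::confint(fit, level = 0.95)
  res <- list(r = stats::cor(a, b),
              slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              slope_ci = unname(ci[2, ]),
              intercept_ci = unname(ci[1, ]),
              slope_ci_contains_1 = ci[2, 1] <= 1 && 1 <= ci[2, 2],
              intercept_ci_contains_0 = ci[1, 1] <= 0 && 0 <= ci[1, 2],
              n = length(a), nd_policy = nd_policy)
  class(res) <- "method_comparison"
  res
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison n = %d (%s): r = %.4f>\n", x$n,
              x$nd_policy, x$r))
  cat(sprintf("  slope %.3f [%.3f, %.3f]%s\n", x$slope, x$slope_ci[1],
              x$slope_ci[2],
              if (x$slope_ci_contains_1) " (contains 1)" else ""))
  cat(sprintf("  intercept %.3f [%.3f, %.3f]%s\n", x$intercept,
              x$intercept_ci[1], x$intercept_ci[2],
              if (x$intercept_ci_contains_0) " (contains 0)" else ""))
  invisible(x)
}

#' Read a paired method-comparison table
#'
#' Parses a CSV with columns `sample`, and two method columns where the
#' literal `n.d.` marks a non-detect (stored as `NA`).
#'
#' @param path CSV path; defaults to the packaged nicotine NMR-vs-HPLC
#'   table.
#' @return Data frame with numeric method columns (`NA` = non-detect).
#' @export
read_method_comparison <- function(path = NULL) {
  path <- path %||% system.file("extdata", "nmr_hplc_comparison.csv",
                                package = "vaporisk", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in setdiff(names(d), "sample")) {
    v <- trimws(as.character(d[[col]]))
    v[v %in% c("n.d.", "nd", "ND", "n.d")] <- NA
    d[[col]] <- as.numeric(v)
  }
  d
}
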