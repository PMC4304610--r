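# Margin-of-exposure statistics against a packaged registry of
# toxicological reference points (LOAEL / NOAEL / NOEL / BMDL10).

#' Load the toxicological threshold registry
#'
#' Reads the packaged registry of reference points used for MOE calculation:
#' per agent, the primary threshold in mg/kg bw/day (the most sensitive
#' endpoint: LOAEL, NOAEL, NOEL or BMDL10), whether the endpoint derives
#' from human or animal data, and where available a secondary health-based
#' guidance value (ADI or MRL).  MOE always uses the primary threshold; the
#' ADI/MRL is retained for comparison statements only.
#'
#' @param path Optional path to a YAML registry; defaults to the packaged
#'   one.
#' @return Data frame with columns `agent`, `value`, `endpoint_type`,
#'   `endpoint_source`, `secondary_value`, `secondary_type`, `endpoint`,
#'   `reference`.
#' @export
tox_thresholds <- function(path = NULL) {
  path <- path %||% system.file("extdata", "tox_thresholds.yaml",
                                package = "vaporisk", mustWork = TRUE)
  reg <- yaml::read_yaml(path)
  rows <- lapply(names(reg), function(a) {
    r <- reg[[a]]
    if (is.null(r$value) || r$value <= 0)
      stop("registry entry for ", a, " needs value > 0", call. = FALSE)
    if (!is.null(r$secondary_value) && r$secondary_value >= r$value)
      stop("secondary (ADI/MRL) must be below primary threshold for ", a,
           call. = FALSE)
    data.frame(agent = a, value = r$value,
               endpoint_type = r$endpoint_type,
               endpoint_source = r$endpoint_source,
               secondary_value = r$secondary_value %||% NA_real_,
               secondary_type = r$secondary_type %||% NA_character_,
               endpoint = r$endpoint %||% NA_character_,
               reference = r$reference %||% NA_character_)
  })
  do.call(rbind, rows)
}

#' Margin-of-exposure distribution for one agent
#'
#' MOE is the ratio of the toxicological reference point to the estimated
#' intake.  Computed per iteration as `threshold / exposure`, with zero
#' exposures mapping to `+Inf` (a non-use iteration has unbounded margin);
#' infinities are kept so the percentiles reflect the full distribution
#' (they sort last).  Also reports the MOE at the mean exposure,
#' `threshold / mean(exposure)`, since risk statements are made in both
#' framings.
#'
#' @param exposures Numeric vector of non-negative exposures
#'   (mg/kg bw/day), or an `exposure_sim` data frame.
#' @param threshold One row of [tox_thresholds()] (or a list with `value`
#'   and `endpoint_source`).
#' @return Object of class `moe_result`: list with `moe` (per-iteration
#'   vector), `summary` (named percentiles p1, p5, p25, p50, p75, p95, p99,
#'   min, max), `moe_at_mean_exposure`, `risk_band`, `endpoint_source`,
#'   `all_zero` flag.
#' @export
moe_distribution <- function(exposures, threshold) {
  x <- if (is.data.frame(exposures)) exposures$exposure
       else as.numeric(exposures)
  if (any(x < 0)) stop("exposures must be non-negative", call. = FALSE)
  value <- threshold$value
  if (is.null(value) || value <= 0)
    stop("threshold value must be positive", call. = FALSE)
  moe <- ifelse(x == 0, Inf, value / x)
  probs <- c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99)
  s <- stats::quantile(moe, probs, type = 1, names = FALSE)
  summary <- c(p1 = s[1], p5 = s[2], p25 = s[3], p50 = s[4], p75 = s[5],
               p95 = s[6], p99 = s[7], min = min(moe), max = max(moe))
  all_zero <- all(x == 0)
  at_mean <- if (all_zero) NA_real_ else value / mean(x)
  res <- list(moe = moe, summary = summary,
              moe_at_mean_exposure = at_mean,
              endpoint_source = threshold$endpoint_source,
              risk_band = categorize_moe(summary[["p50"]],
                                         threshold$endpoint_source),
              all_zero = all_zero,
              agent = attr(exposures, "agent") %||% threshold$agent)
  class(res) <- "moe_result"
  res
}

#' Classify a margin of exposure into a risk band
#'
#' For endpoints derived from animal experiments the conventional 100-fold
#' uncertainty factor applies: median MOE below 10 is "high risk", below 100
#' "risk", otherwise "acceptable".  For human endpoints (nicotine's LOAEL)
#' the interspecies factor drops out: below 1 "high risk", below 10 "risk",
#' otherwise "acceptable".
#'
#' @param median_moe Median of the MOE distribution (may be `Inf`).
#' @param endpoint_source `"human"` or `"animal"`.
#' @return One of `"high risk"`, `"risk"`, `"acceptable"`.
#' @export
categorize_moe <- function(median_moe, endpoint_source = c("animal",
                                                           "human")) {
  endpoint_source <- match.arg(endpoint_source)
  cuts <- if (endpoint_source == "human") c(1, 10) else c(10, 100)
  if (median_moe < cuts[1]) "high risk"
  else if (median_moe < cuts[2]) "risk"
  else "acceptable"
}

#' @export
print.moe_result <- function(x, ...) {
  cat(sprintf("<moe_result %s (%s endpoint): band \"%s\">\n",
              x$agent %||% "?", x$endpoint_source, x$risk_band))
  cat(sprintf("  MOE at mean exposure: %s\n",
              if (is.na(x$moe_at_mean_exposure)) "undefined (all-zero exposure)"
              else format(signif(x$moe_at_mean_exposure, 4))))
  print(signif(x$summary, 4))
  invisible(x)
}

#' Box-plot percentile table of MOE distributions for several agents
#'
#' One row per agent with the percentiles that define the MOE box plot
#' (box p25/p75, whiskers p5/p95, marks p1/p99, min/max), the median, the
#' MOE at mean exposure and the risk band.  Infinite values serialize as
#' the literal string `"inf"` when written to CSV.
#'
#' @param moe_results Named list of `moe_result` objects.
#' @return Data frame, one row per agent.
#' @export
moe_summary_table <- function(moe_results) {
  rows <- lapply(names(moe_results), function(a) {
    m <- moe_results[[a]]
    cbind(data.frame(agent = a), as.data.frame(t(m$summary)),
          data.frame(moe_at_mean_exposure = m$moe_at_mean_exposure,
                     endpoint_source = m$endpoint_source,
                     risk_band = m$risk_band))
  })
  do.call(rbind, rows)
}
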