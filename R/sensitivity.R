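# Sensitivity analysis: standardized multiple-regression coefficients of the
# simulated exposure on the simulated inputs, ranking input influence.

#' Standardized-regression sensitivity analysis
#'
#' Ordinary least squares of the z-scored output on the z-scored inputs; the
#' coefficients are the standardized slopes, whose absolute values rank the
#' influence of each input on the exposure.  The exposure formula is
#' multiplicative, so the linear fit is an approximation; its `R^2` is
#' reported.  A rank-based variant (regression on ranks, akin to Spearman)
#' is available via `rank_based = TRUE`.
#'
#' @param inputs Numeric matrix or data frame of simulated input draws (one
#'   column per input), or an `exposure_sim` data frame (the four input
#'   columns are used and `output` defaults to its `exposure` column).
#' @param output Numeric vector of simulated outputs.
#' @param rank_based Use ranks of inputs and output instead of raw values.
#' @return Object of class `sensitivity_report`: data frame `coefficients`
#'   with columns `input`, `coefficient`, `rank`, plus `r_squared` and a
#'   `zero_variance` flag vector.
#' @export
standardized_regression <- function(inputs, output = NULL,
                                    rank_based = FALSE) {
  if (inherits(inputs, "exposure_sim")) {
    output <- output %||% inputs$exposure
    inputs <- inputs[c("concentration", "amount", "vaporization",
                       "bodyweight")]
  }
  X <- as.matrix(inputs)
  y <- as.numeric(output)
  n <- length(y)
  if (n <= 10) stop("need more than 10 iterations", call. = FALSE)
  if (nrow(X) != n) stop("inputs and output lengths differ", call. = FALSE)
  if (rank_based) {
    X <- apply(X, 2, rank)
    y <- rank(y)
  }
  sds <- apply(X, 2, stats::sd)
  zero_var <- sds == 0 | !is.finite(sds)
  if (stats::sd(y) == 0)
    stop("output has zero variance", call. = FALSE)
  Z <- scale(X[, !zero_var, drop = FALSE])
  zy <- as.numeric(scale(y))
  fit <- stats::lm.fit(cbind(1, Z), zy)
  beta <- numeric(ncol(X))
  beta[!zero_var] <- fit$coefficients[-1]
  r2 <- 1 - sum(fit$residuals^2) / sum(zy^2)
  cf <- data.frame(input = colnames(X) %||% paste0("x", seq_len(ncol(X))),
                   coefficient = beta, row.names = NULL)
  cf$rank <- rank(-abs(cf$coefficient), ties.method = "first")
  res <- list(coefficients = cf[order(cf$rank), ], r_squared = r2,
              zero_variance = zero_var, rank_based = rank_based)
  class(res) <- "sensitivity_report"
  res
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report%s, R^2 = %.3f>\n",
              if (x$rank_based) " (rank-based)" else "", x$r_squared))
  print(x$coefficients, row.names = FALSE)
  if (any(x$zero_variance))
    cat("zero-variance inputs flagged:",
        paste(names(which(x$zero_variance)), collapse = ", "), "\n")
  invisible(x)
}
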