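# Synthetic study-shaped data: a 54-sample concentration/label table,
# calibration fixtures and spectrum traces, so every pipeline stage is
# testable without access to the (unpublished) raw measurements.

#' Default per-analyte concentration generators
#'
#' One generator per assessed agent: the detection incidence and the risk
#' function drawn from when the analyte is present.  For the four
#' parametric agents these are the fitted concentration risk functions of
#' the study conditions; for the three low-incidence agents the positive
#' values are resampled from reconstructed data vectors.  The thujone
#' vector (two positives, 183 and 178 mg/L, among 54 samples) is fully
#' determined by the reported results; the 1,3-propanediol and ethyl
#' vanillin positive vectors are *synthetic* — constructed once so that the
#' full 54-sample vector matches the reported incidence, mean and SD and
#' stays inside the reported concentration range (their raw values are
#' unpublished).
#'
#' @return Named list; each element has `incidence`, `spec` (a
#'   [risk_dist]), and `unit`.
#' @export
default_agent_generators <- function() {
  list(
    nicotine = list(
      incidence = 0.65,
      spec = risk_truncate(risk_normal(11.023, 13.134, unit = "mg/ml"),
                           lower = 0),
      unit = "mg/ml"),
    glycerol = list(
      incidence = 0.94,
      spec = risk_truncate(
        risk_weibull(1.8104, 44.812, shift = -2.8327, unit = "g/100g"),
        lower = 0),
      unit = "g/100g"),
    propylene_glycol = list(
      incidence = 0.94,
      spec = risk_truncate(
        risk_triang(-18.939, 91.8, 100.45, unit = "g/100g"), lower = 0),
      unit = "g/100g"),
    ethylene_glycol = list(
      incidence = 0.91,
      spec = risk_truncate(
        risk_loglogistic(-0.40204, 5.15, 1.8215, unit = "g/100g"),
        lower = 0),
      unit = "g/100g"),
    propanediol_13 = list(
      incidence = 7 / 54,
      spec = risk_resample(synthetic_positive_values("propanediol_13"),
                           unit = "g/100g"),
      unit = "g/100g"),
    thujone = list(
      incidence = 2 / 54,
      spec = risk_resample(c(183, 178), unit = "mg/L"),
      unit = "mg/L"),
    ethyl_vanillin = list(
      incidence = 14 / 54,
      spec = risk_resample(synthetic_positive_values("ethyl_vanillin"),
                           unit = "mg/L"),
      unit = "mg/L")
  )
}

#' Synthetic positive-value vectors for unpublished analytes
#'
#' Deterministic reconstructions of the positive (detected) concentrations
#' for the two resampled analytes whose raw data are unpublished, chosen so
#' the full 54-sample vector (zeros included) matches the reported mean,
#' SD, incidence and range.  `"thujone"` returns the exactly known pair.
#'
#' @param analyte One of `"thujone"`, `"propanediol_13"`,
#'   `"ethyl_vanillin"`.
#' @return Numeric vector of positive concentrations.
#' @export
synthetic_positive_values <- function(analyte = c("thujone",
                                                  "propanediol_13",
                                                  "ethyl_vanillin")) {
  switch(match.arg(analyte),
    thujone = c(183, 178),
    propanediol_13 = c(3.3, 3.3, 3.5, 3.8, 4.2, 5.6, 8.7),
    ethyl_vanillin = c(7.7, 16.8, 29.3, 43.6, 59.1, 75.6, 93, 111.1,
                       129.9, 149.3, 169.2, 189.7, 210.6, 335))
}

#' Generate a study-shaped concentration table
#'
#' For each sample and analyte, the concentration is 0 (non-detect) with
#' probability `1 - incidence`, otherwise a draw from the analyte's risk
#' function (truncated at 0).  Long format, one row per sample-analyte
#' cell.
#'
#' @param n_samples Number of samples (default 54).
#' @param generators Named list as from [default_agent_generators()].
#' @param seed Optional integer seed.
#' @param exact_counts When `TRUE`, each analyte gets exactly
#'   `round(incidence * n_samples)` detects in random positions instead of
#'   independent Bernoulli detection — conditioning the table on the
#'   observed study composition (useful when a test depends on the
#'   incidence side of a decision boundary).
#' @return Data frame with columns `sample_id`, `analyte`, `value`, `unit`,
#'   `detect`.
#' @export
generate_sample_table <- function(n_samples = 54,
                                  generators = default_agent_generators(),
                                  seed = NULL, exact_counts = FALSE) {
  stopifnot(n_samples >= 1)
  for (g in generators)
    if (g$incidence < 0 || g$incidence > 1)
      stop("incidence must be in [0, 1]", call. = FALSE)
  with_seed(seed, {
    rows <- lapply(names(generators), function(a) {
      g <- generators[[a]]
      present <- if (exact_counts) {
        k <- round(g$incidence * n_samples)
        seq_len(n_samples) %in% sample.int(n_samples, k)
      } else stats::runif(n_samples) < g$incidence
      value <- numeric(n_samples)
      if (any(present))
        value[present] <- dist_sample(g$spec, sum(present), method = "srs")
      data.frame(sample_id = sprintf("S%02d", seq_len(n_samples)),
                 analyte = a, value = value, unit = g$unit,
                 detect = present)
    })
    do.call(rbind, rows)
  })
}

#' Attach declared-label metadata with controlled discordance
#'
#' Assigns a declared nicotine label to each sample so that a configurable
#' fraction of the declared "nicotine-free" samples actually contain
#' nicotine, and a configurable count of declared nicotine-containing
#' samples contain none — emulating the labelling discordances observed in
#' market surveys.  Labels of concordant positives are the measured value
#' jittered and rounded to typical label steps.
#'
#' @param table A [generate_sample_table()] result containing nicotine
#'   rows.
#' @param false_free_rate Target fraction of declared-free samples that in
#'   fact contain nicotine (default 5/23).
#' @param false_containing_count Number of nicotine-free samples declared
#'   as containing nicotine (default 1).
#' @param seed Optional integer seed.
#' @return The table with a `declared_label` column on nicotine rows
#'   (`"nicotine-free"` or a declared mg/ml value) and `NA` elsewhere.
#' @export
generate_label_metadata <- function(table, false_free_rate = 5 / 23,
                                    false_containing_count = 1,
                                    seed = NULL) {
  stopifnot(false_free_rate >= 0, false_free_rate < 1,
            false_containing_count >= 0)
  nic <- table$analyte == "nicotine"
  if (!any(nic)) stop("table has no nicotine rows", call. = FALSE)
  with_seed(seed, {
    value <- table$value[nic]
    pos <- which(value > 0)
    zer <- which(value == 0)
    n_false_cont <- min(false_containing_count, length(zer))
    false_cont <- if (n_false_cont > 0) sample(zer, n_false_cont) else integer(0)
    true_free_declared <- setdiff(zer, false_cont)
    # declared-free set = all remaining true zeros plus enough positives to
    # reach the target discordance fraction among declared-free samples
    n_false_free <- round(length(true_free_declared) *
                            false_free_rate / (1 - false_free_rate))
    n_false_free <- min(n_false_free, length(pos))
    false_free <- if (n_false_free > 0) sample(pos, n_false_free) else integer(0)
    label <- character(length(value))
    label[c(true_free_declared, false_free)] <- "nicotine-free"
    honest_pos <- setdiff(pos, false_free)
    label[honest_pos] <- format(round(value[honest_pos] *
                                        stats::runif(length(honest_pos),
                                                     0.9, 1.1), 1))
    label[false_cont] <- format(round(stats::runif(n_false_cont, 6, 24), 0))
    table$declared_label <- NA_character_
    table$declared_label[nic] <- label
    table
  })
}

#' Audit label concordance of a generated table
#'
#' @param table A table with nicotine `declared_label` metadata.
#' @return List with counts: `declared_free`, `false_free` (declared free
#'   but nicotine present), `false_containing` (declared containing but
#'   nicotine absent).
#' @export
audit_labels <- function(table) {
  nic <- table[table$analyte == "nicotine", ]
  free <- nic$declared_label == "nicotine-free"
  list(declared_free = sum(free),
       false_free = sum(free & nic$value > 0),
       false_containing = sum(!free & nic$value == 0))
}

#' Generate a noisy calibration fixture
#'
#' Intensity ratios on a straight line plus Gaussian noise,
#' `response = slope * c + intercept + N(0, noise_sd)`, per replicate.
#'
#' @param slope,intercept Line parameters.
#' @param noise_sd Gaussian noise SD on the response.
#' @param levels Concentration levels (non-empty).
#' @param replicates Replicates per level (default 1).
#' @param seed Optional integer seed.
#' @return Data frame with columns `concentration`, `response`.
#' @export
generate_calibration_fixture <- function(slope, intercept, noise_sd,
                                         levels, replicates = 1,
                                         seed = NULL) {
  if (length(levels) == 0) stop("levels must be non-empty", call. = FALSE)
  conc <- rep(levels, each = replicates)
  with_seed(seed, {
    data.frame(concentration = conc,
               response = slope * conc + intercept +
                 stats::rnorm(length(conc), 0, noise_sd))
  })
}

#' Generate a synthetic spectrum trace
#'
#' A Lorentzian peak (amplitude at the centre equal to `amplitude`) plus
#' white Gaussian noise on a uniform abscissa over `[0, 1]`.
#'
#' @param peak_center Centre position in `[0, 1]`.
#' @param amplitude Peak amplitude.
#' @param width Half-width at half-maximum (`> 0`).
#' @param noise_sd Gaussian noise SD.
#' @param n_points Number of points (`>= 16`, default 4096).
#' @param seed Optional integer seed.
#' @return List with `x`, `intensity`, and index vectors `signal_window`
#'   (within one width of the centre) and `noise_window` (the far half of
#'   the trace).
#' @export
generate_spectrum_trace <- function(peak_center, amplitude, width,
                                    noise_sd, n_points = 4096,
                                    seed = NULL) {
  stopifnot(width > 0, n_points >= 16)
  x <- seq(0, 1, length.out = n_points)
  signal <- amplitude * width^2 / ((x - peak_center)^2 + width^2)
  intensity <- with_seed(seed,
                         signal + stats::rnorm(n_points, 0, noise_sd))
  sw <- which(abs(x - peak_center) <= width)
  dist_from_peak <- abs(x - peak_center)
  nw <- which(dist_from_peak >= stats::quantile(dist_from_peak, 0.5) &
                dist_from_peak > 10 * width)
  if (length(nw) == 0) nw <- setdiff(seq_len(n_points), sw)
  list(x = x, intensity = intensity, signal_window = sw, noise_window = nw)
}
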