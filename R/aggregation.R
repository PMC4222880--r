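# Whole-domain annual aggregation indicators: presence area, concentration
# curves, the space selectivity index, and per-year summary statistics.

#' Presence area
#'
#' Percentage of sampled points at which the species was found,
#' independently of its abundance.
#'
#' @param values Biomass per EDSU for one year and species.
#' @return Percentage in [0, 100].
#' @export
presence_area <- function(values) {
  if (length(values) == 0) stopf("presence_area needs at least one value")
  100 * mean(values > 0)
}

#' Concentration curve of a biomass distribution
#'
#' The curve gives the maximum proportion of total biomass that can be
#' found in a given proportion of the samples: samples are sorted by
#' decreasing biomass and cumulated. A homogeneously distributed
#' population yields the first diagonal; the further the curve lies above
#' the diagonal, the more concentrated the population.
#'
#' @param values Biomass per EDSU (total must be positive).
#' @return A data frame of class `concentration_curve` with columns
#'   `sample_fraction` and `biomass_fraction`, starting at (0, 0) and
#'   ending at (1, 1).
#' @export
concentration_curve <- function(values) {
  if (length(values) == 0) stopf("empty input")
  if (any(values < 0)) stopf("negative biomass")
  total <- sum(values)
  if (total <= 0) stopf("total biomass must be positive")
  n <- length(values)
  sorted <- sort(values, decreasing = TRUE)
  out <- data.frame(sample_fraction = (0:n) / n,
                    biomass_fraction = c(0, cumsum(sorted) / total))
  class(out) <- c("concentration_curve", "data.frame")
  out
}

#' Space selectivity index
#'
#' Twice the area between the concentration curve and the first diagonal
#' (a Gini-type concentration coefficient). Zero for a homogeneously
#' distributed population; approaches 1 as biomass concentrates in fewer
#' samples (maximum `1 - 1/n` when a single sample holds everything).
#' The area is computed by exact trapezoidal integration of the curve
#' vertices, which makes the index identical to the Gini coefficient of
#' the value distribution.
#'
#' @inheritParams concentration_curve
#' @return Index in `[0, 1 - 1/n]`.
#' @export
space_selectivity_index <- function(values) {
  cc <- concentration_curve(values)
  y <- cc$biomass_fraction
  n <- length(values)
  area <- sum((y[-1] + y[-length(y)]) / 2) / n
  2 * (area - 0.5)
}

#' @export
plot.concentration_curve <- function(x, ...) {
  graphics::plot(x$sample_fraction, x$biomass_fraction, type = "l",
                 xlab = "proportion of samples",
                 ylab = "proportion of biomass", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Annual aggregation summaries per species and year
#'
#' @param dataset A `survey_dataset` (see [read_survey()]).
#' @param c Offset of the log transform (tons), see [log_transform()].
#' @return One row per year and species with presence area (%), total
#'   biomass (tons), `log_biomass = ln(total)`, mean density over occupied
#'   EDSUs, the coefficient of variation of per-EDSU biomass (sample SD /
#'   mean) and the space selectivity index.
#' @export
annual_summaries <- function(dataset, c = 0.05) {
  rec <- dataset$records
  out <- do.call(rbind, lapply(dataset$species, function(sp) {
    do.call(rbind, lapply(dataset$years, function(yr) {
      v <- rec[[sp]][rec$year == yr]
      total <- sum(v)
      data.frame(year = yr, species = sp,
                 presence_area_pct = presence_area(v),
                 total_biomass = total,
                 log_biomass = if (total > 0) log(total) else NA,
                 mean_density_presence = if (any(v > 0)) mean(v[v > 0]) else NA,
                 cv_biomass = if (mean(v) > 0) stats::sd(v) / mean(v) else NA,
                 selectivity = if (total > 0) space_selectivity_index(v)
                               else NA)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Regress an annual indicator on total log-biomass
#'
#' Ordinary least-squares simple regression of a per-year indicator
#' (presence area, mean density, selectivity, ...) on the annual total
#' log-biomass index. A standard linear-model wrapper, reported for
#' convenience; not bespoke method content.
#'
#' @param metric Per-year indicator values.
#' @param logbiomass Per-year log-biomass values (same length, >= 3).
#' @return A list with `slope`, `intercept`, `r2_adj`, `p_value` (two-sided
#'   slope test) and the underlying `lm` fit.
#' @export
metric_vs_logbiomass <- function(metric, logbiomass) {
  if (length(metric) != length(logbiomass)) stopf("length mismatch")
  if (length(metric) < 3) stopf("need at least 3 years")
  fit <- stats::lm(metric ~ logbiomass)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) < 2 || is.na(sm$coefficients[2, 4])) 1
       else sm$coefficients[2, 4]
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2_adj = sm$adj.r.squared, p_value = p, fit = fit)
}
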