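# Trend fitting and the three-criterion ecological trend assessment.

.pick_parameter <- function(yearly, parameter) {
  if (is.null(parameter)) {
    parameter <- unique(yearly$parameter)
    if (length(parameter) != 1)
      stop("yearly summaries contain several parameters; supply `parameter`")
  }
  yearly[yearly$parameter == parameter, , drop = FALSE]
}

#' Fit an OLS trend to yearly median anomalies
#'
#' Ordinary least squares of the yearly median anomaly on calendar year —
#' one unweighted point per retained year. The slope estimates the average
#' change of the parameter per year in its original units; the two-sided
#' p-value tests the no-trend null (slope = 0) against the t distribution
#' with n - 2 degrees of freedom.
#'
#' @param yearly output of [yearly_summaries()] (one parameter, or supply
#'   \code{parameter}).
#' @param parameter canonical parameter name to select when \code{yearly}
#'   holds several.
#' @param weight_by_sites logical; when \code{TRUE}, weight each year by its
#'   contributing site count (non-default sensitivity option).
#' @return object of class \code{trend_fit}: parameter, slope, intercept,
#'   p_value, r_squared, n_years, df, plus the years and fitted values.
#' @export
fit_trend <- function(yearly, parameter = NULL, weight_by_sites = FALSE) {
  ys <- .pick_parameter(yearly, parameter)
  if (nrow(ys) < 3) stop("need at least 3 retained years to fit a trend")
  if (stats::var(ys$year) == 0) stop("all retained years are identical")
  w <- if (weight_by_sites) ys$n_sites else NULL
  fit <- stats::lm(median_anomaly ~ year, data = ys, weights = w)
  sm <- summary(fit)
  co <- sm$coefficients
  p_val <- unname(co["year", "Pr(>|t|)"])
  # a constant series has zero slope and zero residual variance; treat the
  # 0/0 t statistic as no evidence against the no-trend null
  if (is.nan(p_val)) p_val <- 1
  structure(list(
    parameter = ys$parameter[1],
    slope = unname(co["year", "Estimate"]),
    intercept = unname(co["(Intercept)", "Estimate"]),
    slope_se = unname(co["year", "Std. Error"]),
    p_value = p_val,
    r_squared = sm$r.squared,
    n_years = nrow(ys),
    df = fit$df.residual,
    years = ys$year,
    observed = ys$median_anomaly,
    fitted = unname(stats::fitted(fit)),
    weighted = weight_by_sites
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, digits = 4, ...) {
  cat("Trend fit (", x$parameter, "): slope = ",
      signif(x$slope, digits), " per yr, p = ", signif(x$p_value, digits),
      ", r^2 = ", signif(x$r_squared, digits),
      ", n = ", x$n_years, " years\n", sep = "")
  invisible(x)
}

#' Ecologically derived slope thresholds
#'
#' Builds the per-parameter magnitude thresholds (units per year) used by
#' the third trend criterion, each computed from its published basis as a
#' change spread over a century:
#' \describe{
#'   \item{temperature}{2 degC policy warming limit / 100 yr = 0.02.}
#'   \item{chla}{3.5 ug/L oligotrophic-mesotrophic limit / 100 yr = 0.035.}
#'   \item{tn}{350 ug/L oligotrophic-mesotrophic limit / 100 yr = 3.5.}
#'   \item{tp}{10 ug/L oligotrophic-mesotrophic limit / 100 yr = 0.1.}
#'   \item{np_ratio}{difference between the median molar TN:TP of
#'     non-nitrogen-limited (61) and nitrogen-limited (35) lakes / 100 yr
#'     = 0.26.}
#' }
#' A slope of this magnitude sustained for a century would move any
#' oligotrophic lake to mesotrophic (nutrients, chlorophyll), exceed the
#' policy warming target (temperature), or shift a lake across the
#' nitrogen-limitation divide (TN:TP).
#'
#' @return data frame of class \code{threshold_registry} with columns
#'   parameter, threshold, provenance.
#' @export
threshold_derivations <- function() {
  out <- data.frame(
    parameter = c("temperature", "chla", "tn", "tp", "np_ratio"),
    threshold = c(2 / 100, 3.5 / 100, 350 / 100, 10 / 100, (61 - 35) / 100),
    provenance = c(
      "2 degC century policy warming limit / 100 yr",
      "3.5 ug/L oligo-mesotrophic chlorophyll limit / 100 yr",
      "350 ug/L oligo-mesotrophic TN limit / 100 yr",
      "10 ug/L oligo-mesotrophic TP limit / 100 yr",
      "(61 - 35) molar TN:TP nitrogen-limitation gap / 100 yr"
    ),
    stringsAsFactors = FALSE
  )
  class(out) <- c("threshold_registry", "data.frame")
  out
}

.lookup_threshold <- function(registry, parameter) {
  i <- match(parameter, registry$parameter)
  if (is.na(i)) stop("no slope threshold registered for parameter ", parameter)
  registry$threshold[i]
}

#' Criterion 1: statistical support
#'
#' True when the two-sided p-value of the slope is at or below \code{alpha}.
#' The default 0.10 treats moderate evidence as support, consistent with
#' reading p-values as graded evidence rather than a hard significance cut.
#'
#' @param fit a \code{trend_fit}.
#' @param alpha support level.
#' @return single logical.
#' @export
criterion_statistical <- function(fit, alpha = 0.10) {
  fit$p_value <= alpha
}

#' Criterion 2: temporal pattern of high and low years
#'
#' Splits the retained years at the midpoint of the observed year range and
#' asks whether years above the baseline cluster in one half and years below
#' in the other. Among years with nonzero median anomaly, an increasing
#' pattern requires the share of positive-anomaly years falling in the late
#' half, and the share of negative-anomaly years falling in the early half,
#' to each reach \code{pattern_fraction} (when that sign is present at all);
#' a decreasing pattern is the mirror image. Years whose median anomaly is
#' exactly zero are neither high nor low and are excluded from the counts.
#'
#' @param yearly yearly summaries for one parameter (>= 4 retained years).
#' @param pattern_fraction required share, default 2/3.
#' @param parameter optional selector as in [fit_trend()].
#' @return single logical with attribute \code{"direction"} (increasing,
#'   decreasing, or none).
#' @export
criterion_pattern <- function(yearly, pattern_fraction = 2 / 3,
                              parameter = NULL) {
  ys <- .pick_parameter(yearly, parameter)
  if (nrow(ys) < 4) stop("need at least 4 retained years to assess a pattern")
  mid <- (min(ys$year) + max(ys$year)) / 2
  late <- ys$year > mid
  pos <- ys$median_anomaly > 0
  neg <- ys$median_anomaly < 0
  share <- function(sel, half) if (any(sel)) mean(half[sel]) else NA_real_
  up <- c(share(pos, late), share(neg, !late))
  down <- c(share(pos, !late), share(neg, late))
  holds <- function(sh) any(!is.na(sh)) && all(sh[!is.na(sh)] >= pattern_fraction)
  direction <- if (holds(up)) "increasing" else if (holds(down)) "decreasing" else "none"
  structure(direction != "none", direction = direction)
}

#' Criterion 3: ecologically meaningful slope magnitude
#'
#' True when the absolute slope reaches the parameter's registered
#' threshold; a slope exactly at the threshold attains it.
#'
#' @param fit a \code{trend_fit}.
#' @param registry a [threshold_derivations()] registry.
#' @return single logical.
#' @export
criterion_magnitude <- function(fit, registry = threshold_derivations()) {
  abs(fit$slope) >= .lookup_threshold(registry, fit$parameter)
}

.classify_count <- function(n_met) {
  if (n_met >= 2) "trend" else if (n_met == 1) "weak_trend" else "no_trend"
}

.trend_direction <- function(classification, slope) {
  if (classification == "no_trend" || slope == 0) "none"
  else if (slope > 0) "increasing" else "decreasing"
}

.trend_symbol <- function(classification, direction) {
  switch(classification,
         trend = if (direction == "decreasing") "--" else "++",
         weak_trend = if (direction == "decreasing") "-" else "+",
         no_trend = "0")
}

#' Three-criterion trend assessment
#'
#' Fits the OLS trend and evaluates the three lines of evidence —
#' statistical support ([criterion_statistical()]), temporal pattern
#' ([criterion_pattern()]), and ecological slope magnitude
#' ([criterion_magnitude()]). A trend exists when at least two criteria are
#' met, a weak trend when exactly one is, and no trend when none are.
#' Direction follows the sign of the slope (none for no-trend).
#'
#' @param yearly yearly summaries for one parameter.
#' @param registry slope threshold registry.
#' @param alpha statistical support level.
#' @param pattern_fraction pattern share requirement.
#' @param parameter optional selector.
#' @param weight_by_sites passed to [fit_trend()].
#' @return object of class \code{trend_assessment}: the fit, the three
#'   criterion flags, n_criteria_met, classification (trend / weak_trend /
#'   no_trend), direction, and the display symbol (++, +, 0, -, --).
#' @export
assess_trend <- function(yearly, registry = threshold_derivations(),
                         alpha = 0.10, pattern_fraction = 2 / 3,
                         parameter = NULL, weight_by_sites = FALSE) {
  ys <- .pick_parameter(yearly, parameter)
  fit <- fit_trend(ys, weight_by_sites = weight_by_sites)
  pat <- criterion_pattern(ys, pattern_fraction)
  crit <- c(statistical = criterion_statistical(fit, alpha),
            pattern = as.logical(pat),
            magnitude = criterion_magnitude(fit, registry))
  n_met <- sum(crit)
  classification <- .classify_count(n_met)
  direction <- .trend_direction(classification, fit$slope)
  structure(list(
    parameter = fit$parameter,
    fit = fit,
    crit_statistical = unname(crit["statistical"]),
    crit_pattern = unname(crit["pattern"]),
    pattern_direction = attr(pat, "direction"),
    crit_magnitude = unname(crit["magnitude"]),
    n_criteria_met = n_met,
    classification = classification,
    direction = direction,
    symbol = .trend_symbol(classification, direction),
    alpha = alpha,
    pattern_fraction = pattern_fraction
  ), class = "trend_assessment")
}

#' @export
print.trend_assessment <- function(x, digits = 4, ...) {
  cat(x$parameter, ": ", x$symbol, " (", x$classification,
      if (x$direction != "none") paste0(", ", x$direction), ")\n", sep = "")
  cat("  slope = ", signif(x$fit$slope, digits), "/yr, p = ",
      signif(x$fit$p_value, digits), ", r^2 = ",
      signif(x$fit$r_squared, digits), ", n = ", x$fit$n_years, "\n", sep = "")
  cat("  criteria met: statistical=", x$crit_statistical,
      ", pattern=", x$crit_pattern, ", magnitude=", x$crit_magnitude,
      " (", x$n_criteria_met, "/3)\n", sep = "")
  invisible(x)
}

#' Classify a trend from already-known criterion inputs
#'
#' Applies the rubric directly to a (slope, p-value, pattern) triple — for
#' example slopes and p-values reported by an earlier analysis — without
#' refitting. Useful for auditing published classifications.
#'
#' @param parameter canonical parameter name (for the magnitude threshold).
#' @param slope slope in canonical units per year.
#' @param p_value two-sided p-value of the slope.
#' @param pattern logical: does the high/low-year pattern criterion hold?
#' @param registry,alpha as in [assess_trend()].
#' @return list with the criterion flags, n_criteria_met, classification,
#'   direction and symbol.
#' @export
trend_rubric <- function(parameter, slope, p_value, pattern,
                         registry = threshold_derivations(), alpha = 0.10) {
  crit <- c(statistical = p_value <= alpha,
            pattern = isTRUE(pattern),
            magnitude = abs(slope) >= .lookup_threshold(registry, parameter))
  n_met <- sum(crit)
  classification <- .classify_count(n_met)
  direction <- .trend_direction(classification, slope)
  list(parameter = parameter,
       crit_statistical = unname(crit["statistical"]),
       crit_pattern = unname(crit["pattern"]),
       crit_magnitude = unname(crit["magnitude"]),
       n_criteria_met = n_met,
       classification = classification,
       direction = direction,
       symbol = .trend_symbol(classification, direction))
}

#' Leave-one-year-out trend refit
#'
#' Refits the trend with one calendar year removed, reporting the full and
#' reduced fits side by side — a check on whether a single influential year
#' (for example one with very few sites) drives the apparent trend.
#'
#' @param yearly yearly summaries for one parameter.
#' @param year calendar year to drop.
#' @param parameter optional selector.
#' @return list with elements \code{full} and \code{reduced} (both
#'   \code{trend_fit}) and \code{year}.
#' @export
leave_year_out <- function(yearly, year, parameter = NULL) {
  ys <- .pick_parameter(yearly, parameter)
  full <- fit_trend(ys)
  if (!year %in% ys$year) {
    warning("year ", year, " is not among the retained years; nothing removed")
    reduced <- full
  } else {
    rest <- ys[ys$year != year, , drop = FALSE]
    if (nrow(rest) < 3)
      stop("removing year ", year, " leaves fewer than 3 years")
    reduced <- fit_trend(rest)
  }
  list(full = full, reduced = reduced, year = year)
}

#' Detection-limit sensitivity of the trend classifications
#'
#' Runs the full anomaly pipeline twice — once on all data as reported and
#' once excluding measurements flagged below the detection limit — and
#' reports whether each parameter's classification agrees between the runs.
#'
#' @param samples canonical sample data frame with below_detection flags.
#' @param config an [eligibility_config()].
#' @param ... further arguments passed to [wq_trend()].
#' @return list with \code{all} and \code{above_detection} (both
#'   \code{wq_trend} objects) and \code{agreement}, a data frame of
#'   per-parameter classifications and an \code{agree} flag.
#' @export
detection_limit_sensitivity <- function(samples, config = eligibility_config(),
                                        ...) {
  fit_all <- wq_trend(samples, config = config, ...)
  fit_excl <- wq_trend(samples[!samples$below_detection, , drop = FALSE],
                       config = config, ...)
  pa <- vapply(fit_all$assessments, function(a) a$classification, "")
  pe <- vapply(fit_excl$assessments, function(a) a$classification, "")
  params <- union(names(pa), names(pe))
  agreement <- data.frame(
    parameter = params,
    all_data = unname(pa[params]),
    above_detection = unname(pe[params]),
    stringsAsFactors = FALSE
  )
  agreement$agree <- !is.na(agreement$all_data) &
    !is.na(agreement$above_detection) &
    agreement$all_data == agreement$above_detection
  list(all = fit_all, above_detection = fit_excl, agreement = agreement)
}

#' Mean first day of the year exceeding a temperature threshold
#'
#' For each site-year with temperature data in the requested range, finds
#' the earliest sample date whose temperature exceeds the threshold, then
#' averages the day-of-year across site-years. A later-period decrease in
#' this mean is one signature of a lengthening growing season (cyanobacteria
#' favour water above about 25 degC).
#'
#' @param samples canonical sample data frame (temperature rows are used).
#' @param threshold exceedance threshold in degrees C.
#' @param years optional integer vector of calendar years to include.
#' @return list: mean_day (mean day-of-year of first exceedance),
#'   n_site_years (with an exceedance), n_no_exceedance (site-years in range
#'   with temperature data but none above the threshold).
#' @export
first_exceedance_day <- function(samples, threshold = 25, years = NULL) {
  tsamp <- samples[samples$parameter == "temperature", , drop = FALSE]
  yr <- .sample_year(tsamp)
  if (!is.null(years)) {
    keep <- yr %in% years
    tsamp <- tsamp[keep, , drop = FALSE]
    yr <- yr[keep]
  }
  if (nrow(tsamp) == 0) stop("no temperature samples in the requested years")
  key <- paste(tsamp$site_id, yr, sep = "\r")
  doy <- as.integer(format(tsamp$sample_date, "%j"))
  exceed <- tsamp$value > threshold
  first_day <- tapply(ifelse(exceed, doy, NA_integer_), key,
                      function(d) if (all(is.na(d))) NA_real_ else
                        min(d, na.rm = TRUE))
  hit <- !is.na(first_day)
  if (!any(hit))
    stop("no site-year exceeds ", threshold, " degC in the requested years")
  list(mean_day = mean(first_day[hit]),
       n_site_years = sum(hit),
       n_no_exceedance = sum(!hit))
}
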