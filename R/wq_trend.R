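# The headline fitter: eligibility -> anomalies -> trend assessment.

#' Fit site-specific median anomaly trends
#'
#' The package's main entry point. Starting from canonical long-format
#' monitoring samples it (1) derives molar TN:TP ratio samples when both
#' nutrients are present, (2) applies the site eligibility screen, (3) runs
#' the anomaly pipeline — per-site annual medians, per-site long-term
#' reference medians, site-specific anomalies, yearly cross-site median
#' anomalies — and (4) fits an OLS trend per parameter and classifies it
#' with the three-criterion rubric (statistical support, high/low-year
#' pattern, ecological slope magnitude).
#'
#' Working in anomalies rather than raw values shifts every site onto a
#' common zero baseline, so the yearly aggregate is robust to staggered
#' site enrollment and unequal sampling effort; working in medians keeps it
#' robust to the right-skew and outliers (e.g. algal blooms) typical of
#' nutrient and chlorophyll data.
#'
#' @param samples canonical sample data frame (see [read_samples()]).
#' @param config an [eligibility_config()].
#' @param compute_np derive \code{np_ratio} samples from paired tn/tp
#'   measurements when not already present.
#' @param np_pairing pairing rule passed to [compute_np_ratio()].
#' @param coverage_mode passed to [apply_eligibility()].
#' @param reference_basis,reference_years passed to
#'   [site_reference_medians()].
#' @param min_sites_per_year minimum sites per retained year; defaults to
#'   the value in \code{config}.
#' @param registry slope threshold registry ([threshold_derivations()]).
#' @param alpha statistical support level for criterion 1.
#' @param pattern_fraction share requirement for criterion 2.
#' @param weight_by_sites weight yearly points by site count (non-default).
#' @return object of class \code{wq_trend} with components
#'   \code{eligibility} (report), \code{site_year_medians},
#'   \code{site_references}, \code{anomalies}, \code{yearly},
#'   \code{assessments} (named list of \code{trend_assessment}),
#'   \code{skipped} (parameters with too few retained years) and the
#'   options used. Supports \code{print}, \code{summary}, \code{coef},
#'   \code{fitted}, \code{predict}, \code{residuals} and \code{plot}.
#'
#' @examples
#' sim <- simulate_program(sim_config(n_sites = 12, seed = 42))
#' fit <- wq_trend(sim$samples)
#' fit
#' coef(fit)
#' summary(fit)
#' @export
wq_trend <- function(samples, config = eligibility_config(),
                     compute_np = TRUE, np_pairing = "event",
                     coverage_mode = "strict",
                     reference_basis = "annual", reference_years = NULL,
                     min_sites_per_year = config$min_sites_per_year,
                     registry = threshold_derivations(),
                     alpha = 0.10, pattern_fraction = 2 / 3,
                     weight_by_sites = FALSE) {
  cl <- match.call()
  np_report <- NULL
  if (compute_np && !"np_ratio" %in% samples$parameter &&
      all(c("tn", "tp") %in% samples$parameter)) {
    np <- compute_np_ratio(samples, pairing = np_pairing)
    np_report <- attr(np, "report")
    samples <- rbind(samples, np)
  }
  elig <- apply_eligibility(samples, config, coverage_mode = coverage_mode)
  if (nrow(elig$samples) == 0)
    stop("no samples survive the eligibility screen")
  sym <- annual_site_medians(elig$samples)
  refs <- site_reference_medians(sym, basis = reference_basis,
                                 samples = elig$samples,
                                 reference_years = reference_years)
  anoms <- compute_anomalies(sym, refs)
  yearly <- yearly_summaries(anoms, min_sites_per_year = min_sites_per_year)

  params <- unique(yearly$parameter)
  assessments <- list()
  skipped <- character(0)
  for (p in params) {
    ys <- yearly[yearly$parameter == p, , drop = FALSE]
    if (nrow(ys) < 4) {
      skipped <- c(skipped, p)
      next
    }
    assessments[[p]] <- assess_trend(ys, registry = registry, alpha = alpha,
                                     pattern_fraction = pattern_fraction,
                                     weight_by_sites = weight_by_sites)
  }
  structure(list(
    call = cl,
    config = config,
    options = list(coverage_mode = coverage_mode,
                   reference_basis = reference_basis,
                   reference_years = reference_years,
                   min_sites_per_year = min_sites_per_year,
                   alpha = alpha, pattern_fraction = pattern_fraction,
                   weight_by_sites = weight_by_sites),
    np_report = np_report,
    eligibility = elig$report,
    site_year_medians = sym,
    site_references = refs,
    anomalies = anoms,
    yearly = yearly,
    registry = registry,
    assessments = assessments,
    skipped = skipped
  ), class = "wq_trend")
}

#' @export
print.wq_trend <- function(x, ...) {
  cat("Site-specific median anomaly trend analysis\n")
  cat("  window:", x$config$start_year, "-", x$config$end_year,
      "| eligible sites (union):", x$eligibility$union_site_count, "\n")
  for (p in names(x$assessments)) {
    a <- x$assessments[[p]]
    cat(sprintf("  %-12s %-3s slope %s/yr (p = %s, n = %d yr)\n",
                p, a$symbol, signif(a$fit$slope, 3),
                signif(a$fit$p_value, 3), a$fit$n_years))
  }
  if (length(x$skipped) > 0)
    cat("  not assessed (fewer than 4 retained years):",
        paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.wq_trend <- function(object, ...) {
  rows <- lapply(object$assessments, function(a) data.frame(
    parameter = a$parameter,
    slope = a$fit$slope,
    slope_se = a$fit$slope_se,
    p_value = a$fit$p_value,
    r_squared = a$fit$r_squared,
    n_years = a$fit$n_years,
    crit_statistical = a$crit_statistical,
    crit_pattern = a$crit_pattern,
    crit_magnitude = a$crit_magnitude,
    n_criteria_met = a$n_criteria_met,
    classification = a$classification,
    direction = a$direction,
    symbol = a$symbol,
    stringsAsFactors = FALSE
  ))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(table = out, options = object$options,
                 skipped = object$skipped),
            class = "summary.wq_trend")
}

#' @export
print.summary.wq_trend <- function(x, digits = 3, ...) {
  cat("Trend assessment (alpha =", x$options$alpha,
      ", pattern fraction =", round(x$options$pattern_fraction, 3), ")\n")
  tab <- x$table
  tab$slope <- signif(tab$slope, digits)
  tab$slope_se <- signif(tab$slope_se, digits)
  tab$p_value <- signif(tab$p_value, digits)
  tab$r_squared <- signif(tab$r_squared, digits)
  print(tab[, c("parameter", "symbol", "slope", "p_value", "r_squared",
                "n_years", "crit_statistical", "crit_pattern",
                "crit_magnitude", "classification")],
        row.names = FALSE)
  if (length(x$skipped) > 0)
    cat("not assessed:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.wq_trend <- function(object, ...) {
  vapply(object$assessments, function(a) a$fit$slope, numeric(1))
}

#' @export
fitted.wq_trend <- function(object, ...) {
  rows <- lapply(object$assessments, function(a)
    data.frame(parameter = a$parameter, year = a$fit$years,
               fitted = a$fit$fitted, stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predict yearly median anomalies from the fitted trends
#'
#' @param object a \code{wq_trend} fit.
#' @param newdata optional data frame with columns \code{parameter} and
#'   \code{year}; defaults to the retained years of every assessed
#'   parameter.
#' @param ... unused.
#' @return data frame with parameter, year and the predicted yearly median
#'   anomaly on the fitted line.
#' @export
predict.wq_trend <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    out <- fitted(object)
    names(out)[names(out) == "fitted"] <- "prediction"
    return(out)
  }
  stopifnot(all(c("parameter", "year") %in% names(newdata)))
  pred <- vapply(seq_len(nrow(newdata)), function(i) {
    a <- object$assessments[[newdata$parameter[i]]]
    if (is.null(a)) return(NA_real_)
    a$fit$intercept + a$fit$slope * newdata$year[i]
  }, numeric(1))
  data.frame(parameter = newdata$parameter, year = newdata$year,
             prediction = pred, stringsAsFactors = FALSE)
}

#' @export
residuals.wq_trend <- function(object, ...) {
  rows <- lapply(object$assessments, function(a)
    data.frame(parameter = a$parameter, year = a$fit$years,
               residual = a$fit$observed - a$fit$fitted,
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot yearly median anomalies with the fitted trend
#'
#' One panel per requested parameter, in the style of monitoring-program
#' trend figures: points are yearly median anomalies coloured by sign (red
#' above the site baselines, blue below, grey exactly equal), thick bars
#' span the 25th-75th percentiles, thin whiskers the full range, an
#' asterisk marks years with only the minimum number of sites, and the
#' fitted OLS line is overlaid.
#'
#' @param x a \code{wq_trend} fit.
#' @param parameter parameter(s) to plot; default all assessed.
#' @param ... further arguments passed to \code{\link[graphics]{plot}}.
#' @export
plot.wq_trend <- function(x, parameter = NULL, ...) {
  params <- if (is.null(parameter)) names(x$assessments) else parameter
  for (p in params) {
    a <- x$assessments[[p]]
    if (is.null(a)) {
      warning("parameter ", p, " was not assessed; skipping figure")
      next
    }
    ys <- x$yearly[x$yearly$parameter == p, , drop = FALSE]
    col <- ifelse(ys$median_anomaly > 0, "firebrick",
                  ifelse(ys$median_anomaly < 0, "steelblue", "grey50"))
    graphics::plot(ys$year, ys$median_anomaly, type = "n",
                   ylim = range(ys$min, ys$max),
                   xlab = "Year", ylab = paste(p, "anomaly"),
                   main = paste0(p, " (", a$symbol, ")"), ...)
    graphics::abline(h = 0, col = "grey80", lty = 2)
    graphics::segments(ys$year, ys$min, ys$year, ys$max,
                       col = "grey60", lwd = 1)
    graphics::segments(ys$year, ys$p25, ys$year, ys$p75, col = col, lwd = 3)
    graphics::points(ys$year, ys$median_anomaly, pch = 19, col = col)
    if (any(ys$low_n_flag))
      graphics::text(ys$year[ys$low_n_flag], ys$max[ys$low_n_flag], "*",
                     pos = 3, cex = 1.4)
    graphics::abline(a$fit$intercept, a$fit$slope, lwd = 2)
  }
  invisible(x)
}
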