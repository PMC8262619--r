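# Site/record selection criteria for the anomaly analysis.

#' Eligibility configuration
#'
#' Bundles the record- and site-selection rules applied before the anomaly
#' pipeline: analysis window, growing-season months, seasonal coverage bins,
#' split-window presence ranges, maximum sample depth, minimum years of data
#' per site and parameter, and the minimum sites per year consumed by
#' [yearly_summaries()].
#'
#' Two presets encode the shipped study designs. \code{"uriww"}: 1993-2016,
#' May-October, bins May-Jun / Jul-Aug / Sep-Oct, split windows 1993-2004 and
#' 2005-2016, depth <= 2 m, >= 10 years per parameter, >= 3 sites per year.
#' \code{"lagos_ne"}: as above but 1993-2013 with split windows 1993-2002 and
#' 2003-2013, and no depth filter (depth is not reported; records are surface
#' or epilimnion samples).
#'
#' @param preset \code{"uriww"} (default) or \code{"lagos_ne"}.
#' @param start_year,end_year inclusive calendar-year analysis window.
#' @param months inclusive set of month numbers retained.
#' @param seasonal_bins list of month-number vectors; a qualifying year needs
#'   at least one sampling event in every bin.
#' @param split_windows list of two year ranges (length-2 vectors); an
#'   eligible site needs at least one sampling event in each.
#' @param max_depth_m maximum sample depth in metres, or \code{NA} to disable
#'   the depth filter. Samples with missing depth always pass.
#' @param min_years_per_parameter minimum qualifying years per site and
#'   parameter.
#' @param min_sites_per_year minimum sites for a year to enter the trend.
#' @return object of class \code{eligibility_config}.
#' @export
eligibility_config <- function(preset = c("uriww", "lagos_ne"),
                               start_year = NULL, end_year = NULL,
                               months = 5:10,
                               seasonal_bins = list(5:6, 7:8, 9:10),
                               split_windows = NULL,
                               max_depth_m = NULL,
                               min_years_per_parameter = 10,
                               min_sites_per_year = 3) {
  preset <- match.arg(preset)
  if (preset == "uriww") {
    if (is.null(start_year)) start_year <- 1993
    if (is.null(end_year)) end_year <- 2016
    if (is.null(split_windows)) split_windows <- list(c(1993, 2004), c(2005, 2016))
    if (is.null(max_depth_m)) max_depth_m <- 2
  } else {
    if (is.null(start_year)) start_year <- 1993
    if (is.null(end_year)) end_year <- 2013
    if (is.null(split_windows)) split_windows <- list(c(1993, 2002), c(2003, 2013))
    if (is.null(max_depth_m)) max_depth_m <- NA_real_
  }
  stopifnot(start_year <= end_year,
            min_years_per_parameter >= 1, min_sites_per_year >= 1,
            length(split_windows) == 2)
  for (w in split_windows)
    if (w[1] < start_year || w[2] > end_year)
      stop("split windows must lie within [start_year, end_year]")
  structure(list(preset = preset, start_year = start_year, end_year = end_year,
                 months = months, seasonal_bins = seasonal_bins,
                 split_windows = split_windows, max_depth_m = max_depth_m,
                 min_years_per_parameter = min_years_per_parameter,
                 min_sites_per_year = min_sites_per_year),
            class = "eligibility_config")
}

#' @export
print.eligibility_config <- function(x, ...) {
  cat("Eligibility configuration (preset: ", x$preset, ")\n", sep = "")
  cat("  years: ", x$start_year, "-", x$end_year,
      "; months: ", paste(range(x$months), collapse = "-"), "\n", sep = "")
  cat("  seasonal bins:",
      paste(vapply(x$seasonal_bins, function(b)
        paste(range(b), collapse = "-"), ""), collapse = ", "), "\n")
  cat("  split windows:",
      paste(vapply(x$split_windows, function(w)
        paste(w, collapse = "-"), ""), collapse = " and "), "\n")
  cat("  max depth:", if (is.na(x$max_depth_m)) "none" else
    paste0(x$max_depth_m, " m"),
    "| min years/parameter:", x$min_years_per_parameter,
    "| min sites/year:", x$min_sites_per_year, "\n")
  invisible(x)
}

.sample_year <- function(samples) as.integer(format(samples$sample_date, "%Y"))
.sample_month <- function(samples) as.integer(format(samples$sample_date, "%m"))

#' Window and depth filter
#'
#' Retains samples inside the analysis window: year within
#' \code{[start_year, end_year]}, month in the growing-season month set, and
#' (when depth is present and the filter enabled) depth no greater than
#' \code{max_depth_m}.
#'
#' @param samples canonical sample data frame.
#' @param config an [eligibility_config()].
#' @return filtered sample data frame.
#' @export
filter_window <- function(samples, config) {
  yr <- .sample_year(samples)
  mo <- .sample_month(samples)
  keep <- yr >= config$start_year & yr <= config$end_year & mo %in% config$months
  if (!is.na(config$max_depth_m))
    keep <- keep & (is.na(samples$depth_m) | samples$depth_m <= config$max_depth_m)
  samples[keep, , drop = FALSE]
}

#' Seasonal coverage of one site-year
#'
#' A site-year qualifies for a parameter when every seasonal bin (default
#' May-Jun, Jul-Aug, Sep-Oct) contains at least one sampling event — a
#' unique date with a retained measurement of that parameter.
#'
#' @param samples window-filtered samples of one site, parameter and year.
#' @param bins list of month-number vectors.
#' @return single logical.
#' @export
seasonal_coverage <- function(samples, bins = list(5:6, 7:8, 9:10)) {
  mo <- .sample_month(samples)
  all(vapply(bins, function(b) any(mo %in% b), logical(1)))
}

#' Split-window presence of one site
#'
#' True when each of the two year ranges contains at least one sampling
#' event for the site and parameter, guarding against sites present in only
#' one half of the record.
#'
#' @param samples window-filtered samples of one site and parameter.
#' @param split_windows list of two length-2 year ranges.
#' @return single logical.
#' @export
split_window_presence <- function(samples, split_windows) {
  yr <- .sample_year(samples)
  all(vapply(split_windows,
             function(w) any(yr >= w[1] & yr <= w[2]), logical(1)))
}

#' Apply the site selection criteria
#'
#' Runs the full eligibility screen per parameter: window/depth filtering,
#' per-year seasonal coverage, split-window presence, and the minimum-years
#' rule. A site is eligible for a parameter when it has sampling events in
#' both split windows and at least \code{min_years_per_parameter} qualifying
#' years; only samples from eligible site-parameter combinations (and, in
#' \code{"strict"} mode, from qualifying years) are retained.
#'
#' \code{coverage_mode} resolves how seasonal coverage counts years:
#' \describe{
#'   \item{\code{"strict"} (default)}{a year counts toward the minimum (and
#'     its samples are retained) only when all seasonal bins are covered for
#'     that site, parameter and year.}
#'   \item{\code{"site"}}{a site needs at least one fully covered year; all
#'     its years with any sample then count and are retained.}
#' }
#'
#' @param samples canonical sample data frame.
#' @param config an [eligibility_config()].
#' @param coverage_mode \code{"strict"} or \code{"site"}.
#' @return list with \code{samples} (retained, eligibility-filtered samples)
#'   and \code{report} (class \code{eligibility_report}): per-parameter
#'   eligible site counts, union and all-parameter intersection counts,
#'   per-site eligible year lists, and rejection tallies by criterion.
#' @export
apply_eligibility <- function(samples, config,
                              coverage_mode = c("strict", "site")) {
  coverage_mode <- match.arg(coverage_mode)
  win <- filter_window(samples, config)
  params <- intersect(WQ_PARAMETERS, unique(win$parameter))
  keep_idx <- integer(0)
  eligible_sites <- stats::setNames(vector("list", length(params)), params)
  eligible_years <- list()
  rejections <- c(split_window = 0L, no_covered_year = 0L, min_years = 0L)

  for (p in params) {
    sp <- win[win$parameter == p, , drop = FALSE]
    idx_by_site <- split(seq_len(nrow(sp)), sp$site_id)
    ok_sites <- character(0)
    for (site in names(idx_by_site)) {
      rows <- sp[idx_by_site[[site]], , drop = FALSE]
      if (!split_window_presence(rows, config$split_windows)) {
        rejections["split_window"] <- rejections["split_window"] + 1L
        next
      }
      yr <- .sample_year(rows)
      covered <- vapply(split(seq_len(nrow(rows)), yr), function(i)
        seasonal_coverage(rows[i, , drop = FALSE], config$seasonal_bins),
        logical(1))
      if (!any(covered)) {
        rejections["no_covered_year"] <- rejections["no_covered_year"] + 1L
        next
      }
      qualifying <- if (coverage_mode == "strict")
        as.integer(names(covered)[covered]) else sort(unique(yr))
      if (length(qualifying) < config$min_years_per_parameter) {
        rejections["min_years"] <- rejections["min_years"] + 1L
        next
      }
      ok_sites <- c(ok_sites, site)
      eligible_years[[paste(site, p, sep = "\r")]] <- qualifying
      keep_idx <- c(keep_idx,
                    which(win$parameter == p & win$site_id == site &
                            .sample_year(win) %in% qualifying))
    }
    eligible_sites[[p]] <- ok_sites
  }

  per_param <- vapply(eligible_sites, length, integer(1))
  union_sites <- unique(unlist(eligible_sites))
  inter_sites <- if (length(params) > 0) Reduce(intersect, eligible_sites) else character(0)
  report <- structure(list(
    coverage_mode = coverage_mode,
    eligible_sites = eligible_sites,
    per_parameter_site_count = per_param,
    union_site_count = length(union_sites),
    intersection_site_count = length(inter_sites),
    eligible_years = eligible_years,
    rejections = as.list(rejections)
  ), class = "eligibility_report")
  list(samples = win[sort(unique(keep_idx)), , drop = FALSE], report = report)
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat("Eligibility report (coverage mode:", x$coverage_mode, ")\n")
  cat("  eligible sites per parameter:\n")
  for (p in names(x$per_parameter_site_count))
    cat("    ", format(p, width = 12), x$per_parameter_site_count[[p]], "\n")
  cat("  union:", x$union_site_count,
      "| all-parameter intersection:", x$intersection_site_count, "\n")
  cat("  site rejections:",
      paste(names(x$rejections), unlist(x$rejections), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Serialize an eligibility report to JSON
#'
#' @param report an \code{eligibility_report}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_eligibility_report <- function(report, path) {
  out <- report
  out$eligible_years <- NULL
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
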