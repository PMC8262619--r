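# Site-specific median anomalies: annual medians, long-term references,
# anomalies, and yearly cross-site summaries.

#' Per-site annual medians
#'
#' Collapses all retained measurements of a parameter at a site within one
#' calendar year to a single median. Working from one value per site-year
#' prevents pseudoreplication bias: sites sampled more intensively would
#' otherwise dominate the yearly aggregate. Even-count medians use the
#' midpoint of the two central order statistics.
#'
#' @param samples eligibility-filtered canonical sample data frame.
#' @return data frame with columns site_id, year, parameter, annual_median,
#'   n_samples; one row per (site, year, parameter).
#' @export
annual_site_medians <- function(samples) {
  if (nrow(samples) == 0)
    return(data.frame(site_id = character(0), year = integer(0),
                      parameter = character(0), annual_median = numeric(0),
                      n_samples = integer(0), stringsAsFactors = FALSE))
  year <- .sample_year(samples)
  key <- paste(samples$site_id, year, samples$parameter, sep = "\r")
  idx <- split(seq_len(nrow(samples)), key)
  first <- vapply(idx, `[`, integer(1), 1L)
  out <- data.frame(
    site_id = samples$site_id[first],
    year = year[first],
    parameter = samples$parameter[first],
    annual_median = vapply(idx, function(i) stats::median(samples$value[i]),
                           numeric(1)),
    n_samples = lengths(idx),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$parameter, out$site_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-site long-term reference medians
#'
#' Computes one reference value per site and parameter against which annual
#' medians are compared. The default basis is the median of the site's
#' annual medians over the reference period, which keeps the reference
#' insensitive to within-year sampling intensity; \code{basis = "raw"}
#' instead takes the median of all reference-period measurements (a
#' sensitivity alternative, and it requires \code{samples}).
#'
#' @param site_year_medians output of [annual_site_medians()].
#' @param basis \code{"annual"} (default) or \code{"raw"}.
#' @param samples canonical samples; required when \code{basis = "raw"}.
#' @param reference_years optional integer vector restricting the reference
#'   period; default uses all available years (the full analysis window).
#' @return data frame with columns site_id, parameter, reference_median,
#'   n_years.
#' @export
site_reference_medians <- function(site_year_medians,
                                   basis = c("annual", "raw"),
                                   samples = NULL, reference_years = NULL) {
  basis <- match.arg(basis)
  sym <- site_year_medians
  ref_sym <- if (is.null(reference_years)) sym else
    sym[sym$year %in% reference_years, , drop = FALSE]
  key <- paste(ref_sym$site_id, ref_sym$parameter, sep = "\r")
  idx <- split(seq_len(nrow(ref_sym)), key)
  first <- vapply(idx, `[`, integer(1), 1L)
  out <- data.frame(
    site_id = ref_sym$site_id[first],
    parameter = ref_sym$parameter[first],
    reference_median = NA_real_,
    n_years = lengths(idx),
    stringsAsFactors = FALSE
  )
  if (basis == "annual") {
    out$reference_median <- vapply(idx, function(i)
      stats::median(ref_sym$annual_median[i]), numeric(1))
  } else {
    if (is.null(samples))
      stop("basis = \"raw\" requires the samples argument")
    yr <- .sample_year(samples)
    sel <- if (is.null(reference_years)) rep(TRUE, nrow(samples)) else
      yr %in% reference_years
    raw <- samples[sel, , drop = FALSE]
    rkey <- paste(raw$site_id, raw$parameter, sep = "\r")
    med <- tapply(raw$value, rkey, stats::median)
    out$reference_median <- as.numeric(med[paste(out$site_id, out$parameter,
                                                 sep = "\r")])
  }
  out <- out[order(out$parameter, out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Site-specific anomalies
#'
#' Subtracts each site's long-term reference median from its annual medians,
#' shifting every site onto a common baseline of zero. Anomalies are in the
#' parameter's original units, so a yearly anomaly trend reads directly as
#' average change per year.
#'
#' @param site_year_medians output of [annual_site_medians()].
#' @param site_references output of [site_reference_medians()].
#' @return data frame with columns site_id, year, parameter, anomaly.
#' @export
compute_anomalies <- function(site_year_medians, site_references) {
  key <- paste(site_year_medians$site_id, site_year_medians$parameter,
               sep = "\r")
  rkey <- paste(site_references$site_id, site_references$parameter,
                sep = "\r")
  m <- match(key, rkey)
  if (anyNA(m))
    stop("missing reference median for ",
         paste(unique(key[is.na(m)]), collapse = ", "))
  data.frame(
    site_id = site_year_medians$site_id,
    year = site_year_medians$year,
    parameter = site_year_medians$parameter,
    anomaly = site_year_medians$annual_median -
      site_references$reference_median[m],
    stringsAsFactors = FALSE
  )
}

#' Yearly cross-site anomaly summaries
#'
#' Collapses site-specific anomalies to one median anomaly per year and
#' parameter, with the 25th/75th percentiles, range, and contributing site
#' count. Years with fewer than \code{min_sites_per_year} sites are excluded
#' (and listed in the \code{"excluded_years"} attribute); years with exactly
#' the minimum are flagged \code{low_n_flag}, mirroring the asterisk used in
#' monitoring-program trend figures.
#'
#' @param anomalies output of [compute_anomalies()].
#' @param min_sites_per_year minimum sites for a year to be retained.
#' @return data frame with columns year, parameter, median_anomaly, p25,
#'   p75, min, max, n_sites, low_n_flag; rows ordered by parameter then
#'   year.
#' @export
yearly_summaries <- function(anomalies, min_sites_per_year = 3) {
  key <- paste(anomalies$parameter, anomalies$year, sep = "\r")
  idx <- split(seq_len(nrow(anomalies)), key)
  first <- vapply(idx, `[`, integer(1), 1L)
  n_sites <- vapply(idx, function(i) length(unique(anomalies$site_id[i])),
                    integer(1))
  stat <- function(f) vapply(idx, function(i) f(anomalies$anomaly[i]),
                             numeric(1))
  out <- data.frame(
    year = anomalies$year[first],
    parameter = anomalies$parameter[first],
    median_anomaly = stat(stats::median),
    p25 = stat(function(v) stats::quantile(v, 0.25, type = 7, names = FALSE)),
    p75 = stat(function(v) stats::quantile(v, 0.75, type = 7, names = FALSE)),
    min = stat(min),
    max = stat(max),
    n_sites = n_sites,
    stringsAsFactors = FALSE
  )
  drop <- out$n_sites < min_sites_per_year
  excluded <- out[drop, c("parameter", "year", "n_sites"), drop = FALSE]
  out <- out[!drop, , drop = FALSE]
  if (nrow(out) == 0)
    stop("no year has at least ", min_sites_per_year,
         " sites for any parameter")
  out$low_n_flag <- out$n_sites == min_sites_per_year
  out <- out[order(out$parameter, out$year), , drop = FALSE]
  rownames(out) <- NULL
  rownames(excluded) <- NULL
  attr(out, "excluded_years") <- excluded
  out
}

#' Write yearly anomaly summaries to CSV
#'
#' Deterministic row order (parameter, then year), full floating precision.
#'
#' @param yearly output of [yearly_summaries()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_yearly_summaries <- function(yearly, path) {
  cols <- c("year", "parameter", "median_anomaly", "p25", "p75", "min",
            "max", "n_sites", "low_n_flag")
  utils::write.csv(yearly[order(yearly$parameter, yearly$year), cols],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
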