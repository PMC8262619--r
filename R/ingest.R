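# Reading and harmonizing long-format lake monitoring records.

WQ_PARAMETERS <- c("temperature", "chla", "tn", "tp", "np_ratio")

WQ_UNITS <- c(temperature = "degC", chla = "ug/L", tn = "ug/L",
              tp = "ug/L", np_ratio = "molar")

#' Molar nitrogen-to-phosphorus conversion constant
#'
#' Ratio of the atomic weight of phosphorus (30.974) to that of nitrogen
#' (14.007). Multiplying a TN:TP mass-concentration ratio by this constant
#' converts it to a molar ratio. Kept at full floating precision
#' (approximately 2.2113, commonly quoted rounded to 2.21).
#'
#' @export
np_molar_constant <- 30.974 / 14.007

.default_param_map <- c(
  temperature = "temperature", temp = "temperature", water_temp = "temperature",
  chla = "chla", chl_a = "chla", chl = "chla", chlorophyll = "chla",
  chlorophyll_a = "chla",
  tn = "tn", total_nitrogen = "tn",
  tp = "tp", total_phosphorus = "tp",
  np_ratio = "np_ratio", np = "np_ratio", tn_tp = "np_ratio", "tn:tp" = "np_ratio"
)

.default_unit_map <- stats::setNames(
  c(1, 1, 1, 1000, 1, 1, 1, 1, 1, 1, 1),
  c("ug/l", "µg/l", "μg/l", "mg/l", "degc", "c", "°c",
    "celsius", "molar", "ratio", "none")
)

#' Read long-format monitoring samples
#'
#' Reads a delimited text file of water-quality measurements, maps columns
#' and parameter names onto the canonical schema, converts units, validates
#' each row, and returns the retained samples together with a load report.
#'
#' The canonical sample table has columns \code{site_id} (character),
#' \code{sample_date} (\code{Date}), \code{depth_m} (numeric metres, may be
#' \code{NA}), \code{parameter} (one of \code{temperature}, \code{chla},
#' \code{tn}, \code{tp}, \code{np_ratio}), \code{value} (numeric, canonical
#' units: degrees C for temperature, ug/L for concentrations, dimensionless
#' molar ratio for \code{np_ratio}), \code{below_detection} (logical) and
#' \code{detection_limit} (numeric, \code{NA} when not applicable).
#' Replicate measurements of the same site/date/depth/parameter are legal;
#' they are resolved by medians downstream.
#'
#' Rows that cannot be harmonized are dropped, never repaired: unparseable
#' dates (\code{bad_date}), non-numeric or missing values (\code{bad_value}),
#' negative concentrations (\code{negative_value}), temperatures outside the
#' plausibility window (\code{temperature_range}), unknown parameter names
#' (\code{unknown_parameter}), unknown unit labels (\code{unknown_unit}) and
#' negative depths (\code{bad_depth}).
#'
#' @param path path to a CSV/TSV file.
#' @param schema_map named character vector mapping canonical column names
#'   (\code{site_id}, \code{sample_date}, \code{parameter}, \code{value},
#'   optionally \code{depth_m}, \code{units}, \code{below_detection},
#'   \code{detection_limit}) to the column names used in the file. Columns
#'   already bearing canonical names need no entry.
#' @param unit_map named numeric vector of multiplicative conversion factors
#'   to canonical units, keyed by (case-insensitive) unit label; merged over
#'   the built-in defaults (\code{mg/L} is 1000, canonical labels 1).
#' @param param_map named character vector mapping (case-insensitive)
#'   parameter labels in the file to canonical parameter names; merged over
#'   built-in synonyms.
#' @param date_formats candidate date formats tried in order.
#' @param temperature_range length-2 numeric plausibility window in degrees C.
#' @param sep field separator passed to \code{\link[utils]{read.csv}}.
#'
#' @return list with \code{samples} (canonical data frame as above) and
#'   \code{report}: rows read, kept, and rejected counts by reason.
#' @seealso [compute_np_ratio()], [wq_trend()]
#' @export
read_samples <- function(path, schema_map = NULL, unit_map = NULL,
                         param_map = NULL,
                         date_formats = c("%Y-%m-%d", "%Y/%m/%d", "%m/%d/%Y"),
                         temperature_range = c(-5, 45), sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  canonicalize_samples(raw, schema_map = schema_map, unit_map = unit_map,
                       param_map = param_map, date_formats = date_formats,
                       temperature_range = temperature_range)
}

#' Canonicalize a raw sample table
#'
#' Workhorse behind [read_samples()]; accepts an in-memory data frame with
#' character (or already typed) columns and applies the same mapping,
#' conversion and validation rules. Useful for re-validating programmatic
#' input.
#'
#' @inheritParams read_samples
#' @param raw data frame of raw records.
#' @return list with \code{samples} and \code{report} as in [read_samples()].
#' @export
canonicalize_samples <- function(raw, schema_map = NULL, unit_map = NULL,
                                 param_map = NULL,
                                 date_formats = c("%Y-%m-%d", "%Y/%m/%d", "%m/%d/%Y"),
                                 temperature_range = c(-5, 45)) {
  schema <- c(site_id = "site_id", sample_date = "sample_date",
              depth_m = "depth_m", parameter = "parameter", value = "value",
              units = "units", below_detection = "below_detection",
              detection_limit = "detection_limit")
  if (!is.null(schema_map)) schema[names(schema_map)] <- schema_map
  required <- c("site_id", "sample_date", "parameter", "value")
  missing_cols <- required[!schema[required] %in% names(raw)]
  if (length(missing_cols) > 0)
    stop("missing required column(s): ",
         paste(schema[missing_cols], collapse = ", "))

  pm <- .default_param_map
  if (!is.null(param_map)) pm[tolower(names(param_map))] <- param_map
  um <- .default_unit_map
  if (!is.null(unit_map)) um[tolower(names(unit_map))] <- unit_map

  n <- nrow(raw)
  get_col <- function(field) {
    if (schema[[field]] %in% names(raw)) raw[[schema[[field]]]] else rep(NA, n)
  }

  site_id <- as.character(get_col("site_id"))
  date_raw <- as.character(get_col("sample_date"))
  sample_date <- .parse_dates(date_raw, date_formats)
  value <- suppressWarnings(as.numeric(get_col("value")))
  depth_raw <- get_col("depth_m")
  depth_m <- suppressWarnings(as.numeric(depth_raw))
  param_raw <- tolower(trimws(as.character(get_col("parameter"))))
  parameter <- unname(pm[param_raw])
  units_raw <- tolower(trimws(as.character(get_col("units"))))
  units_raw[is.na(units_raw)] <- ""
  # an absent/blank unit label means the value is already canonical
  unit_factor <- ifelse(units_raw == "", 1, unname(um[units_raw]))
  bd_raw <- get_col("below_detection")
  below_detection <- .parse_logical(bd_raw)
  detection_limit <- suppressWarnings(as.numeric(get_col("detection_limit")))

  reason <- rep(NA_character_, n)
  flag <- function(cond, why) reason[is.na(reason) & cond] <<- why
  flag(is.na(sample_date), "bad_date")
  flag(is.na(value), "bad_value")
  flag(is.na(parameter), "unknown_parameter")
  flag(is.na(unit_factor), "unknown_unit")
  flag(!is.na(depth_raw) & nzchar(trimws(as.character(depth_raw))) &
         is.na(depth_m), "bad_depth")
  flag(!is.na(depth_m) & depth_m < 0, "bad_depth")

  value <- value * ifelse(is.na(unit_factor), 1, unit_factor)
  detection_limit <- detection_limit * ifelse(is.na(unit_factor), 1, unit_factor)
  conc <- !is.na(parameter) & parameter != "temperature"
  flag(conc & value < 0, "negative_value")
  flag(!is.na(parameter) & parameter == "temperature" &
         (value < temperature_range[1] | value > temperature_range[2]),
       "temperature_range")

  keep <- is.na(reason)
  samples <- data.frame(
    site_id = site_id[keep],
    sample_date = sample_date[keep],
    depth_m = depth_m[keep],
    parameter = parameter[keep],
    value = value[keep],
    below_detection = ifelse(is.na(below_detection[keep]), FALSE,
                             below_detection[keep]),
    detection_limit = detection_limit[keep],
    stringsAsFactors = FALSE
  )
  tallies <- table(reason[!keep])
  report <- list(
    rows_read = n,
    rows_kept = sum(keep),
    rows_rejected = sum(!keep),
    rejected_by_reason = as.list(stats::setNames(as.integer(tallies),
                                                 names(tallies)))
  )
  list(samples = samples, report = report)
}

.parse_dates <- function(x, formats) {
  out <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  pending <- !is.na(x) & nzchar(trimws(x))
  for (fmt in formats) {
    if (!any(pending)) break
    parsed <- as.Date(x[pending], format = fmt)
    # reject partial matches like "2000-13-40" that as.Date maps to NA anyway
    hit <- !is.na(parsed)
    out[which(pending)[hit]] <- parsed[hit]
    pending[pending] <- !hit
  }
  out
}

.parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "n", "")] <- FALSE
  out
}

#' Derive molar TN:TP ratio samples
#'
#' Pairs total nitrogen and total phosphorus measurements and emits derived
#' \code{np_ratio} samples: \code{(tn / tp) * np_molar_constant}, i.e. the
#' mass-concentration ratio converted to a molar ratio with the atomic-weight
#' ratio P/N = 30.974/14.007 at full precision (2.21 rounded).
#'
#' Pairing is by sampling event by default: tn and tp measured at the same
#' site, date and depth. Replicates within an event are first collapsed to
#' their median. Events with tp equal to zero produce no ratio (counted in
#' the report), as do unmatched events. The derived row is flagged below
#' detection when either component was.
#'
#' @param samples canonical sample data frame (see [read_samples()]).
#' @param pairing \code{"event"} (site, date, depth; default) or
#'   \code{"site_year"} for a coarser sensitivity pairing.
#' @return data frame of \code{np_ratio} samples in the canonical schema,
#'   with a \code{"report"} attribute listing pair counts, unmatched events
#'   and zero-tp events.
#' @export
compute_np_ratio <- function(samples, pairing = c("event", "site_year")) {
  pairing <- match.arg(pairing)
  tn <- samples[samples$parameter == "tn", , drop = FALSE]
  tp <- samples[samples$parameter == "tp", , drop = FALSE]
  key <- function(df) {
    if (pairing == "event") {
      paste(df$site_id, format(df$sample_date),
            ifelse(is.na(df$depth_m), "NA", format(df$depth_m)), sep = "\r")
    } else {
      paste(df$site_id, format(df$sample_date, "%Y"), sep = "\r")
    }
  }
  collapse <- function(df) {
    k <- key(df)
    val <- tapply(df$value, k, stats::median)
    bd <- tapply(df$below_detection, k, any)
    first <- df[!duplicated(k), , drop = FALSE]
    first <- first[match(names(val), key(first)), , drop = FALSE]
    first$value <- as.numeric(val)
    first$below_detection <- as.logical(bd)
    first
  }
  tn <- collapse(tn)
  tp <- collapse(tp)
  m <- match(key(tn), key(tp))
  matched <- !is.na(m)
  tp_m <- tp[m[matched], , drop = FALSE]
  tn_m <- tn[matched, , drop = FALSE]
  zero_tp <- tp_m$value == 0
  out <- tn_m[!zero_tp, , drop = FALSE]
  tpv <- tp_m$value[!zero_tp]
  out$parameter <- rep("np_ratio", nrow(out))
  out$value <- (out$value / tpv) * np_molar_constant
  out$below_detection <- out$below_detection | tp_m$below_detection[!zero_tp]
  out$detection_limit <- rep(NA_real_, nrow(out))
  rownames(out) <- NULL
  attr(out, "report") <- list(
    n_pairs = nrow(out),
    n_zero_tp = sum(zero_tp),
    n_tn_unmatched = sum(!matched),
    n_tp_unmatched = nrow(tp) - sum(matched)
  )
  out
}

TROPHIC_CLASSES <- c("oligotrophic", "mesotrophic", "eutrophic", "hypereutrophic")

#' Classify trophic state from chlorophyll a
#'
#' Maps chlorophyll a concentrations onto the four trophic state classes
#' with left-closed intervals: a value equal to a boundary belongs to the
#' upper (more productive) class. Default boundaries are 3.5 ug/L
#' (oligotrophic/mesotrophic), 9 ug/L (mesotrophic/eutrophic) and 24 ug/L
#' (eutrophic/hypereutrophic).
#'
#' @param chl numeric vector of chlorophyll a concentrations (ug/L, >= 0).
#' @param boundaries strictly increasing length-3 numeric vector of class
#'   boundaries (ug/L).
#' @return factor with levels oligotrophic, mesotrophic, eutrophic,
#'   hypereutrophic.
#' @export
classify_trophic_state <- function(chl, boundaries = c(3.5, 9, 24)) {
  stopifnot(length(boundaries) == 3, all(diff(boundaries) > 0))
  if (any(chl < 0, na.rm = TRUE)) stop("chlorophyll must be non-negative")
  idx <- findInterval(chl, boundaries) + 1L
  factor(TROPHIC_CLASSES[idx], levels = TROPHIC_CLASSES)
}

#' Summary statistics for one parameter
#'
#' Quartiles (linear interpolation between order statistics, the type-7
#' convention), mean, median, maximum and standard deviation over all
#' retained measurements of one parameter, in canonical units.
#'
#' @param samples canonical sample data frame.
#' @param parameter one of the canonical parameter names.
#' @return one-row data frame: parameter, units, p25, mean, median, p75,
#'   max, sd.
#' @export
summarize_parameter <- function(samples, parameter) {
  stopifnot(parameter %in% WQ_PARAMETERS)
  v <- samples$value[samples$parameter == parameter]
  if (length(v) == 0) stop("no samples for parameter ", parameter)
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  data.frame(parameter = parameter, units = unname(WQ_UNITS[parameter]),
             p25 = q[1], mean = mean(v), median = stats::median(v),
             p75 = q[2], max = max(v),
             sd = if (length(v) == 1) 0 else stats::sd(v),
             stringsAsFactors = FALSE)
}

#' Trophic state distribution across sites
#'
#' Classifies each site by its long-term median chlorophyll a and reports
#' the percentage of sites in each trophic class.
#'
#' @param x either a canonical sample data frame (chlorophyll rows are used)
#'   or a numeric vector of per-site median chlorophyll values.
#' @param boundaries passed to [classify_trophic_state()].
#' @return data frame with columns \code{class} and \code{percent}
#'   (percentages sum to 100).
#' @export
trophic_distribution <- function(x, boundaries = c(3.5, 9, 24)) {
  if (is.data.frame(x)) {
    chl <- x[x$parameter == "chla", , drop = FALSE]
    if (nrow(chl) == 0) stop("no chlorophyll samples")
    meds <- tapply(chl$value, chl$site_id, stats::median)
  } else {
    meds <- x
  }
  if (length(meds) == 0) stop("no site medians")
  cls <- classify_trophic_state(as.numeric(meds), boundaries)
  pct <- 100 * as.numeric(table(cls)) / length(cls)
  data.frame(class = TROPHIC_CLASSES, percent = pct, stringsAsFactors = FALSE)
}

#' Write canonical samples to CSV
#'
#' @param samples canonical sample data frame.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_samples <- function(samples, path) {
  out <- samples
  out$sample_date <- format(out$sample_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
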