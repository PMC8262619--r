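# End-to-end run orchestration and report/figure writers.

#' Run the full anomaly trend pipeline and write its artifacts
#'
#' Reads (or accepts) canonical samples, fits [wq_trend()], and writes every
#' stage's output to \code{output_dir}: the eligibility report
#' (\code{eligibility_report.json}), site-year medians
#' (\code{site_year_medians.csv}), yearly median anomalies
#' (\code{yearly_anomaly.csv}), the trend report (\code{trend_report.csv}
#' and \code{.json}), a plain-text classification summary
#' (\code{trend_summary.txt}), the effective options
#' (\code{run_config.json}), and, optionally, one figure per parameter.
#' Outputs are deterministic for identical input and configuration.
#'
#' @param input path to a canonical samples CSV, or a canonical sample data
#'   frame.
#' @param output_dir directory for artifacts (created if needed).
#' @param config an [eligibility_config()].
#' @param figures write one figure file per assessed parameter.
#' @param figure_format \code{"png"} or \code{"pdf"}.
#' @param quiet suppress per-stage record counts.
#' @param ... further arguments passed to [wq_trend()].
#' @return invisibly, the \code{wq_trend} object with an added
#'   \code{artifacts} attribute listing the files written.
#' @export
run_pipeline <- function(input, output_dir, config = eligibility_config(),
                         figures = TRUE, figure_format = c("png", "pdf"),
                         quiet = FALSE, ...) {
  figure_format <- match.arg(figure_format)
  say <- function(...) if (!quiet) message(...)
  if (is.character(input)) {
    loaded <- read_samples(input)
    samples <- loaded$samples
    say("read ", loaded$report$rows_read, " rows, kept ",
        loaded$report$rows_kept, ", rejected ", loaded$report$rows_rejected)
  } else {
    samples <- input
    say("using ", nrow(samples), " in-memory samples")
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- wq_trend(samples, config = config, ...)
  say("eligible sites (union): ", fit$eligibility$union_site_count,
      "; site-year medians: ", nrow(fit$site_year_medians),
      "; retained year summaries: ", nrow(fit$yearly))

  paths <- c(
    eligibility = write_eligibility_report(
      fit$eligibility, file.path(output_dir, "eligibility_report.json")),
    site_year_medians = {
      p <- file.path(output_dir, "site_year_medians.csv")
      utils::write.csv(fit$site_year_medians, p, row.names = FALSE,
                       quote = FALSE)
      p
    },
    yearly = write_yearly_summaries(
      fit$yearly, file.path(output_dir, "yearly_anomaly.csv")),
    trend_csv = write_trend_report(
      fit, file.path(output_dir, "trend_report.csv")),
    trend_json = {
      p <- file.path(output_dir, "trend_report.json")
      jsonlite::write_json(summary(fit)$table, p, auto_unbox = TRUE,
                           pretty = TRUE, digits = NA)
      p
    },
    summary_txt = {
      p <- file.path(output_dir, "trend_summary.txt")
      writeLines(format_trend_table(fit), p)
      p
    },
    run_config = {
      p <- file.path(output_dir, "run_config.json")
      cfg <- c(unclass(fit$config), fit$options)
      jsonlite::write_json(cfg, p, auto_unbox = TRUE, pretty = TRUE)
      p
    }
  )
  if (figures)
    paths <- c(paths, render_figures(fit, output_dir, format = figure_format))
  say("wrote ", length(paths), " artifacts to ", output_dir)
  attr(fit, "artifacts") <- paths
  invisible(fit)
}

#' Write the per-parameter trend report as CSV
#'
#' @param fit a \code{wq_trend} object.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_trend_report <- function(fit, path) {
  utils::write.csv(summary(fit)$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plain-text trend classification table
#'
#' Formats the classifications with the conventional symbols: \code{++}/
#' \code{--} for a trend, \code{+}/\code{-} for a weak trend, \code{0} for
#' no trend.
#'
#' @param fit a \code{wq_trend} object.
#' @return character vector of lines.
#' @export
format_trend_table <- function(fit) {
  tab <- summary(fit)$table
  c("Trend classification (++/-- trend, +/- weak trend, 0 no trend)",
    sprintf("  %-12s %-3s slope=%-10s p=%-10s n=%d",
            tab$parameter, tab$symbol, signif(tab$slope, 4),
            signif(tab$p_value, 4), tab$n_years))
}

#' Render anomaly trend figures to files
#'
#' Writes one figure per assessed parameter via [plot.wq_trend()].
#' Parameters without an assessment are skipped with a warning.
#'
#' @param fit a \code{wq_trend} object.
#' @param output_dir target directory.
#' @param format \code{"png"} or \code{"pdf"}.
#' @return named character vector of files written.
#' @export
render_figures <- function(fit, output_dir, format = c("png", "pdf")) {
  format <- match.arg(format)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (p in names(fit$assessments)) {
    path <- file.path(output_dir, paste0("trend_", p, ".", format))
    if (format == "png") grDevices::png(path, width = 900, height = 600)
    else grDevices::pdf(path, width = 9, height = 6)
    tryCatch(plot(fit, parameter = p), finally = grDevices::dev.off())
    paths[paste0("figure_", p)] <- path
  }
  paths
}
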