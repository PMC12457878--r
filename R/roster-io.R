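#' Read a worker roster from CSV
#'
#' Strict reader for the pipeline's input format: comma-separated, UTF-8,
#' mandatory header, period decimal point (comma decimals are a row-level
#' error, not silently coerced — the format is frozen precisely because
#' source tables in this field mix decimal conventions). Header matching is
#' case-insensitive.
#'
#' Mandatory columns: `worker_id`, `concentration_ppm`, `weight_kg`,
#' `hours_per_day`, `days_per_year`, `tenure_years`. Optional:
#' `rfc` (per-worker reference dose), `mda`, `bun`, `creatinine`
#' (biomarkers; empty cells are missing values). Unknown columns are
#' carried through untouched.
#'
#' @param path Path to the CSV file.
#' @param validate Check the exposure-field invariants after parsing
#'   (default TRUE).
#' @return A roster data.frame with canonical lower-case column names.
#' @examples
#' r <- read_roster(system.file("extdata", "table3.csv", package = "benzrisk"))
#' nrow(r)
#' @export
read_roster <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("roster file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8", strip.white = TRUE)
  if (nrow(raw) == 0L) {
    stop("empty roster: ", path, " has a header but no data rows",
         call. = FALSE)
  }
  names(raw) <- tolower(names(raw))
  mandatory <- c("worker_id", "concentration_ppm", "weight_kg",
                 "hours_per_day", "days_per_year", "tenure_years")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols)) {
    stop("roster ", path, " is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  numeric_cols <- intersect(
    c(setdiff(mandatory, "worker_id"), "rfc", biomarker_columns(),
      "breathing_rate", "intake", "rq"),
    names(raw))
  problems <- character(0)
  for (col in numeric_cols) {
    cell <- raw[[col]]
    parsed <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & cell != "" & cell != "NA" & is.na(parsed))
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "row %d, column '%s': cannot parse numeral '%s'%s",
        bad, col, cell[bad],
        ifelse(grepl(",", cell[bad]), " (comma decimals are not accepted)",
               "")))
    }
    raw[[col]] <- parsed
  }
  if (length(problems)) {
    stop("roster ", path, " failed validation:\n  - ",
         paste(utils::head(problems, 10), collapse = "\n  - "),
         call. = FALSE)
  }
  optional_na <- intersect(setdiff(numeric_cols, mandatory), names(raw))
  mandatory_na <- vapply(setdiff(mandatory, "worker_id"),
                         function(col) anyNA(raw[[col]]), logical(1))
  if (any(mandatory_na)) {
    stop("roster ", path, ": missing values in mandatory column(s): ",
         paste(names(mandatory_na)[mandatory_na], collapse = ", "),
         call. = FALSE)
  }
  if ("verified" %in% names(raw)) {
    raw$verified <- as.logical(raw$verified)
  }
  if (validate) {
    validate_exposure_inputs(raw$concentration_ppm, raw$weight_kg,
                             raw$hours_per_day, raw$days_per_year,
                             raw$tenure_years, raw$worker_id)
  }
  raw
}

#' Write a roster (or assessment) to CSV
#'
#' Full-precision CSV output in the same dialect [read_roster()] accepts,
#' so `read_roster(write_roster(x, f))` round-trips every value.
#'
#' @param roster A roster or assessment data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  out <- as.data.frame(roster)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' The packaged 27-worker validation roster
#'
#' The per-worker exposure table of the motivating car-painting study:
#' airborne benzene concentration, body weight, daily and annual exposure,
#' tenure, the study's own reference dose per row (`rfc`), and — for
#' validation only — the published breathing-rate, intake and RQ columns.
#' The `verified` flag marks the rows whose published intake and RQ are
#' internally consistent with their published inputs (rows 1–15 and 17);
#' the remaining rows carry printing defects in the source — several RQ
#' cells repeat a concentration value, and row 16's tenure is truncated to
#' 0.08 y from about one month (0.083 y) — and are excluded from numeric
#' reproduction checks, though their classifications and the column means
#' are sound.
#'
#' @return A roster data.frame with 27 rows.
#' @examples
#' t3 <- table3_roster()
#' sum(t3$verified)
#' @export
table3_roster <- function() {
  read_roster(system.file("extdata", "table3.csv", package = "benzrisk"))
}

#' Render a plain-text assessment report
#'
#' Formats the standard report blocks: the per-worker computation chain at
#' 6 significant figures, the TLV-exceedance and RQ-classification
#' frequency tables, the exposure column means, and — when biomarkers are
#' available — the correlation screen. Cohorts without biomarker data get
#' an explicit "insufficient data" marker instead of a correlation block.
#'
#' @param assessment A `benz_assessment` from [assess_cohort()].
#' @param screen Optional `correlation_screen`; if NULL one is attempted
#'   from the assessment's biomarker columns.
#' @param params [risk_params()] used for the threshold labels.
#' @return Character vector of report lines, invisibly; printed to the
#'   console when `quiet = FALSE`.
#' @param quiet Suppress printing and just return the lines.
#' @export
render_report <- function(assessment, screen = NULL, params = risk_params(),
                          quiet = FALSE) {
  params <- as_risk_params(params)
  if (!is.data.frame(assessment) || nrow(assessment) == 0L) {
    stop("render_report: empty assessment", call. = FALSE)
  }
  lines <- c("Benzene occupational risk assessment",
             strrep("=", 36), "")
  worker_cols <- c("worker_id", "concentration_ppm", "weight_kg",
                   "hours_per_day", "days_per_year", "tenure_years",
                   "breathing_rate_m3h", "rfc", "intake", "rq",
                   "rq_class", "tlv_class")
  tab <- assessment[, worker_cols]
  for (col in names(tab)) {
    if (is.numeric(tab[[col]])) tab[[col]] <- signif(tab[[col]], 6)
  }
  lines <- c(lines, "Per-worker computation",
             utils::capture.output(print.data.frame(tab, row.names = FALSE)),
             "")
  means <- vapply(c("concentration_ppm", "weight_kg", "hours_per_day",
                    "days_per_year", "tenure_years", "intake", "rq"),
                  function(col) mean(assessment[[col]]), numeric(1))
  lines <- c(lines, "Column means",
             paste0("  ", format(names(means), width = 18),
                    signif(means, 6)), "")
  tlv <- frequency_table(assessment$tlv_class)
  rqf <- frequency_table(assessment$rq_class)
  fmt_freq <- function(ft, title) {
    c(title,
      sprintf("  %-12s %4d  %5.1f%%", ft$category, ft$n,
              round(ft$percentage, 1)),
      sprintf("  %-12s %4d", "total", attr(ft, "total")), "")
  }
  lines <- c(lines,
             fmt_freq(tlv, sprintf("Concentration vs TLV (%g ppm)",
                                   params$tlv_ppm)),
             fmt_freq(rqf, sprintf("Risk Quotient classification (unsafe: RQ >= %g)",
                                   params$rq_threshold)))
  if (is.null(screen)) {
    have_bm <- intersect(biomarker_columns(), names(assessment))
    enough <- length(have_bm) > 0 &&
      any(vapply(have_bm, function(b) sum(!is.na(assessment[[b]])) >= 3,
                 logical(1)))
    screen <- if (enough) {
      tryCatch(suppressWarnings(correlation_screen(assessment)),
               error = function(e) NULL)
    } else NULL
  }
  if (is.null(screen)) {
    lines <- c(lines, "Exposure-biomarker correlations",
               "  insufficient data: no biomarker column with >= 3 values",
               "")
  } else {
    lines <- c(lines, "Exposure-biomarker correlations (Pearson, two-sided)",
               sprintf("  %-18s %-11s %7s %4s %8s",
                       "exposure", "biomarker", "r", "n", "p"),
               sprintf("  %-18s %-11s %7.3f %4d %8.3f",
                       screen$exposure, screen$biomarker, screen$r,
                       screen$n, screen$p_value),
               "")
  }
  if (!quiet) cat(lines, sep = "\n")
  invisible(lines)
}
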