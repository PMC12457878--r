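#' Frequency table of a categorical classification
#'
#' Counts and percentages over a fixed, ordered set of categories, the
#' building block of the cohort's descriptive tables (age bands, TLV
#' exceedance, RQ classification). Percentages are stored at full precision;
#' the print method rounds to one decimal.
#'
#' @param values A factor, or a vector coercible to one.
#' @param levels Optional category order; defaults to the factor levels or
#'   the order of first appearance.
#' @param na_rm Drop missing values before counting (default TRUE).
#' @return A data.frame of class `frequency_table` with columns `category`,
#'   `n`, `percentage`, and attribute `total`.
#' @examples
#' a <- assess_cohort(table3_roster())
#' frequency_table(a$rq_class)
#' @export
frequency_table <- function(values, levels = NULL, na_rm = TRUE) {
  if (na_rm) values <- values[!is.na(values)]
  if (length(values) == 0L) {
    stop("frequency_table: no non-missing values to tabulate", call. = FALSE)
  }
  if (!is.factor(values)) {
    values <- factor(values, levels = if (is.null(levels)) unique(values)
                                      else levels)
  } else if (!is.null(levels)) {
    values <- factor(values, levels = levels)
  }
  n <- as.vector(table(values))
  total <- sum(n)
  out <- data.frame(
    category = base::levels(values),
    n = n,
    percentage = 100 * n / total,
    stringsAsFactors = FALSE
  )
  attr(out, "total") <- total
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' @export
print.frequency_table <- function(x, ...) {
  shown <- data.frame(category = x$category, n = x$n,
                      percentage = round(x$percentage, 1))
  print.data.frame(shown, row.names = FALSE, ...)
  cat(sprintf("total: %d\n", attr(x, "total")))
  invisible(x)
}

#' Cut a numeric vector at a threshold into a two-level factor
#'
#' Convenience binning for the two rules of the assessment, e.g.
#' `threshold_bins(rq, 1, "geq")` gives the unsafe/safe split and
#' `threshold_bins(conc, 0.5, "gt")` the TLV exceedance split.
#'
#' @param x Numeric vector.
#' @param threshold Cut point.
#' @param boundary `"geq"`: first level is `x >= threshold`; `"gt"`: first
#'   level is `x > threshold`.
#' @param labels Length-2 category labels, upper category first.
#' @return A factor with the upper category as first level.
#' @export
threshold_bins <- function(x, threshold, boundary = c("geq", "gt"),
                           labels = NULL) {
  boundary <- match.arg(boundary)
  upper <- if (boundary == "geq") x >= threshold else x > threshold
  if (is.null(labels)) {
    op <- if (boundary == "geq") ">=" else ">"
    lo <- if (boundary == "geq") "<" else "<="
    labels <- c(paste0(op, threshold), paste0(lo, threshold))
  }
  factor(ifelse(upper, labels[1], labels[2]), levels = labels)
}

#' Descriptive summary of a numeric column
#'
#' Arithmetic mean (the cohort tables' "avg" row) together with sd, min,
#' max and n, computed at full precision.
#'
#' @param x Numeric vector.
#' @param na_rm Drop missing values (default TRUE).
#' @return A one-row data.frame: `n`, `mean`, `sd`, `min`, `max`.
#' @export
column_summary <- function(x, na_rm = TRUE) {
  if (!is.numeric(x)) stop("column_summary: x must be numeric", call. = FALSE)
  if (na_rm) x <- x[!is.na(x)]
  if (length(x) == 0L) {
    stop("column_summary: no non-missing values", call. = FALSE)
  }
  data.frame(n = length(x), mean = mean(x), sd = stats::sd(x),
             min = min(x), max = max(x))
}

#' Pearson correlation with a t-based two-sided p-value
#'
#' Product-moment correlation over the pairwise complete observations, with
#' significance from the exact null distribution of
#' t = r sqrt(df) / sqrt(1 - r^2) on df = n - 2 degrees of freedom,
#' two-sided. The effective n is always the number of complete (x, y)
#' pairs actually used, never a declared sample size.
#'
#' @param x,y Numeric vectors of equal length; incomplete pairs are dropped.
#' @param pair_label Optional label carried into the result.
#' @return An object of class `correlation_result`: a list with
#'   `pair_label`, `r`, `n_effective`, `df`, `statistic` (the t value) and
#'   `p_value`.
#' @examples
#' set.seed(1)
#' x <- rnorm(27); y <- 0.5 * x + rnorm(27)
#' pearson_test(x, y, "x vs y")
#' @export
pearson_test <- function(x, y, pair_label = NULL) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop("pearson_test: x and y must be numeric vectors of equal length",
         call. = FALSE)
  }
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    stop("pearson_test: fewer than 3 complete pairs (", n, ")",
         call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_test: zero variance in x or y; correlation undefined",
         call. = FALSE)
  }
  r <- sum(scale(x, scale = FALSE) * scale(y, scale = FALSE)) /
    ((n - 1) * stats::sd(x) * stats::sd(y))
  r <- max(-1, min(1, r))
  res <- pearson_p_from_r(r, n)
  structure(list(pair_label = pair_label, r = r, n_effective = n,
                 df = res$df, statistic = res$statistic,
                 p_value = res$p_value),
            class = "correlation_result")
}

#' p-value of a Pearson correlation from (r, n) alone
#'
#' The t transform lets a reported correlation be re-tested without the raw
#' data: t = r sqrt(n - 2) / sqrt(1 - r^2), referred to the t distribution
#' with n - 2 degrees of freedom, two-sided. Useful for auditing published
#' correlation tables where only r and n are printed.
#'
#' @param r Pearson correlation(s) in \[-1, 1\].
#' @param n Number of complete pairs (>= 3).
#' @return A data.frame with columns `r`, `n`, `df`, `statistic`, `p_value`.
#' @examples
#' pearson_p_from_r(-0.266, 27) # p = 0.180
#' @export
pearson_p_from_r <- function(r, n) {
  if (any(abs(r) > 1)) stop("|r| must be <= 1", call. = FALSE)
  if (any(n < 3)) stop("need n >= 3 (df >= 1)", call. = FALSE)
  df <- n - 2
  tstat <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  data.frame(r = r, n = n, df = df, statistic = tstat,
             p_value = 2 * stats::pt(-abs(tstat), df))
}

#' @export
print.correlation_result <- function(x, ...) {
  lab <- if (is.null(x$pair_label)) "" else paste0(x$pair_label, ": ")
  cat(sprintf("%sr = %.3f, n = %d (df = %d), t = %.3f, two-sided p = %.3f\n",
              lab, x$r, x$n_effective, x$df, x$statistic, x$p_value))
  invisible(x)
}

#' Exposure-biomarker correlation screen
#'
#' Runs one Pearson test per (exposure metric, biomarker) pair over a risk
#' assessment, using pairwise complete cases for each pair independently,
#' as in a series of stand-alone bivariate tests. No multiplicity
#' adjustment is applied by default; `p_adjust = "bonferroni"` is available.
#' A pair that cannot be tested (too few complete pairs, zero variance) is
#' reported as an NA row with a warning rather than aborting the screen.
#'
#' For right-skewed exposure metrics (RQ is a product of lognormal-like
#' factors), `exposure_transform = "log"` applies the natural log to the
#' exposure column before correlating — standard practice in occupational
#' hygiene.
#'
#' @param assessment A `benz_assessment` (or any data.frame holding the
#'   requested columns).
#' @param exposures Exposure metric column names
#'   (default `c("concentration_ppm", "rq")`).
#' @param biomarkers Biomarker column names; defaults to whichever of
#'   `mda`, `bun`, `creatinine` are present.
#' @param exposure_transform `"identity"` or `"log"`.
#' @param p_adjust `"none"` (default, matching a series of stand-alone
#'   bivariate tests) or `"bonferroni"`.
#' @return A data.frame of class `correlation_screen`: one row per pair with
#'   `exposure`, `biomarker`, `r`, `n`, `df`, `statistic`, `p_value`.
#' @examples
#' spec <- cohort_spec(n_workers = 40)
#' a <- assess_cohort(generate_cohort(spec, seed = 7))
#' correlation_screen(a)
#' @export
correlation_screen <- function(assessment,
                               exposures = c("concentration_ppm", "rq"),
                               biomarkers = NULL,
                               exposure_transform = c("identity", "log"),
                               p_adjust = c("none", "bonferroni")) {
  exposure_transform <- match.arg(exposure_transform)
  p_adjust <- match.arg(p_adjust)
  if (is.null(biomarkers)) {
    biomarkers <- intersect(biomarker_columns(), names(assessment))
  }
  if (length(biomarkers) == 0L) {
    stop("correlation_screen: no biomarker columns present", call. = FALSE)
  }
  missing_cols <- setdiff(c(exposures, biomarkers), names(assessment))
  if (length(missing_cols)) {
    stop("correlation_screen: column(s) not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pairs <- expand.grid(biomarker = biomarkers, exposure = exposures,
                       stringsAsFactors = FALSE)[, c("exposure", "biomarker")]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ex <- pairs$exposure[i]; bm <- pairs$biomarker[i]
    x <- assessment[[ex]]
    if (exposure_transform == "log") x <- log(x)
    res <- tryCatch(pearson_test(x, assessment[[bm]]), error = identity)
    if (inherits(res, "error")) {
      warning("screen pair (", ex, ", ", bm, ") skipped: ",
              conditionMessage(res), call. = FALSE)
      data.frame(exposure = ex, biomarker = bm, r = NA_real_,
                 n = NA_integer_, df = NA_integer_, statistic = NA_real_,
                 p_value = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(exposure = ex, biomarker = bm, r = res$r,
                 n = res$n_effective, df = res$df, statistic = res$statistic,
                 p_value = res$p_value, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (p_adjust == "bonferroni") {
    out$p_adjusted <- pmin(1, out$p_value * sum(!is.na(out$p_value)))
  }
  attr(out, "exposure_transform") <- exposure_transform
  class(out) <- c("correlation_screen", "data.frame")
  out
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat("Exposure-biomarker Pearson screen",
      if (identical(attr(x, "exposure_transform"), "log"))
        "(log exposure)" else "", "\n")
  shown <- x
  for (col in c("r", "statistic", "p_value", "p_adjusted")) {
    if (col %in% names(shown)) shown[[col]] <- round(shown[[col]], 3)
  }
  print.data.frame(shown, row.names = FALSE, ...)
  invisible(x)
}
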