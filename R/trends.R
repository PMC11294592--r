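#' Year-on-year percentage changes in filing counts
#'
#' Calendar-year (January--December) totals and the year-on-year percentage
#' change `100 * (total_t - total_{t-1}) / total_{t-1}`. Years whose
#' previous year had zero filings are skipped (recorded in
#' `skipped_years`), matching the convention of ignoring zero-patent years
#' when averaging growth. The start and end years are deliberately required
#' arguments: comparison windows differ between analyses and should never
#' be chosen silently.
#'
#' @param series A [monthly_counts()] series covering the requested years in
#'   full (each year needs all 12 months).
#' @param start_year,end_year First and last calendar year (at least 2
#'   complete years).
#' @return A `trend_summary` list: `yearly_totals` (named integer),
#'   `yoy_changes` (named numeric, `NA` for skipped years),
#'   `skipped_years`, `mean_percent_change`.
#' @export
yearly_percent_changes <- function(series, start_year, end_year) {
  if (end_year - start_year < 1) {
    stop("window must cover at least 2 complete calendar years", call. = FALSE)
  }
  months <- series_months(series)
  years <- seq.int(start_year, end_year)
  totals <- vapply(years, function(yr) {
    idx <- which(substr(months, 1, 4) == sprintf("%04d", yr))
    if (length(idx) != 12) {
      stop("series does not cover all 12 months of ", yr, call. = FALSE)
    }
    sum(series$counts[idx])
  }, numeric(1))
  names(totals) <- years
  changes <- rep(NA_real_, length(years) - 1)
  names(changes) <- years[-1]
  prev <- totals[-length(totals)]
  cur <- totals[-1]
  ok <- prev > 0
  changes[ok] <- 100 * (cur[ok] - prev[ok]) / prev[ok]
  skipped <- as.integer(names(changes)[!ok])
  structure(list(yearly_totals = totals,
                 yoy_changes = changes,
                 skipped_years = skipped,
                 mean_percent_change = if (any(ok)) mean(changes[ok]) else
                   NA_real_),
            class = "trend_summary")
}

#' @export
print.trend_summary <- function(x, ...) {
  yrs <- as.integer(names(x$yearly_totals))
  cat(sprintf("<trend_summary: %d-%d, mean yearly change %+.1f%%%s>\n",
              min(yrs), max(yrs), x$mean_percent_change,
              if (length(x$skipped_years))
                sprintf(", %d year(s) skipped", length(x$skipped_years))
              else ""))
  invisible(x)
}

#' Mean year-on-year percentage change
#'
#' Arithmetic mean over the defined (non-skipped) yearly changes of a
#' [yearly_percent_changes()] summary.
#'
#' @param summary A `trend_summary`.
#' @return The mean percentage change (scalar).
#' @export
mean_percent_change <- function(summary) {
  ch <- summary$yoy_changes[!is.na(summary$yoy_changes)]
  if (!length(ch)) stop("no defined yearly changes", call. = FALSE)
  mean(ch)
}

#' Median monthly count over a period
#'
#' @param series A [monthly_counts()] series.
#' @param period Length-2 `c(from, to)` month labels inside the series
#'   (closed interval).
#' @return The median monthly count (mean of the central pair for an even
#'   number of months).
#' @export
period_median <- function(series, period) {
  sub <- series_window(series, period[1], period[2])
  median(sub$counts)
}

#' Peak filing month
#'
#' @param series A [monthly_counts()] series.
#' @return List with `month` (earliest month attaining the maximum) and
#'   `count`.
#' @export
peak_month <- function(series) {
  i <- which.max(series$counts)  # which.max returns the earliest maximum
  list(month = series_months(series)[i], count = series$counts[i])
}

#' Centered moving-average smoothing
#'
#' Display smoother for filing series: a centered moving average with an
#' odd window; at the edges the window truncates to the available months,
#' so the output has the input's length. Default window 13 months (~ one
#' year, centered).
#'
#' @param series A [monthly_counts()] series.
#' @param window Odd positive integer window, at most the series length.
#' @return Numeric vector of smoothed values, same length as the series.
#' @export
smooth_series <- function(series, window = 13) {
  n <- length(series$counts)
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  if (window < 1 || window > n) {
    stop("window must be in 1..", n, call. = FALSE)
  }
  half <- (window - 1) / 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    mean(series$counts[lo:hi])
  }, numeric(1))
}

#' Full trend summary for a series
#'
#' Convenience wrapper bundling the yearly changes, period median, peak and
#' smoothed series into one object (the pipeline's `trends` stage output).
#'
#' @inheritParams yearly_percent_changes
#' @param median_period Optional `c(from, to)` month labels for the period
#'   median.
#' @param smooth_window Odd window for [smooth_series()].
#' @return A `trend_summary` with `period_median`, `peak` and `smoothed`
#'   added.
#' @export
trend_summary <- function(series, start_year, end_year,
                          median_period = NULL, smooth_window = 13) {
  out <- yearly_percent_changes(series, start_year, end_year)
  out$period_median <- if (!is.null(median_period)) {
    period_median(series, median_period)
  } else NA_real_
  out$peak <- peak_month(series)
  out$smoothed <- smooth_series(series, smooth_window)
  out
}
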