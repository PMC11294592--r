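#' Monthly filing-count series
#'
#' A contiguous run of monthly counts with a start month: `counts[i]` is the
#' number of filings in month `start_month + (i - 1)`. This is the input to
#' the changepoint and trend modules.
#'
#' @param counts Non-negative integer vector, length at least 2, one entry
#'   per consecutive month.
#' @param start_month Start month as `"YYYY-MM"`.
#' @param taxon Optional taxon tag.
#' @return A `monthly_counts` object.
#' @export
monthly_counts <- function(counts, start_month, taxon = NA_character_) {
  counts <- as.numeric(counts)
  if (length(counts) < 2) stop("a count series needs at least 2 months",
                               call. = FALSE)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  ym_index(start_month)  # validates format
  structure(list(taxon = as.character(taxon),
                 start_month = start_month,
                 counts = as.integer(counts)),
            class = "monthly_counts")
}

#' @export
print.monthly_counts <- function(x, ...) {
  cat(sprintf("<monthly_counts%s: %d months %s..%s, total %d>\n",
              if (is.na(x$taxon)) "" else paste0(" '", x$taxon, "'"),
              length(x$counts), x$start_month,
              series_months(x)[length(x$counts)], sum(x$counts)))
  invisible(x)
}

#' @export
length.monthly_counts <- function(x) length(x$counts)

#' Month labels of a count series
#' @param series A [monthly_counts()] object.
#' @return Character vector of `"YYYY-MM"` labels, one per count.
#' @export
series_months <- function(series) {
  ym_label(ym_index(series$start_month) + seq_along(series$counts) - 1L)
}

#' Extract a contiguous sub-series
#' @param series A [monthly_counts()] object.
#' @param from,to Month labels (`"YYYY-MM"`) of the closed sub-window.
#' @return A `monthly_counts` object.
#' @export
series_window <- function(series, from, to) {
  m <- series_months(series)
  i <- match(from, m); j <- match(to, m)
  if (is.na(i) || is.na(j) || j < i) {
    stop("window ", from, "..", to, " not inside series", call. = FALSE)
  }
  monthly_counts(series$counts[i:j], from, series$taxon)
}

reverse_series <- function(series) {
  monthly_counts(rev(series$counts), series$start_month, series$taxon)
}

#' Aggregate patent records to monthly filing counts
#'
#' Counts records per calendar month of the priority date over a closed
#' window; months with no records are explicit zeros. Records outside the
#' window are dropped and reported via the `"dropped"` attribute.
#'
#' @param records A `patent_records` data.frame.
#' @param window Length-2 character vector `c(from, to)` of `"YYYY-MM"`
#'   months, `from <= to`, spanning at least 2 months.
#' @param taxon Taxon tag for the resulting series (defaults to the single
#'   taxon present in `records`, if unique).
#' @return A [monthly_counts()] series; `attr(, "dropped")` holds the number
#'   of out-of-window records.
#' @export
aggregate_monthly <- function(records, window = c("1970-01", "2020-12"),
                              taxon = NULL) {
  if (length(window) != 2) stop("window must be c(from, to)", call. = FALSE)
  i0 <- ym_index(window[1]); i1 <- ym_index(window[2])
  if (i1 < i0) stop("empty aggregation window", call. = FALSE)
  if (i1 == i0) stop("aggregation window must span at least 2 months",
                     call. = FALSE)
  n <- i1 - i0 + 1L
  counts <- integer(n)
  dropped <- 0L
  if (nrow(records)) {
    idx <- ym_index(date_ym(records$priority_date)) - i0 + 1L
    inside <- idx >= 1L & idx <= n
    dropped <- sum(!inside)
    tab <- tabulate(idx[inside], nbins = n)
    counts <- as.integer(tab)
  }
  if (is.null(taxon)) {
    tx <- unique(records$taxon)
    tx <- tx[!is.na(tx)]
    taxon <- if (length(tx) == 1) tx else NA_character_
  }
  out <- monthly_counts(counts, window[1], taxon)
  attr(out, "dropped") <- dropped
  out
}

#' Read or write a count series as CSV
#'
#' Two columns: `month` (`YYYY-MM`) and `count`.
#'
#' @param series A [monthly_counts()] object.
#' @param path File path.
#' @param taxon Taxon tag applied on read.
#' @return `read_series()` returns a `monthly_counts`; `write_series()`
#'   returns `path` invisibly.
#' @export
write_series <- function(series, path) {
  df <- data.frame(month = series_months(series), count = series$counts)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path, taxon = NA_character_) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c("character", "integer"))
  idx <- ym_index(df$month)
  if (any(diff(idx) != 1L)) stop("series months are not contiguous",
                                 call. = FALSE)
  monthly_counts(df$count, df$month[1], taxon)
}
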