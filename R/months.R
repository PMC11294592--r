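## Year-month arithmetic. A "ym" is the string "YYYY-MM"; internally months
## are mapped to an integer index (12*year + month - 1) so that consecutive
## months differ by exactly 1 regardless of year boundaries.

ym_index <- function(ym) {
  ok <- grepl("^\\d{4}-(0[1-9]|1[0-2])$", ym)
  if (!all(ok)) {
    stop("invalid year-month value(s): ",
         paste(unique(ym[!ok]), collapse = ", "), call. = FALSE)
  }
  year <- as.integer(substr(ym, 1L, 4L))
  mon <- as.integer(substr(ym, 6L, 7L))
  12L * year + mon - 1L
}

ym_label <- function(index) {
  index <- as.integer(index)
  sprintf("%04d-%02d", index %/% 12L, index %% 12L + 1L)
}

ym_add <- function(ym, k) ym_label(ym_index(ym) + as.integer(k))

ym_diff <- function(a, b) ym_index(a) - ym_index(b)

ym_seq <- function(from, to) {
  i <- ym_index(from)
  j <- ym_index(to)
  if (j < i) stop("empty year-month sequence: ", from, " > ", to, call. = FALSE)
  ym_label(seq.int(i, j))
}

## Month of a Date (or a parseable "YYYY-MM-DD" string).
date_ym <- function(date) format(as.Date(date), "%Y-%m")

## Strict ISO date parser: rejects impossible calendar dates such as
## "2020-13-01" or "2019-02-30" (as.Date alone would return NA or roll over).
parse_iso_date <- function(x) {
  out <- rep(as.Date(NA), length(x))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  d <- as.Date(x[ok], format = "%Y-%m-%d")
  # round-trip check catches rolled-over components
  ok2 <- !is.na(d) & format(d, "%Y-%m-%d") == x[ok]
  d[!ok2] <- NA
  out[ok] <- d
  out
}
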