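## Patent records are held as a plain data.frame with one row per filed
## patent and two list-columns (applicants, matched_terms). This mirrors the
## JSONL interchange layout one-to-one.

RECORD_FIELDS <- c("record_id", "title", "abstract", "priority_date",
                   "jurisdiction", "applicants", "taxon", "matched_terms")

#' Construct a patent-record table
#'
#' Builds the canonical record data.frame used throughout the package: one
#' row per filed patent, with the priority date (date of first filing) as
#' the event timestamp.
#'
#' @param record_id Character vector of unique, non-empty identifiers.
#' @param title,abstract Character vectors of patent text.
#' @param priority_date `Date` vector (or ISO `"YYYY-MM-DD"` strings).
#' @param jurisdiction Character vector of jurisdiction codes.
#' @param applicants List of character vectors (may be empty), recycled if
#'   a single value is given.
#' @param taxon Character vector tagging the searched taxon.
#' @param matched_terms List of character vectors of search terms matched so
#'   far; filled by [filter_by_keywords()].
#' @return A `data.frame` with class `patent_records`.
#' @export
patent_records <- function(record_id, title, abstract, priority_date,
                           jurisdiction = "XX", applicants = list(character()),
                           taxon = NA_character_,
                           matched_terms = list(character())) {
  n <- length(record_id)
  df <- data.frame(record_id = as.character(record_id),
                   title = rep_len(as.character(title), n),
                   abstract = rep_len(as.character(abstract), n),
                   priority_date = rep_len(as.Date(priority_date), n),
                   jurisdiction = rep_len(as.character(jurisdiction), n),
                   taxon = rep_len(as.character(taxon), n),
                   stringsAsFactors = FALSE)
  if (!is.list(applicants) || length(applicants) == 0) applicants <- list(character())
  if (!is.list(matched_terms) || length(matched_terms) == 0) matched_terms <- list(character())
  df$applicants <- rep_len(applicants, n)
  df$matched_terms <- rep_len(matched_terms, n)
  df <- df[, RECORD_FIELDS]
  class(df) <- c("patent_records", "data.frame")
  validate_records(df)
  df
}

empty_records <- function() {
  patent_records(character(), character(), character(),
                 as.Date(character()), character())[0, ]
}

#' Validate a patent-record table
#'
#' Checks the structural invariants: required columns present, non-empty
#' unique identifiers, parseable priority dates.
#'
#' @param records A record table as returned by [patent_records()].
#' @return `records`, invisibly; errors on violation.
#' @export
validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(RECORD_FIELDS, names(records))
  if (length(missing_cols)) {
    stop("record table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(records)) {
    if (anyNA(records$record_id) || any(!nzchar(records$record_id))) {
      stop("record_id must be non-empty", call. = FALSE)
    }
    if (anyDuplicated(records$record_id)) {
      stop("duplicate record_id values; run deduplicate_records() first",
           call. = FALSE)
    }
    if (anyNA(records$priority_date)) {
      stop("unparseable priority_date values", call. = FALSE)
    }
  }
  invisible(records)
}

#' Read patent records from JSONL or CSV
#'
#' Malformed rows (missing required fields, invalid or out-of-window dates,
#' unparseable JSON) are excluded from the output and collected in an error
#' report with their line numbers; they are never dropped silently.
#'
#' @param path Path to the input file.
#' @param format `"jsonl"` (one JSON object per line) or `"csv"`
#'   (`applicants`/`matched_terms` pipe-delimited).
#' @param date_window Length-2 `Date` (or ISO string) vector; records with a
#'   priority date outside the closed window are reported as errors. Default
#'   1970-01-01 to 2020-12-31, the study window.
#' @return A `patent_records` data.frame. The error report (a data.frame with
#'   columns `line`, `message`) is attached as attribute `"errors"` and
#'   retrievable with [record_errors()].
#' @export
read_records <- function(path, format = c("jsonl", "csv"),
                         date_window = as.Date(c("1970-01-01", "2020-12-31"))) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  date_window <- as.Date(date_window)
  errors <- list()
  note <- function(line, msg) errors[[length(errors) + 1L]] <<-
    data.frame(line = line, message = msg, stringsAsFactors = FALSE)

  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines_keep <- which(nzchar(trimws(lines)))
    rows <- vector("list", length(lines_keep))
    for (i in seq_along(lines_keep)) {
      ln <- lines_keep[i]
      obj <- tryCatch(jsonlite::fromJSON(lines[ln], simplifyVector = TRUE),
                      error = function(e) NULL)
      if (is.null(obj) || !is.list(obj)) {
        note(ln, "unparseable JSON object")
        next
      }
      rows[[i]] <- c(obj, list(.line = ln))
    }
    rows <- Filter(Negate(is.null), rows)
  } else {
    raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                    encoding = "UTF-8")
    rows <- lapply(seq_len(nrow(raw)), function(i) {
      obj <- as.list(raw[i, , drop = FALSE])
      obj$applicants <- strsplit(obj$applicants %||% "", "|", fixed = TRUE)[[1]]
      obj$matched_terms <- strsplit(obj$matched_terms %||% "", "|", fixed = TRUE)[[1]]
      c(obj, list(.line = i + 1L))  # header is line 1
    })
  }

  kept <- list()
  for (obj in rows) {
    ln <- obj$.line
    miss <- setdiff(c("record_id", "title", "abstract", "priority_date"),
                    names(obj)[!vapply(obj, function(x)
                      length(x) == 0 || (length(x) == 1 && is.na(x)), logical(1))])
    if (length(miss)) {
      note(ln, paste("missing required field(s):", paste(miss, collapse = ", ")))
      next
    }
    d <- parse_iso_date(as.character(obj$priority_date))
    if (is.na(d)) {
      note(ln, paste0("invalid priority_date: ", obj$priority_date))
      next
    }
    if (d < date_window[1] || d > date_window[2]) {
      note(ln, paste0("priority_date ", format(d), " outside window ",
                      format(date_window[1]), "..", format(date_window[2])))
      next
    }
    kept[[length(kept) + 1L]] <- list(
      record_id = as.character(obj$record_id),
      title = as.character(obj$title),
      abstract = as.character(obj$abstract),
      priority_date = d,
      jurisdiction = as.character(obj$jurisdiction %||% "XX"),
      applicants = as.character(obj$applicants %||% character()),
      taxon = as.character(obj$taxon %||% NA_character_),
      matched_terms = as.character(obj$matched_terms %||% character()))
  }

  err_df <- if (length(errors)) do.call(rbind, errors) else
    data.frame(line = integer(), message = character(), stringsAsFactors = FALSE)

  if (!length(kept)) {
    out <- empty_records()
  } else {
    ids <- vapply(kept, `[[`, "", "record_id")
    if (anyDuplicated(ids)) {
      # defer uniqueness to deduplicate_records(); build without validation
      out <- build_records_unchecked(kept)
    } else {
      out <- patent_records(
        record_id = ids,
        title = vapply(kept, `[[`, "", "title"),
        abstract = vapply(kept, `[[`, "", "abstract"),
        priority_date = as.Date(vapply(kept, function(r)
          format(r$priority_date), "")),
        jurisdiction = vapply(kept, `[[`, "", "jurisdiction"),
        applicants = lapply(kept, `[[`, "applicants"),
        taxon = vapply(kept, `[[`, "", "taxon"),
        matched_terms = lapply(kept, `[[`, "matched_terms"))
    }
  }
  attr(out, "errors") <- err_df
  out
}

build_records_unchecked <- function(kept) {
  df <- data.frame(
    record_id = vapply(kept, `[[`, "", "record_id"),
    title = vapply(kept, `[[`, "", "title"),
    abstract = vapply(kept, `[[`, "", "abstract"),
    priority_date = as.Date(vapply(kept, function(r) format(r$priority_date), "")),
    jurisdiction = vapply(kept, `[[`, "", "jurisdiction"),
    taxon = vapply(kept, `[[`, "", "taxon"),
    stringsAsFactors = FALSE)
  df$applicants <- lapply(kept, `[[`, "applicants")
  df$matched_terms <- lapply(kept, `[[`, "matched_terms")
  df <- df[, RECORD_FIELDS]
  class(df) <- c("patent_records", "data.frame")
  df
}

#' @rdname read_records
#' @param records A record table returned by [read_records()].
#' @export
record_errors <- function(records) {
  attr(records, "errors") %||%
    data.frame(line = integer(), message = character())
}

#' Write patent records to JSONL or CSV
#'
#' @inheritParams read_records
#' @param records A `patent_records` data.frame.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(records)), function(i) {
      jsonlite::toJSON(list(
        record_id = records$record_id[i],
        title = records$title[i],
        abstract = records$abstract[i],
        priority_date = format(records$priority_date[i], "%Y-%m-%d"),
        jurisdiction = records$jurisdiction[i],
        applicants = records$applicants[[i]],
        taxon = records$taxon[i],
        matched_terms = records$matched_terms[[i]]),
        auto_unbox = TRUE, null = "null", na = "null")
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    flat <- data.frame(
      record_id = records$record_id, title = records$title,
      abstract = records$abstract,
      priority_date = format(records$priority_date, "%Y-%m-%d"),
      jurisdiction = records$jurisdiction,
      applicants = vapply(records$applicants, paste, "", collapse = "|"),
      taxon = records$taxon,
      matched_terms = vapply(records$matched_terms, paste, "", collapse = "|"),
      stringsAsFactors = FALSE)
    write.csv(flat, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Remove duplicate patent records
#'
#' Among records sharing a `record_id`, the one with the earliest priority
#' date survives (ties broken by first appearance); output order otherwise
#' follows the first occurrence of each id.
#'
#' @param records A record table (duplicates allowed).
#' @return A list with elements `records` (the deduplicated table) and
#'   `removed` (integer count of dropped rows).
#' @export
deduplicate_records <- function(records) {
  if (!nrow(records)) return(list(records = records, removed = 0L))
  ord <- seq_len(nrow(records))
  # output order = first occurrence of each id; survivor per id = earliest
  # priority date, ties broken by position
  first_pos <- tapply(ord, records$record_id, min)
  id_order <- names(sort(first_pos))
  surv <- vapply(id_order, function(id) {
    idx <- ord[records$record_id == id]
    idx[order(records$priority_date[idx], idx)][1]
  }, integer(1))
  out <- records[unname(surv), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("patent_records", "data.frame")
  list(records = out, removed = nrow(records) - nrow(out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.patent_records <- function(x, ...) {
  cat(sprintf("<patent_records: %d record(s)", nrow(x)))
  if (nrow(x)) {
    cat(sprintf(", %s..%s", format(min(x$priority_date)),
                format(max(x$priority_date))))
    tx <- unique(x$taxon)
    tx <- tx[!is.na(tx)]
    if (length(tx)) cat(", taxa: ", paste(tx, collapse = ", "), sep = "")
  }
  cat(">\n")
  ne <- nrow(record_errors(x))
  if (ne) cat(sprintf("  (%d malformed input row(s) reported; see record_errors())\n", ne))
  invisible(x)
}
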