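#' Keyword specification for one taxon
#'
#' An include/exclude term list in the style of a patent search refinement
#' table: a record is relevant iff at least one include term matches and no
#' exclude term matches (exclusion overrides inclusion; e.g. "pangolin" is
#' also the name of a fruit-fly gene, so pangolin searches exclude
#' "drosophila").
#'
#' @param taxon Taxon name the specification belongs to.
#' @param include_terms Non-empty character vector of include terms.
#' @param exclude_terms Character vector of exclude ("NOT") terms, possibly
#'   empty. Must be disjoint from the include terms after normalization
#'   (lowercasing and whitespace collapsing).
#' @return A `keyword_spec` object.
#' @export
keyword_spec <- function(taxon, include_terms, exclude_terms = character()) {
  include_terms <- norm_term(include_terms)
  exclude_terms <- norm_term(exclude_terms)
  if (!length(include_terms) || any(!nzchar(include_terms))) {
    stop("include_terms must be a non-empty list of non-empty terms",
         call. = FALSE)
  }
  overlap <- intersect(include_terms, exclude_terms)
  if (length(overlap)) {
    stop("include and exclude terms overlap after normalization: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  structure(list(taxon = as.character(taxon),
                 include_terms = unique(include_terms),
                 exclude_terms = unique(exclude_terms)),
            class = "keyword_spec")
}

norm_term <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("\\s+", " ", x)
}

#' @export
print.keyword_spec <- function(x, ...) {
  cat(sprintf("<keyword_spec '%s': %d include, %d exclude term(s)>\n",
              x$taxon, length(x$include_terms), length(x$exclude_terms)))
  invisible(x)
}

## One compiled matcher per term. Latin-script terms match on word
## boundaries (lookarounds, so phrases and terms with punctuation work);
## terms containing non-ASCII characters (pinyin with diacritics, CJK)
## match as literal substrings.
term_matcher <- function(term) {
  term <- norm_term(term)
  if (grepl("[^\\x01-\\x7f]", term, perl = TRUE)) {
    list(term = term, fixed = TRUE, pattern = term)
  } else {
    esc <- gsub("([][{}()+*^$|\\\\?.#])", "\\\\\\1", term)
    esc <- gsub(" ", "\\\\s+", esc, fixed = FALSE)
    list(term = term, fixed = FALSE,
         pattern = paste0("(?<![[:alnum:]])", esc, "(?![[:alnum:]])"))
  }
}

term_hits <- function(text_lower, matcher) {
  if (matcher$fixed) grepl(matcher$pattern, text_lower, fixed = TRUE)
  else grepl(matcher$pattern, text_lower, perl = TRUE)
}

#' Filter patent records by include/exclude keywords
#'
#' A record is kept iff at least one include term matches the searched
#' fields and no exclude term matches anywhere in them. Matching is
#' case-insensitive; multi-word terms match as contiguous phrases.
#'
#' @param records A `patent_records` data.frame.
#' @param spec A [keyword_spec()].
#' @param fields Character subset of `c("title", "abstract")` to search.
#' @return A list with `kept` and `excluded` record tables; `matched_terms`
#'   is populated on the kept records with the include terms that matched.
#' @export
filter_by_keywords <- function(records, spec,
                               fields = c("title", "abstract")) {
  stopifnot(inherits(spec, "keyword_spec"))
  fields <- match.arg(fields, several.ok = TRUE)
  if (!nrow(records)) return(list(kept = records, excluded = records))
  text <- tolower(do.call(paste, c(unname(as.list(
    records[, fields, drop = FALSE])), sep = " \u241e ")))
  inc <- lapply(spec$include_terms, term_matcher)
  exc <- lapply(spec$exclude_terms, term_matcher)
  inc_hits <- vapply(inc, function(m) term_hits(text, m),
                     logical(nrow(records)))
  inc_hits <- matrix(inc_hits, nrow = nrow(records))
  any_inc <- rowSums(inc_hits) > 0
  any_exc <- if (length(exc)) {
    rowSums(matrix(vapply(exc, function(m) term_hits(text, m),
                          logical(nrow(records))),
                   nrow = nrow(records))) > 0
  } else rep(FALSE, nrow(records))
  keep <- any_inc & !any_exc
  kept <- records[keep, , drop = FALSE]
  if (nrow(kept)) {
    kept$matched_terms <- lapply(which(keep), function(i)
      spec$include_terms[inc_hits[i, ]])
  }
  excluded <- records[!keep, , drop = FALSE]
  rownames(kept) <- rownames(excluded) <- NULL
  class(kept) <- class(excluded) <- c("patent_records", "data.frame")
  list(kept = kept, excluded = excluded)
}

#' Read or write keyword specifications (YAML/JSON)
#'
#' The file maps each taxon to `include` and `exclude` term lists. A bundled
#' specification for the six study taxa ships at
#' `system.file("extdata", "keywords_six_taxa.yaml", package = "patenttrends")`.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return A named list of [keyword_spec()] objects.
#' @export
read_keyword_specs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  out <- lapply(names(raw), function(tx) {
    keyword_spec(tx,
                 include_terms = unlist(raw[[tx]]$include),
                 exclude_terms = unlist(raw[[tx]]$exclude %||% character()))
  })
  names(out) <- names(raw)
  out
}

#' @rdname read_keyword_specs
#' @param specs Named list of `keyword_spec` objects.
#' @export
write_keyword_specs <- function(specs, path) {
  out <- lapply(specs, function(s)
    list(include = as.list(s$include_terms),
         exclude = as.list(s$exclude_terms)))
  names(out) <- vapply(specs, `[[`, "", "taxon")
  yaml::write_yaml(out, path)
  invisible(path)
}
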