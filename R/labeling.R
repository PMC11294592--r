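#' Build a thematic codebook from a topic model
#'
#' Per label, keywords are the union of the top five non-generic terms of
#' each LDA topic mapped to that label and the configured standard terms
#' (e.g. "disorders" or "pain" under medicine). Duplicates are collapsed
#' with the LDA-derived provenance winning.
#'
#' @param model An `lda_model`.
#' @param label_map Named vector/list mapping topic index (as character or
#'   integer position) to a label; every topic to be used must be covered.
#' @param standard_terms Named list of per-label standard term vectors (may
#'   omit labels).
#' @param generic_stoplist Terms never admitted as keywords (see
#'   [generic_terms()]).
#' @param n_terms LDA terms taken per topic (default 5).
#' @return A `topic_codebook`: list with `labels`, `keywords` (per-label
#'   character vectors) and `provenance` (per-label vectors of
#'   `"lda_top_term"` / `"standard_term"` / `"expansion_iteration_k"`).
#' @export
build_codebook <- function(model, label_map, standard_terms = list(),
                           generic_stoplist = character(), n_terms = 5) {
  label_map <- unlist(label_map)
  if (is.null(names(label_map))) {
    names(label_map) <- as.character(seq_along(label_map))
  }
  labels <- unique(c(unname(label_map), names(standard_terms)))
  keywords <- provenance <- setNames(vector("list", length(labels)), labels)
  for (topic_id in names(label_map)) {
    lab <- label_map[[topic_id]]
    terms <- top_terms(model, as.integer(topic_id), n = n_terms,
                       generic_stoplist = generic_stoplist)
    keywords[[lab]] <- c(keywords[[lab]], terms)
    provenance[[lab]] <- c(provenance[[lab]],
                           rep("lda_top_term", length(terms)))
  }
  for (lab in names(standard_terms)) {
    terms <- norm_term(unlist(standard_terms[[lab]]))
    keywords[[lab]] <- c(keywords[[lab]], terms)
    provenance[[lab]] <- c(provenance[[lab]],
                           rep("standard_term", length(terms)))
  }
  for (lab in labels) {
    kw <- norm_term(keywords[[lab]])
    first <- !duplicated(kw)  # earlier source wins: lda terms are added first
    keywords[[lab]] <- kw[first]
    provenance[[lab]] <- provenance[[lab]][first]
    if (!length(keywords[[lab]])) {
      stop("label '", lab, "' has no keywords", call. = FALSE)
    }
  }
  new_codebook(labels, keywords, provenance)
}

new_codebook <- function(labels, keywords, provenance) {
  stopifnot(all(lengths(keywords[labels]) >= 1))
  structure(list(labels = labels,
                 keywords = keywords[labels],
                 provenance = provenance[labels]),
            class = "topic_codebook")
}

#' @export
print.topic_codebook <- function(x, ...) {
  cat(sprintf("<topic_codebook: %d label(s)>\n", length(x$labels)))
  for (lab in x$labels) {
    cat(sprintf("  %s (%d): %s%s\n", lab, length(x$keywords[[lab]]),
                paste(head(x$keywords[[lab]], 6), collapse = ", "),
                if (length(x$keywords[[lab]]) > 6) ", ..." else ""))
  }
  invisible(x)
}

#' Read or write a codebook (YAML)
#'
#' Layout: each label maps to `keywords` and parallel `provenance` lists. A
#' bundled general-purpose codebook (modeled on economic-botany use
#' categories; a synthetic stand-in, not the external standard) ships at
#' `system.file("extdata", "codebook_default.yaml", package = "patenttrends")`.
#'
#' @param path File path.
#' @return `read_codebook()` returns a `topic_codebook`.
#' @export
read_codebook <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  labels <- names(raw)
  keywords <- lapply(raw, function(e) as.character(unlist(e$keywords)))
  provenance <- lapply(labels, function(lab) {
    pv <- as.character(unlist(raw[[lab]]$provenance))
    if (length(pv) != length(keywords[[lab]])) {
      pv <- rep("standard_term", length(keywords[[lab]]))
    }
    pv
  })
  names(provenance) <- labels
  new_codebook(labels, keywords, provenance)
}

#' @rdname read_codebook
#' @param codebook A `topic_codebook`.
#' @export
write_codebook <- function(codebook, path) {
  out <- lapply(codebook$labels, function(lab)
    list(keywords = as.list(codebook$keywords[[lab]]),
         provenance = as.list(codebook$provenance[[lab]])))
  names(out) <- codebook$labels
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Label patent records against a codebook
#'
#' A record receives label L iff any keyword of L matches its title or
#' abstract (same matching rules as [filter_by_keywords()]: word-boundary,
#' case-insensitive, phrases contiguous). Labels are non-exclusive. Every
#' assignment is backed by a stored (record, label, keyword) match triple.
#'
#' @param records A `patent_records` data.frame.
#' @param codebook A `topic_codebook`.
#' @param fields Fields searched (default title + abstract).
#' @return A `labeled_corpus`: `labels_by_record` (record_id -> character
#'   vector of labels), `coverage` (fraction of records with >= 1 label),
#'   `uncovered` (ids without any label), `matches` (data.frame of
#'   record_id, label, keyword), `iteration_log`.
#' @export
label_records <- function(records, codebook,
                          fields = c("title", "abstract")) {
  stopifnot(inherits(codebook, "topic_codebook"))
  text <- tolower(do.call(paste, c(unname(as.list(
    records[, fields, drop = FALSE])), sep = " \u241e ")))
  matches <- list()
  labels_by_record <- setNames(vector("list", nrow(records)),
                               records$record_id)
  for (lab in codebook$labels) {
    for (kw in codebook$keywords[[lab]]) {
      hit <- term_hits(text, term_matcher(kw))
      if (any(hit)) {
        matches[[length(matches) + 1L]] <- data.frame(
          record_id = records$record_id[hit], label = lab, keyword = kw,
          stringsAsFactors = FALSE)
      }
    }
  }
  match_df <- if (length(matches)) do.call(rbind, matches) else
    data.frame(record_id = character(), label = character(),
               keyword = character(), stringsAsFactors = FALSE)
  for (id in unique(match_df$record_id)) {
    labels_by_record[[id]] <- sort(unique(
      match_df$label[match_df$record_id == id]))
  }
  covered <- lengths(labels_by_record) > 0
  structure(list(labels_by_record = labels_by_record,
                 coverage = if (nrow(records)) mean(covered) else NA_real_,
                 uncovered = records$record_id[!covered],
                 matches = match_df,
                 iteration_log = data.frame(iteration = integer(),
                                            keywords_added = integer(),
                                            coverage = numeric())),
            class = "labeled_corpus")
}

#' @export
print.labeled_corpus <- function(x, ...) {
  cat(sprintf("<labeled_corpus: %d record(s), coverage %.1f%%, %d assignment(s)>\n",
              length(x$labels_by_record), 100 * x$coverage,
              nrow(x$matches)))
  invisible(x)
}

#' Automated codebook-expansion policy from an LDA fit
#'
#' The default stand-in for the manual review round: for each uncovered
#' record, its most frequent non-generic abstract term is proposed as a new
#' keyword under the label of the record's highest-probability LDA topic.
#' Returns a policy function usable with [iterate_labeling()]; supplying a
#' different function is the review hook through which human keyword edits
#' enter.
#'
#' @param model An `lda_model` fitted on the same records.
#' @param corpus The `tokenized_corpus` behind `model`.
#' @param label_map Topic-to-label map as in [build_codebook()].
#' @param generic_stoplist Terms never proposed.
#' @return A function `(uncovered_records, codebook)` returning a data.frame
#'   with columns `label`, `keyword`.
#' @export
lda_expansion_policy <- function(model, corpus, label_map,
                                 generic_stoplist = character()) {
  label_map <- unlist(label_map)
  if (is.null(names(label_map))) {
    names(label_map) <- as.character(seq_along(label_map))
  }
  generic_stoplist <- tolower(generic_stoplist)
  function(uncovered_records, codebook) {
    props <- list()
    for (i in seq_len(nrow(uncovered_records))) {
      id <- uncovered_records$record_id[i]
      di <- match(id, corpus$doc_ids)
      if (is.na(di)) next
      toks <- corpus$vocabulary[corpus$documents[[di]]]
      toks <- toks[!(toks %in% generic_stoplist)]
      existing <- unlist(codebook$keywords)
      toks <- toks[!(toks %in% existing)]
      if (!length(toks)) next
      tt <- sort(table(toks), decreasing = TRUE)
      ri <- match(id, rownames(model$doc_topic))
      if (is.na(ri)) next
      top_topic <- which.max(model$doc_topic[ri, ])
      lab <- label_map[[as.character(top_topic)]]
      if (is.null(lab)) next
      props[[length(props) + 1L]] <- data.frame(
        label = lab, keyword = names(tt)[1], stringsAsFactors = FALSE)
    }
    if (!length(props)) {
      return(data.frame(label = character(), keyword = character()))
    }
    unique(do.call(rbind, props))
  }
}

#' Iterate labeling to full coverage
#'
#' Repeats label -> expand until every record carries at least one label or
#' `max_iterations` is reached: after each labeling pass, the expansion
#' policy proposes new (label, keyword) pairs for the uncovered records,
#' which are appended to the codebook with provenance
#' `"expansion_iteration_k"`. Coverage is monotone non-decreasing because
#' keywords are only ever added.
#'
#' @inheritParams label_records
#' @param expansion_policy Function `(uncovered_records, codebook)` returning
#'   a data.frame with columns `label`, `keyword` (see
#'   [lda_expansion_policy()]).
#' @param max_iterations Maximum labeling passes (>= 1).
#' @return List with `labeled` (the final `labeled_corpus`, its
#'   `iteration_log` filled), `codebook` (expanded), and `status`:
#'   `"converged"` (coverage 1), `"stalled"` (policy added nothing while
#'   uncovered records remain) or `"max_iterations"`.
#' @export
iterate_labeling <- function(records, codebook, expansion_policy,
                             max_iterations = 10,
                             fields = c("title", "abstract")) {
  stopifnot(max_iterations >= 1)
  log <- data.frame(iteration = integer(), keywords_added = integer(),
                    coverage = numeric())
  status <- "max_iterations"
  labeled <- NULL
  for (it in seq_len(max_iterations)) {
    labeled <- label_records(records, codebook, fields = fields)
    added <- 0L
    if (isTRUE(labeled$coverage >= 1)) {
      log <- rbind(log, data.frame(iteration = it, keywords_added = 0L,
                                   coverage = labeled$coverage))
      status <- "converged"
      break
    }
    if (it < max_iterations) {
      uncovered <- records[records$record_id %in% labeled$uncovered, ,
                           drop = FALSE]
      proposals <- expansion_policy(uncovered, codebook)
      if (!is.null(proposals) && nrow(proposals)) {
        for (r in seq_len(nrow(proposals))) {
          lab <- proposals$label[r]
          kw <- norm_term(proposals$keyword[r])
          if (!(lab %in% codebook$labels)) {
            codebook$labels <- c(codebook$labels, lab)
            codebook$keywords[[lab]] <- character()
            codebook$provenance[[lab]] <- character()
          }
          if (!(kw %in% codebook$keywords[[lab]])) {
            codebook$keywords[[lab]] <- c(codebook$keywords[[lab]], kw)
            codebook$provenance[[lab]] <-
              c(codebook$provenance[[lab]],
                sprintf("expansion_iteration_%d", it))
            added <- added + 1L
          }
        }
      }
      if (added == 0L) {
        log <- rbind(log, data.frame(iteration = it, keywords_added = 0L,
                                     coverage = labeled$coverage))
        status <- "stalled"
        break
      }
    }
    log <- rbind(log, data.frame(iteration = it, keywords_added = added,
                                 coverage = labeled$coverage))
  }
  if (status == "max_iterations") {
    # re-label once more so late additions from the final pass count
    labeled <- label_records(records, codebook, fields = fields)
    if (isTRUE(labeled$coverage >= 1)) status <- "converged"
  }
  labeled$iteration_log <- log
  list(labeled = labeled, codebook = codebook, status = status)
}

#' Cumulative label proportions over time
#'
#' For each month in the window, the proportion of each label among all
#' label assignments made to records filed up to and including that month.
#' The denominator is the total number of assignments, not of records: a
#' record with two labels contributes twice, mirroring a diversification
#' curve where topics are not mutually exclusive. Rows sum to 1 from the
#' first month with any labeled record (earlier rows are all zero).
#'
#' @param labeled A `labeled_corpus` from [label_records()] or
#'   [iterate_labeling()].
#' @param records The `patent_records` the labels refer to.
#' @param window Length-2 `c(from, to)` month labels (`"YYYY-MM"`).
#' @return Numeric matrix, months x labels; each label's cumulative count is
#'   attached as attribute `"cumulative_counts"`. Empty (0-row) with a
#'   warning if no labeled record falls in the window.
#' @export
cumulative_label_proportions <- function(labeled, records,
                                         window = c("1970-01", "2020-12")) {
  months <- ym_seq(window[1], window[2])
  m_idx <- ym_index(months)
  rec_month <- ym_index(date_ym(records$priority_date))
  names(rec_month) <- records$record_id
  mm <- labeled$matches
  mm <- mm[mm$record_id %in% records$record_id, , drop = FALSE]
  assign_df <- unique(mm[, c("record_id", "label")])
  if (!nrow(assign_df)) {
    warning("no labeled records in window", call. = FALSE)
    return(matrix(numeric(), nrow = 0, ncol = 0))
  }
  assign_month <- rec_month[assign_df$record_id]
  labels <- sort(unique(assign_df$label))
  counts <- matrix(0, length(months), length(labels),
                   dimnames = list(months, labels))
  for (r in seq_len(nrow(assign_df))) {
    j <- match(assign_df$label[r], labels)
    first <- assign_month[r] - m_idx[1] + 1L
    if (first <= length(months)) {
      counts[max(1L, first):length(months), j] <-
        counts[max(1L, first):length(months), j] + 1L
    }
  }
  totals <- rowSums(counts)
  props <- counts / ifelse(totals > 0, totals, 1)
  if (all(totals == 0)) {
    warning("no labeled records in window", call. = FALSE)
    return(matrix(numeric(), nrow = 0, ncol = 0))
  }
  attr(props, "cumulative_counts") <- counts
  props
}
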