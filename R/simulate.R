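#' Configuration for a simulated monthly count series
#'
#' Defines a negative-binomial filing process with an optional abrupt rate
#' shift: months before `changepoint_month` are drawn NB(`mu_early`,
#' `phi_early`), months at and after it NB(`mu_late`, `phi_late`). Defaults
#' are the canonical test conditions used throughout the package: a
#' 120-month series jumping from 2 to 10 filings per month at month 60.
#'
#' @param n_months Number of months (>= 2).
#' @param changepoint_month 1-based index of the first month under the late
#'   regime, strictly inside the series (`2..n_months`), or `NULL` for no
#'   changepoint.
#' @param mu_early,mu_late Positive mean monthly counts before/after.
#' @param phi_early,phi_late Positive NB2 dispersions before/after
#'   (variance `mu + mu^2/phi`).
#' @param start_month First month label (`"YYYY-MM"`).
#' @param taxon Optional taxon tag.
#' @param seed Integer RNG seed.
#' @return A `sim_series_config` object.
#' @export
sim_series_config <- function(n_months = 120, changepoint_month = 60,
                              mu_early = 2, mu_late = 10,
                              phi_early = 1, phi_late = 1,
                              start_month = "1970-01",
                              taxon = NA_character_, seed = 1L) {
  stopifnot(n_months >= 2, mu_early > 0, mu_late > 0,
            phi_early > 0, phi_late > 0)
  if (!is.null(changepoint_month)) {
    if (changepoint_month < 2 || changepoint_month > n_months) {
      stop("changepoint_month must lie strictly inside the series (2..",
           n_months, ")", call. = FALSE)
    }
  }
  ym_index(start_month)
  structure(list(n_months = as.integer(n_months),
                 changepoint_month = if (is.null(changepoint_month)) NULL
                   else as.integer(changepoint_month),
                 mu_early = mu_early, mu_late = mu_late,
                 phi_early = phi_early, phi_late = phi_late,
                 start_month = start_month, taxon = as.character(taxon),
                 seed = as.integer(seed)),
            class = "sim_series_config")
}

#' Simulate a monthly filing-count series
#'
#' @param config A [sim_series_config()].
#' @return A [monthly_counts()] series; identical config and seed give an
#'   identical series.
#' @export
simulate_count_series <- function(config) {
  stopifnot(inherits(config, "sim_series_config"))
  set.seed(config$seed)
  n <- config$n_months
  cp <- config$changepoint_month
  if (is.null(cp)) {
    counts <- rnbinom(n, size = config$phi_early, mu = config$mu_early)
  } else {
    counts <- c(rnbinom(cp - 1L, size = config$phi_early, mu = config$mu_early),
                rnbinom(n - cp + 1L, size = config$phi_late, mu = config$mu_late))
  }
  monthly_counts(counts, config$start_month, config$taxon)
}

#' Configuration for a synthetic patent corpus
#'
#' Drives [simulate_patent_corpus()]: per-taxon filing-count series with
#' planted changepoints, abstracts generated from a planted LDA process over
#' a pseudo-word vocabulary, taxon include keywords injected into every
#' record, and a configurable fraction of decoy records carrying an
#' exclusion term (emulating confounders such as the fruit-fly gene that
#' shares the pangolin's name).
#'
#' @param series Named list of [sim_series_config()] objects, one per taxon.
#' @param n_topics_true Number of planted topics (>= 1).
#' @param doc_topic_concentration Dirichlet concentration of per-document
#'   topic weights (default 0.2: documents are mostly single-topic, as
#'   short patent abstracts are).
#' @param topic_word_concentration Dirichlet concentration of topic-word
#'   rows when `disjoint_topics = FALSE` (default 0.05).
#' @param vocabulary_size Pseudo-word vocabulary size (>= `n_topics_true`).
#' @param doc_length_mean Mean abstract length in tokens (Poisson).
#' @param taxon_keywords Named list of include terms per taxon; defaults to
#'   each taxon's own name.
#' @param decoy_terms Exclusion terms available for decoy records.
#' @param decoy_fraction Fraction of records carrying a decoy term, in
#'   \[0, 1\].
#' @param disjoint_topics If `TRUE` (default) the vocabulary is partitioned
#'   equally among topics (uniform within each block), giving fully
#'   separable planted topics; if `FALSE`, topic-word rows are Dirichlet
#'   draws.
#' @param seed Integer RNG seed.
#' @return A `sim_corpus_config` object.
#' @export
sim_corpus_config <- function(series = list(pangolin = sim_series_config(taxon = "pangolin")),
                              n_topics_true = 3,
                              doc_topic_concentration = 0.2,
                              topic_word_concentration = 0.05,
                              vocabulary_size = 400,
                              doc_length_mean = 50,
                              taxon_keywords = NULL,
                              decoy_terms = "drosophila",
                              decoy_fraction = 0.1,
                              disjoint_topics = TRUE,
                              seed = 1L) {
  stopifnot(is.list(series), length(series) >= 1,
            n_topics_true >= 1,
            doc_topic_concentration > 0, topic_word_concentration > 0,
            vocabulary_size >= n_topics_true, doc_length_mean > 0,
            decoy_fraction >= 0, decoy_fraction <= 1)
  if (is.null(names(series)) || any(!nzchar(names(series)))) {
    stop("series must be a named list (one entry per taxon)", call. = FALSE)
  }
  if (is.null(taxon_keywords)) {
    taxon_keywords <- as.list(names(series))
    names(taxon_keywords) <- names(series)
  }
  stopifnot(all(names(series) %in% names(taxon_keywords)))
  structure(list(series = series,
                 n_topics_true = as.integer(n_topics_true),
                 doc_topic_concentration = doc_topic_concentration,
                 topic_word_concentration = topic_word_concentration,
                 vocabulary_size = as.integer(vocabulary_size),
                 doc_length_mean = doc_length_mean,
                 taxon_keywords = taxon_keywords,
                 decoy_terms = as.character(decoy_terms),
                 decoy_fraction = decoy_fraction,
                 disjoint_topics = isTRUE(disjoint_topics),
                 seed = as.integer(seed)),
            class = "sim_corpus_config")
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[sample.int(length(g), 1)] <- 1
  g / sum(g)
}

#' Simulate a patent corpus with planted ground truth
#'
#' Per-taxon monthly record counts follow the driving count series; each
#' abstract is a bag of pseudo-word tokens drawn from the planted
#' topic-mixture process, every record carries at least one taxon include
#' keyword, a `decoy_fraction` share additionally carries an exclusion
#' term, and priority dates fall uniformly inside each record's month.
#'
#' @param config A [sim_corpus_config()].
#' @return List with `records` (a `patent_records` data.frame) and `truth`
#'   (a `planted_truth` list: per-taxon changepoint months, the planted
#'   topic-word matrix, per-record dominant topic labels and decoy flags).
#' @export
simulate_patent_corpus <- function(config) {
  stopifnot(inherits(config, "sim_corpus_config"))
  set.seed(config$seed)
  V <- config$vocabulary_size
  K <- config$n_topics_true
  vocab <- sprintf("w%04d", seq_len(V))
  if (config$disjoint_topics) {
    topic_word <- matrix(0, K, V)
    block <- split(seq_len(V), rep(seq_len(K), length.out = V))
    for (k in seq_len(K)) topic_word[k, block[[k]]] <- 1 / length(block[[k]])
  } else {
    topic_word <- t(vapply(seq_len(K), function(k)
      rdirichlet1(rep(config$topic_word_concentration, V)), numeric(V)))
  }
  colnames(topic_word) <- vocab
  rownames(topic_word) <- paste0("topic", seq_len(K))

  all_rows <- list()
  truth_topic <- integer()
  truth_decoy <- logical()
  truth_ids <- character()
  changepoints <- list()
  for (tx in names(config$series)) {
    scfg <- config$series[[tx]]
    scfg$taxon <- tx
    keep <- intersect(names(scfg), names(formals(sim_series_config)))
    scfg <- do.call(sim_series_config, scfg[keep])
    series <- simulate_count_series(scfg)
    months <- series_months(series)
    changepoints[[tx]] <- if (is.null(scfg$changepoint_month)) NA_character_
      else months[scfg$changepoint_month]
    kw <- tolower(config$taxon_keywords[[tx]])
    idx <- 0L
    for (m in seq_along(months)) {
      cnt <- series$counts[m]
      if (cnt == 0) next
      first_day <- as.Date(paste0(months[m], "-01"))
      ndays <- as.integer(seq(first_day, by = "month", length.out = 2)[2] -
                            first_day)
      for (r in seq_len(cnt)) {
        idx <- idx + 1L
        len <- max(1L, rpois(1, config$doc_length_mean))
        theta <- rdirichlet1(rep(config$doc_topic_concentration, K))
        zs <- sample.int(K, len, replace = TRUE, prob = theta)
        tokens <- vapply(zs, function(z)
          vocab[sample.int(V, 1, prob = topic_word[z, ])], "")
        key <- kw[sample.int(length(kw), 1)]
        decoy <- runif(1) < config$decoy_fraction
        abstract <- paste(c(key, tokens,
                            if (decoy) sample(config$decoy_terms, 1)),
                          collapse = " ")
        all_rows[[length(all_rows) + 1L]] <- list(
          record_id = sprintf("%s-%05d", tx, idx),
          title = paste("preparation of", key, "product", tokens[1]),
          abstract = abstract,
          priority_date = first_day + sample.int(ndays, 1) - 1L,
          jurisdiction = sample(c("CN", "US", "EP", "KR", "JP", "RU"), 1,
                                prob = c(.5, .15, .1, .1, .1, .05)),
          taxon = tx)
        truth_topic <- c(truth_topic, which.max(tabulate(zs, nbins = K)))
        truth_decoy <- c(truth_decoy, decoy)
        truth_ids <- c(truth_ids, sprintf("%s-%05d", tx, idx))
      }
    }
  }
  records <- if (length(all_rows)) {
    patent_records(
      record_id = vapply(all_rows, `[[`, "", "record_id"),
      title = vapply(all_rows, `[[`, "", "title"),
      abstract = vapply(all_rows, `[[`, "", "abstract"),
      priority_date = as.Date(vapply(all_rows, function(r)
        format(r$priority_date), "")),
      jurisdiction = vapply(all_rows, `[[`, "", "jurisdiction"),
      taxon = vapply(all_rows, `[[`, "", "taxon"))
  } else empty_records()
  truth <- structure(list(changepoint_month = changepoints,
                          topic_word = topic_word,
                          record_topics = setNames(truth_topic, truth_ids),
                          decoy = setNames(truth_decoy, truth_ids)),
                     class = "planted_truth")
  list(records = records, truth = truth)
}

#' Write planted ground truth as JSON
#'
#' @param truth A `planted_truth` object from [simulate_patent_corpus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- list(changepoint_month = truth$changepoint_month,
              topic_word = apply(truth$topic_word, 1, function(r)
                as.list(setNames(r, colnames(truth$topic_word))),
                simplify = FALSE),
              record_topics = as.list(truth$record_topics),
              decoy = as.list(truth$decoy))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
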