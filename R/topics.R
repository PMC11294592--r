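#' Tokenize patent abstracts into a modelling corpus
#'
#' Splits abstracts on unicode word boundaries, optionally lowercases,
#' removes stopwords and terms rarer than `min_term_count` corpus-wide, and
#' drops documents left empty (reported via the `"dropped_docs"`
#' attribute).
#'
#' @param records A `patent_records` data.frame; abstracts are tokenized.
#' @param stoplist Character vector of terms to remove (see
#'   [default_stoplist()]).
#' @param min_term_count Minimum corpus-wide occurrences for a term to be
#'   kept in the vocabulary (default 2).
#' @param lowercase Lowercase before tokenizing (default `TRUE`).
#' @return A `tokenized_corpus`: list with `documents` (integer token-id
#'   vectors), `vocabulary` (id -> term), and `doc_ids` aligned to
#'   `documents`.
#' @export
preprocess <- function(records, stoplist = default_stoplist(),
                       min_term_count = 2, lowercase = TRUE) {
  texts <- records$abstract
  if (lowercase) texts <- tolower(texts)
  stoplist <- unique(tolower(stoplist))
  toks <- strsplit(texts, "[^\\p{L}\\p{N}]+", perl = TRUE)
  toks <- lapply(toks, function(t) t[nzchar(t) & !(t %in% stoplist)])
  counts <- table(unlist(toks))
  vocab <- sort(names(counts)[counts >= min_term_count])
  if (!length(vocab)) {
    stop("no terms survive preprocessing; lower min_term_count or shrink the stoplist",
         call. = FALSE)
  }
  docs <- lapply(toks, function(t) {
    ids <- match(t, vocab)
    as.integer(ids[!is.na(ids)])
  })
  keep <- lengths(docs) > 0
  if (!any(keep)) {
    stop("all documents are empty after preprocessing", call. = FALSE)
  }
  out <- structure(list(documents = docs[keep],
                        vocabulary = vocab,
                        doc_ids = records$record_id[keep]),
                   class = "tokenized_corpus")
  attr(out, "dropped_docs") <- records$record_id[!keep]
  out
}

#' @export
print.tokenized_corpus <- function(x, ...) {
  cat(sprintf("<tokenized_corpus: %d document(s), %d tokens, vocabulary %d>\n",
              length(x$documents), sum(lengths(x$documents)),
              length(x$vocabulary)))
  nd <- length(attr(x, "dropped_docs"))
  if (nd) cat(sprintf("  (%d empty document(s) dropped)\n", nd))
  invisible(x)
}

#' A small built-in English stoplist
#'
#' Function words only; domain terms are never included. Extend it per
#' corpus rather than editing it.
#'
#' @return Character vector of stopwords.
#' @export
default_stoplist <- function() {
  c("a", "an", "the", "and", "or", "but", "if", "then", "than", "so",
    "of", "in", "on", "at", "by", "for", "with", "to", "from", "into",
    "onto", "as", "is", "are", "was", "were", "be", "been", "being",
    "it", "its", "this", "that", "these", "those", "which", "who",
    "whom", "whose", "what", "when", "where", "how", "why", "not", "no",
    "nor", "can", "could", "may", "might", "will", "would", "shall",
    "should", "must", "do", "does", "did", "done", "have", "has", "had",
    "such", "each", "per", "via", "also", "any", "all", "both", "more",
    "most", "other", "some", "there", "their", "they", "them", "we",
    "our", "one", "two", "three", "said", "thereof", "wherein",
    "whereby", "comprising", "comprises", "method", "methods",
    "invention", "present", "provided", "provides", "according",
    "relates", "use", "used", "using", "same", "further", "between",
    "about", "after", "before", "during", "through", "under", "over")
}

#' LDA configuration
#'
#' @param n_topics Number of topics K (>= 2).
#' @param alpha Document-topic Dirichlet concentration; default `50 / K`.
#' @param eta Topic-word Dirichlet concentration (default 0.01).
#' @param gibbs_iterations Collapsed Gibbs sweeps (default 1000).
#' @param burn_in Sweeps regarded as transient in the log-likelihood trace
#'   (default half the sweeps); must be smaller than `gibbs_iterations`.
#' @param seed Integer RNG seed.
#' @return An `lda_config` object.
#' @export
lda_config <- function(n_topics, alpha = NULL, eta = 0.01,
                       gibbs_iterations = 1000,
                       burn_in = gibbs_iterations %/% 2, seed = 1L) {
  stopifnot(n_topics >= 2, eta > 0, gibbs_iterations >= 1,
            burn_in >= 0, burn_in < gibbs_iterations)
  # NULL alpha = "use 50/K", resolved at fit time so that topic-number
  # selection can rescale it per candidate K
  if (!is.null(alpha)) stopifnot(alpha > 0)
  structure(list(n_topics = as.integer(n_topics), alpha = alpha, eta = eta,
                 gibbs_iterations = as.integer(gibbs_iterations),
                 burn_in = as.integer(burn_in), seed = as.integer(seed)),
            class = "lda_config")
}

#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' Token-topic assignments are resampled from their collapsed conditionals;
#' the returned topic-word and document-topic distributions are the
#' Dirichlet-smoothed final-sweep count tables. Runs are reproducible for a
#' fixed corpus, configuration and seed.
#'
#' @param corpus A [preprocess()]ed `tokenized_corpus`.
#' @param config An [lda_config()]; `n_topics` must not exceed the
#'   vocabulary size.
#' @param top_n Number of top terms used for the stored coherence and
#'   exclusivity scores (default 10).
#' @param restarts Number of independently initialized Gibbs runs; the run
#'   with the highest final collapsed log joint is kept (default 1).
#'   Collapsed Gibbs can lock into local modes (e.g. one planted topic
#'   split while another is dropped), and restarts are the standard remedy.
#' @return An `lda_model`: `topic_word` (K x V, rows sum to 1), `doc_topic`
#'   (D x K, rows sum to 1), `assignments` (final token-topic labels per
#'   document), `coherence` and `exclusivity` (per topic),
#'   `log_likelihood_trace`, and `tokens_assigned` (per-sweep token totals,
#'   constant by construction).
#' @export
fit_lda <- function(corpus, config, top_n = 10, restarts = 1) {
  stopifnot(inherits(corpus, "tokenized_corpus"), inherits(config, "lda_config"),
            restarts >= 1)
  V <- length(corpus$vocabulary)
  K <- config$n_topics
  if (K > V) stop("n_topics exceeds the vocabulary size", call. = FALSE)
  if (!length(corpus$documents)) stop("empty corpus", call. = FALSE)
  doc_id <- rep.int(seq_along(corpus$documents) - 1L, lengths(corpus$documents))
  word_id <- unlist(corpus$documents) - 1L
  alpha <- config$alpha %||% (50 / K)
  fit <- NULL
  for (r in seq_len(restarts)) {
    set.seed((config$seed + 7919L * (r - 1L)) %% .Machine$integer.max)
    cand <- lda_gibbs_cpp(word_id, doc_id, length(corpus$documents), V, K,
                          alpha, config$eta, config$gibbs_iterations)
    if (is.null(fit) ||
        cand$loglik[length(cand$loglik)] > fit$loglik[length(fit$loglik)]) {
      fit <- cand
    }
  }
  topic_word <- (fit$nkw + config$eta)
  topic_word <- topic_word / rowSums(topic_word)
  colnames(topic_word) <- corpus$vocabulary
  rownames(topic_word) <- paste0("topic", seq_len(K))
  doc_topic <- (fit$ndk + alpha)
  doc_topic <- doc_topic / rowSums(doc_topic)
  rownames(doc_topic) <- corpus$doc_ids
  colnames(doc_topic) <- paste0("topic", seq_len(K))
  assignments <- split(fit$z + 1L, doc_id)
  names(assignments) <- corpus$doc_ids
  model <- structure(list(topic_word = topic_word,
                          doc_topic = doc_topic,
                          assignments = assignments,
                          log_likelihood_trace = fit$loglik,
                          tokens_assigned = fit$tokens_assigned,
                          config = config),
                     class = "lda_model")
  model$coherence <- coherence(model, corpus, top_n = top_n)
  model$exclusivity <- exclusivity(model, top_n = top_n)
  model
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model: K=%d topics, V=%d terms, %d documents>\n",
              nrow(x$topic_word), ncol(x$topic_word), nrow(x$doc_topic)))
  for (k in seq_len(nrow(x$topic_word))) {
    cat(sprintf("  topic%d: %s\n", k,
                paste(top_terms(x, k, 5), collapse = ", ")))
  }
  invisible(x)
}

#' Top terms of a topic
#'
#' Terms ranked by probability under the topic, skipping "generic" terms
#' (the supplied stoplist). If fewer than `n` non-generic terms exist, all
#' available terms are returned with attribute `"incomplete" = TRUE` and a
#' warning.
#'
#' @param model An `lda_model`.
#' @param topic Topic index (1-based).
#' @param n Number of terms wanted.
#' @param generic_stoplist Terms to skip (see [generic_terms()]).
#' @return Character vector of at most `n` terms.
#' @export
top_terms <- function(model, topic, n = 5, generic_stoplist = character()) {
  stopifnot(topic >= 1, topic <= nrow(model$topic_word))
  p <- model$topic_word[topic, ]
  terms <- colnames(model$topic_word)[order(p, decreasing = TRUE)]
  terms <- terms[!(terms %in% tolower(generic_stoplist))]
  if (length(terms) < n) {
    warning("only ", length(terms), " non-generic term(s) available",
            call. = FALSE)
    attr(terms, "incomplete") <- TRUE
    return(terms)
  }
  terms[seq_len(n)]
}

#' Corpus-generic terms by document frequency
#'
#' Terms appearing in more than `max_doc_frac` of documents are treated as
#' generic for codebook construction and top-term reporting.
#'
#' @param corpus A `tokenized_corpus`.
#' @param max_doc_frac Document-frequency threshold (default 0.5).
#' @return Character vector of generic terms.
#' @export
generic_terms <- function(corpus, max_doc_frac = 0.5) {
  df <- doc_freq(corpus)
  corpus$vocabulary[df > max_doc_frac * length(corpus$documents)]
}

doc_freq <- function(corpus) {
  tabulate(unlist(lapply(corpus$documents, unique)),
           nbins = length(corpus$vocabulary))
}

#' Per-topic semantic coherence (UMass)
#'
#' For the `top_n` highest-probability terms of each topic, sums over
#' ordered pairs `log((D(w_i, w_j) + 1) / D(w_j))`, where `D` counts
#' documents containing the term(s) and `w_j` outranks `w_i`. Higher is more
#' coherent; topics whose top terms co-occur in documents score higher.
#' Absent terms contribute through the +1 smoothing, never a division by
#' zero.
#'
#' @param model An `lda_model`.
#' @param corpus The `tokenized_corpus` the model was fitted to.
#' @param top_n Number of top terms scored per topic (>= 2, default 10).
#' @return Numeric vector, one score per topic.
#' @export
coherence <- function(model, corpus, top_n = 10) {
  stopifnot(top_n >= 2)
  df <- doc_freq(corpus)
  doc_sets <- lapply(corpus$documents, unique)
  K <- nrow(model$topic_word)
  vapply(seq_len(K), function(k) {
    terms <- top_terms(model, k, n = min(top_n, ncol(model$topic_word)))
    ids <- match(terms, corpus$vocabulary)
    s <- 0
    for (i in seq_along(ids)[-1]) {
      for (j in seq_len(i - 1)) {
        co <- sum(vapply(doc_sets, function(d)
          (ids[i] %in% d) && (ids[j] %in% d), logical(1)))
        s <- s + log((co + 1) / max(df[ids[j]], 1))
      }
    }
    s
  }, numeric(1))
}

#' Per-topic exclusivity
#'
#' Mean, over a topic's `top_n` terms, of the topic's share of the term's
#' total probability across topics, `P(w|k) / sum_k' P(w|k')`. Lies in
#' (0, 1]; equals 1 exactly when the top terms carry no mass under any
#' other topic, and `1/K` when all topics are identical.
#'
#' @inheritParams coherence
#' @return Numeric vector, one score per topic.
#' @export
exclusivity <- function(model, top_n = 10) {
  stopifnot(top_n >= 1)
  tw <- model$topic_word
  colsum <- colSums(tw)
  K <- nrow(tw)
  vapply(seq_len(K), function(k) {
    terms <- top_terms(model, k, n = min(top_n, ncol(tw)))
    mean(tw[k, terms] / colsum[terms])
  }, numeric(1))
}

#' Choose the number of topics by coherence/exclusivity balance
#'
#' Fits the model at each candidate K, computes mean semantic coherence and
#' mean exclusivity, min-max normalizes each across the candidate grid, and
#' picks the K maximizing their unweighted mean (ties go to the smaller K).
#' The full score table is returned for human review.
#'
#' @param corpus A `tokenized_corpus`.
#' @param k_grid Integer vector of candidate topic numbers.
#' @param config Template [lda_config()]; its `n_topics` is replaced by each
#'   candidate and per-K seeds are derived from its seed.
#' @param top_n Top terms per topic used in both scores (default 30). The
#'   scoring window must reach past the first run of near-tied terms:
#'   a topic that merges two themes can hide the second theme below a
#'   narrow top-10, so selection scores use a wider window than reporting
#'   does.
#' @param restarts Gibbs restarts per candidate K (default 3): score
#'   comparisons across K are only meaningful at each K's posterior mode.
#' @return List with `k_star` (chosen K), `scores` (data.frame with raw and
#'   normalized columns per K), and `models` (the fitted models, named by
#'   K).
#' @export
select_topic_number <- function(corpus, k_grid, config, top_n = 30,
                                restarts = 3) {
  stopifnot(length(k_grid) >= 1)
  k_grid <- sort(unique(as.integer(k_grid)))
  fits <- lapply(k_grid, function(K) {
    cfg <- lda_config(n_topics = K, alpha = config$alpha, eta = config$eta,
                      gibbs_iterations = config$gibbs_iterations,
                      burn_in = config$burn_in,
                      seed = (config$seed + 31L * K) %% .Machine$integer.max)
    fit_lda(corpus, cfg, top_n = top_n, restarts = restarts)
  })
  names(fits) <- k_grid
  coh <- vapply(fits, function(m) mean(m$coherence), numeric(1))
  exc <- vapply(fits, function(m) mean(m$exclusivity), numeric(1))
  norm01 <- function(x) {
    r <- range(x)
    if (diff(r) == 0) rep(0.5, length(x)) else (x - r[1]) / diff(r)
  }
  scores <- data.frame(k = k_grid,
                       coherence = coh, exclusivity = exc,
                       coherence_norm = norm01(coh),
                       exclusivity_norm = norm01(exc))
  scores$score <- (scores$coherence_norm + scores$exclusivity_norm) / 2
  k_star <- k_grid[which.max(scores$score)]
  list(k_star = k_star, scores = scores, models = fits)
}
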