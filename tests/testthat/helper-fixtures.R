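# Shared fixture builders; everything is generated in code at test time.

make_records <- function(n = 3, abstracts = NULL, titles = NULL,
                         dates = NULL, ids = NULL, taxon = "pangolin") {
  patent_records(
    record_id = ids %||% sprintf("rec-%03d", seq_len(n)),
    title = titles %||% rep("untitled", n),
    abstract = abstracts %||% rep("an abstract", n),
    priority_date = dates %||% (as.Date("2000-01-15") + seq_len(n)),
    taxon = taxon)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# Best-match (over topic permutations) of the maximum per-topic TV distance
# between a fitted and a planted topic-word matrix on the shared vocabulary.
best_match_max_tv <- function(fitted, planted) {
  shared <- intersect(colnames(fitted), colnames(planted))
  f <- fitted[, shared, drop = FALSE]
  p <- planted[, shared, drop = FALSE]
  K <- nrow(f)
  perms <- as.matrix(expand.grid(rep(list(seq_len(K)), K)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == K), ,
                 drop = FALSE]
  best <- Inf
  for (i in seq_len(nrow(perms))) {
    worst <- max(vapply(seq_len(K), function(k)
      tv_dist(f[k, ], p[perms[i, k], ]), numeric(1)))
    best <- min(best, worst)
  }
  best
}

# Independent log-gamma evaluation of the NB2 pmf, term by term; the oracle
# against which nb_log_pmf is checked.
nb_lpmf_oracle <- function(y, mu, phi) {
  lgamma(y + phi) - lgamma(phi) - lfactorial(y) +
    phi * (log(phi) - log(mu + phi)) + y * (log(mu) - log(mu + phi))
}

# Tiny hand-constructible tokenized corpus.
make_corpus <- function(docs, vocab) {
  structure(list(documents = lapply(docs, function(d)
    as.integer(match(d, vocab))),
    vocabulary = vocab,
    doc_ids = sprintf("doc-%02d", seq_along(docs))),
    class = "tokenized_corpus")
}

# Hand-constructible LDA model (only topic_word is needed by the scores).
make_model <- function(topic_word) {
  structure(list(topic_word = topic_word,
                 doc_topic = NULL, assignments = NULL),
            class = "lda_model")
}
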