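# Tokenization, collapsed-Gibbs LDA, coherence/exclusivity and K selection.

test_that("preprocessing tokenizes, stops, and thresholds as configured", {
  recs <- make_records(3, abstracts = c("Bear bile powder",
                                        "bear bile tonic",
                                        "bile of bear"))
  corp <- preprocess(recs, stoplist = character(), min_term_count = 1)
  expect_setequal(corp$vocabulary[corp$documents[[1]]],
                  c("bear", "bile", "powder"))

  corp2 <- preprocess(recs, stoplist = "bear", min_term_count = 1)
  expect_false("bear" %in% corp2$vocabulary)
  expect_setequal(corp2$vocabulary[corp2$documents[[1]]], c("bile", "powder"))

  # min_term_count = 2 drops singletons ("powder", "tonic", "of")
  corp3 <- preprocess(recs, stoplist = character(), min_term_count = 2)
  expect_setequal(corp3$vocabulary, c("bear", "bile"))

  # empty documents are dropped with a report; all-empty errors
  recs2 <- make_records(2, abstracts = c("bear bile", "zzz"))
  corp4 <- preprocess(recs2, stoplist = "zzz", min_term_count = 1)
  expect_equal(attr(corp4, "dropped_docs"), "rec-002")
  expect_error(preprocess(make_records(1, abstracts = "x"),
                          stoplist = "x", min_term_count = 1),
               "no terms survive")
})

test_that("lda fit conserves tokens, normalizes, and is seed-reproducible", {
  cc <- sim_corpus_config(
    series = list(tx = sim_series_config(n_months = 6, changepoint_month = NULL,
                                         mu_early = 20, taxon = "tx", seed = 1)),
    n_topics_true = 2, vocabulary_size = 60, doc_length_mean = 30,
    decoy_fraction = 0, seed = 6)
  sim <- simulate_patent_corpus(cc)
  corp <- preprocess(sim$records, stoplist = c("tx", "preparation", "product"),
                     min_term_count = 1)
  cfg <- lda_config(n_topics = 2, alpha = 0.3, gibbs_iterations = 100,
                    burn_in = 50, seed = 12)
  m <- fit_lda(corp, cfg)
  n_tokens <- sum(lengths(corp$documents))
  expect_true(all(m$tokens_assigned == n_tokens))  # at every sweep
  expect_equal(unname(rowSums(m$topic_word)), rep(1, 2), tolerance = 1e-9)
  expect_equal(unname(rowSums(m$doc_topic)),
               rep(1, nrow(m$doc_topic)), tolerance = 1e-9)
  expect_equal(length(unlist(m$assignments)), n_tokens)

  m2 <- fit_lda(corp, cfg)
  expect_identical(m$topic_word, m2$topic_word)
  expect_identical(m$assignments, m2$assignments)
  expect_error(fit_lda(corp, lda_config(n_topics = 100)), "vocabulary")
})

test_that("lda recovers planted disjoint-vocabulary topics", {
  cc <- sim_corpus_config(
    series = list(tx = sim_series_config(n_months = 12, changepoint_month = NULL,
                                         mu_early = 42, phi_early = 5,
                                         taxon = "tx", seed = 71)),
    n_topics_true = 2, vocabulary_size = 100, doc_length_mean = 50,
    decoy_fraction = 0, seed = 72)
  sim <- simulate_patent_corpus(cc)
  expect_gt(nrow(sim$records), 400)
  corp <- preprocess(sim$records,
                     stoplist = c(default_stoplist(), "tx", "preparation",
                                  "product"))
  m <- fit_lda(corp, lda_config(n_topics = 2, alpha = 0.3,
                                gibbs_iterations = 200, burn_in = 100,
                                seed = 73))
  expect_lt(best_match_max_tv(m$topic_word, sim$truth$topic_word), 0.1)
})

test_that("coherence follows its formula on hand-countable corpora", {
  vocab <- c("u", "v", "x", "y")
  # "u","v" co-occur in every document; "x","y" never do, same marginals
  corp <- make_corpus(list(c("u", "v", "x"), c("u", "v", "y")), vocab)
  co_model <- make_model(rbind(
    c(0.4, 0.4, 0.1, 0.1),       # top-2 terms u, v
    c(0.1, 0.1, 0.4, 0.4)))      # top-2 terms x, y
  colnames(co_model$topic_word) <- vocab
  sc <- coherence(co_model, corp, top_n = 2)
  expect_gt(sc[1], sc[2])
  # hand evaluation: D(u,v) = 2, D(u) = D(v) = 2 -> log(3/2);
  # D(x,y) = 0, D(x) = D(y) = 1 -> log(1/1)
  expect_equal(sc[1], log(3 / 2), tolerance = 1e-12)
  expect_equal(sc[2], log(1), tolerance = 1e-12)

  # top_n = 2 with both terms in all D documents -> log((D+1)/D)
  corp3 <- make_corpus(list(c("u", "v"), c("u", "v"), c("v", "u")), c("u", "v"))
  m3 <- make_model(matrix(c(0.6, 0.4), 1, dimnames = list(NULL, c("u", "v"))))
  expect_equal(coherence(m3, corp3, top_n = 2), log(4 / 3), tolerance = 1e-12)
})

test_that("exclusivity is 1 for disjoint topics, 1/K for identical ones", {
  vocab <- c("a", "b", "c", "d")
  disjoint <- make_model(rbind(c(0.5, 0.5, 0, 0), c(0, 0, 0.5, 0.5)))
  colnames(disjoint$topic_word) <- vocab
  expect_equal(exclusivity(disjoint, top_n = 2), c(1, 1))

  identical_tw <- make_model(rbind(c(0.4, 0.3, 0.2, 0.1),
                                   c(0.4, 0.3, 0.2, 0.1)))
  colnames(identical_tw$topic_word) <- vocab
  expect_equal(exclusivity(identical_tw, top_n = 2), c(0.5, 0.5))

  # hand-built 2-topic, 3-word model
  m <- make_model(rbind(c(0.6, 0.3, 0.1), c(0.2, 0.2, 0.6)))
  colnames(m$topic_word) <- c("p", "q", "r")
  # topic 1 top-2: p (0.6/0.8), q (0.3/0.5); topic 2 top-2: r (0.6/0.7), then
  # p and q tie at 0.2 -> first by column order is p (0.2/0.8)
  expect_equal(exclusivity(m, top_n = 2),
               c(mean(c(0.6 / 0.8, 0.3 / 0.5)), mean(c(0.6 / 0.7, 0.2 / 0.8))),
               tolerance = 1e-12)
})

test_that("top terms skip the generic stoplist and flag short vocabularies", {
  m <- make_model(matrix(c(0.5, 0.3, 0.2), 1,
                         dimnames = list(NULL, c("top", "mid", "low"))))
  expect_equal(top_terms(m, 1, 2), c("top", "mid"))
  expect_equal(top_terms(m, 1, 2, generic_stoplist = "top"), c("mid", "low"))
  expect_warning(out <- top_terms(m, 1, 5), "available")
  expect_true(isTRUE(attr(out, "incomplete")))
})

test_that("topic-number selection returns the only candidate and a score table", {
  cc <- sim_corpus_config(
    series = list(tx = sim_series_config(n_months = 4, changepoint_month = NULL,
                                         mu_early = 15, taxon = "tx", seed = 81)),
    n_topics_true = 2, vocabulary_size = 40, doc_length_mean = 20,
    decoy_fraction = 0, seed = 82)
  sim <- simulate_patent_corpus(cc)
  corp <- preprocess(sim$records, stoplist = c("tx", "preparation", "product"),
                     min_term_count = 1)
  cfg <- lda_config(n_topics = 2, alpha = 0.3, gibbs_iterations = 60,
                    burn_in = 30, seed = 83)
  sel <- select_topic_number(corp, k_grid = 3, cfg, restarts = 1)
  expect_equal(sel$k_star, 3L)
  sel2 <- select_topic_number(corp, k_grid = c(2, 4), cfg, restarts = 1)
  expect_equal(nrow(sel2$scores), 2)
  expect_true(all(c("k", "coherence", "exclusivity", "coherence_norm",
                    "exclusivity_norm", "score") %in% names(sel2$scores)))
})
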