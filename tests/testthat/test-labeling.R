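# Codebook construction, multi-label coding, iterative expansion,
# cumulative proportions.

toy_model <- function() {
  tw <- rbind(c(0.30, 0.25, 0.20, 0.15, 0.06, 0.04),
              c(0.04, 0.06, 0.15, 0.20, 0.25, 0.30))
  colnames(tw) <- c("bile", "tonic", "salve", "feed", "breeding", "pen")
  make_model(tw)
}

test_that("codebooks combine LDA top terms with standard terms", {
  cb <- build_codebook(toy_model(),
                       label_map = c("1" = "medicine", "2" = "farming"),
                       standard_terms = list(medicine = c("pain", "bile")),
                       n_terms = 3)
  expect_setequal(cb$labels, c("medicine", "farming"))
  expect_true("pain" %in% cb$keywords$medicine)
  expect_equal(cb$provenance$medicine[cb$keywords$medicine == "pain"],
               "standard_term")
  # duplicate ("bile") appears once, LDA provenance wins
  expect_equal(sum(cb$keywords$medicine == "bile"), 1L)
  expect_equal(cb$provenance$medicine[cb$keywords$medicine == "bile"],
               "lda_top_term")
  # empty standard terms: pure LDA top terms
  cb2 <- build_codebook(toy_model(), c("1" = "medicine", "2" = "farming"),
                        n_terms = 3)
  expect_true(all(unlist(cb2$provenance) == "lda_top_term"))
  expect_equal(cb2$keywords$medicine, c("bile", "tonic", "salve"))
})

test_that("labels are non-exclusive, audited, and uncovered records listed", {
  cb <- new_codebook(c("medicine", "farming"),
                     list(medicine = c("pain", "bile"),
                          farming = c("feed")),
                     list(medicine = rep("standard_term", 2),
                          farming = "standard_term"))
  recs <- make_records(3, abstracts = c("animal feed additive",
                                        "bile tonic for pain and feed",
                                        "a carburetor"))
  lab <- label_records(recs, cb)
  expect_equal(lab$labels_by_record[["rec-001"]], "farming")
  expect_setequal(lab$labels_by_record[["rec-002"]],
                  c("medicine", "farming"))
  expect_equal(lab$uncovered, "rec-003")
  expect_equal(lab$coverage, 2 / 3)
  # audit: every assignment backed by a (record, label, keyword) triple
  for (id in names(lab$labels_by_record)) {
    for (l in lab$labels_by_record[[id]]) {
      expect_true(any(lab$matches$record_id == id & lab$matches$label == l))
    }
  }
})

test_that("iterative labeling reaches full coverage via the expansion policy", {
  # planted uncovered record whose dominant term is "fertilizer"
  abstracts <- c("bile bile tonic", "feed feed pen", "fertilizer fertilizer soil")
  recs <- make_records(3, abstracts = abstracts)
  corp <- preprocess(recs, stoplist = character(), min_term_count = 1)
  doc_topic <- rbind(c(0.9, 0.1), c(0.1, 0.9), c(0.2, 0.8))
  rownames(doc_topic) <- recs$record_id
  model <- make_model(toy_model()$topic_word)
  model$doc_topic <- doc_topic
  cb <- new_codebook(c("medicine", "farming"),
                     list(medicine = "bile", farming = "feed"),
                     list(medicine = "lda_top_term", farming = "lda_top_term"))
  policy <- lda_expansion_policy(model, corp,
                                 c("1" = "medicine", "2" = "farming"))
  res <- iterate_labeling(recs, cb, policy, max_iterations = 3)
  expect_equal(res$status, "converged")
  expect_equal(res$labeled$coverage, 1)
  expect_true("fertilizer" %in% res$codebook$keywords$farming)
  expect_equal(res$codebook$provenance$farming[
    res$codebook$keywords$farming == "fertilizer"], "expansion_iteration_1")
  expect_lte(max(res$labeled$iteration_log$iteration), 3)
  # coverage non-decreasing across iterations
  expect_true(all(diff(res$labeled$iteration_log$coverage) >= 0))
})

test_that("full coverage at iteration 0 converges immediately; stalls are flagged", {
  recs <- make_records(2, abstracts = c("bile drops", "bile paste"))
  cb <- new_codebook("medicine", list(medicine = "bile"),
                     list(medicine = "standard_term"))
  null_policy <- function(uncovered, codebook)
    data.frame(label = character(), keyword = character())
  res <- iterate_labeling(recs, cb, null_policy, max_iterations = 5)
  expect_equal(res$status, "converged")
  expect_equal(nrow(res$labeled$iteration_log), 1)
  expect_equal(res$labeled$iteration_log$keywords_added, 0L)
  expect_identical(res$codebook$keywords, cb$keywords)

  recs2 <- make_records(2, abstracts = c("bile drops", "unrelated widget"))
  res2 <- iterate_labeling(recs2, cb, null_policy, max_iterations = 5)
  expect_equal(res2$status, "stalled")
  expect_lt(res2$labeled$coverage, 1)
})

test_that("cumulative proportions use label assignments as the denominator", {
  recs <- make_records(3,
                       abstracts = c("bile", "feed", "bile and feed"),
                       dates = as.Date(c("2000-01-10", "2000-02-10",
                                         "2000-03-10")))
  cb <- new_codebook(c("medicine", "farming"),
                     list(medicine = "bile", farming = "feed"),
                     list(medicine = "standard_term",
                          farming = "standard_term"))
  lab <- label_records(recs, cb)
  props <- cumulative_label_proportions(lab, recs,
                                        window = c("2000-01", "2000-04"))
  expect_equal(dim(props), c(4L, 2L))
  expect_equal(props["2000-01", ], c(farming = 0, medicine = 1))
  expect_equal(props["2000-02", ], c(farming = 0.5, medicine = 0.5))
  # month 3: the two-label record contributes one count to each label:
  # totals medicine 2, farming 2 over 4 assignments
  expect_equal(props["2000-03", ], c(farming = 0.5, medicine = 0.5))
  expect_equal(unname(rowSums(props)), rep(1, 4), tolerance = 1e-9)
  counts <- attr(props, "cumulative_counts")
  expect_true(all(apply(counts, 2, function(x) all(diff(x) >= 0))))

  # single label throughout -> proportion 1 every month
  lab1 <- label_records(recs[1, , drop = FALSE], cb)
  p1 <- cumulative_label_proportions(lab1, recs[1, , drop = FALSE],
                                     window = c("2000-01", "2000-02"))
  expect_equal(unname(p1[, "medicine"]), c(1, 1))

  expect_warning(
    out <- cumulative_label_proportions(label_records(make_records(0), cb),
                                        make_records(0),
                                        window = c("2000-01", "2000-02")),
    "no labeled records")
  expect_equal(nrow(out), 0)
})

test_that("codebook YAML round-trips with provenance", {
  cb <- new_codebook(c("medicine", "detection"),
                     list(medicine = c("bile", "pain"),
                          detection = "pcr"),
                     list(medicine = c("lda_top_term", "standard_term"),
                          detection = "standard_term"))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_codebook(cb, path)
  back <- read_codebook(path)
  expect_equal(back$keywords, cb$keywords)
  expect_equal(back$provenance, cb$provenance)

  bundled <- read_codebook(system.file("extdata", "codebook_default.yaml",
                                       package = "patenttrends"))
  expect_true("medicine" %in% bundled$labels)
  expect_true(all(lengths(bundled$keywords) >= 1))
})
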