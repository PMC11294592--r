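# Include/exclude keyword semantics and the aggregation of records into
# monthly count series.

test_that("exclusion overrides inclusion and matched terms are recorded", {
  spec <- keyword_spec("pangolin", include_terms = c("pangolin", "chuan shan jia"),
                       exclude_terms = "drosophila")
  recs <- make_records(4, abstracts = c(
    "a medicinal powder containing pangolin scales",
    "expression of the pangolin gene in drosophila embryos",
    "a compound of chuan  shan jia extract",
    "a bear bile derivative"))
  out <- filter_by_keywords(recs, spec)
  expect_equal(out$kept$record_id, c("rec-001", "rec-003"))
  expect_equal(out$kept$matched_terms[[1]], "pangolin")
  expect_equal(out$kept$matched_terms[[2]], "chuan shan jia")
  expect_equal(out$excluded$record_id, c("rec-002", "rec-004"))
})

test_that("matching is case-insensitive, word-bounded, and phrase-aware", {
  spec <- keyword_spec("rhinoceros", include_terms = c("rhino", "gall bladder"))
  recs <- make_records(4, abstracts = c(
    "Rhino horn preparations",
    "rhinoceros-free formulation",   # 'rhino' must not match inside a word
    "dried GALL  BLADDER tissue",
    "gall and bladder are separate here. bladder gall."))
  out <- filter_by_keywords(recs, spec)
  expect_setequal(out$kept$record_id, c("rec-001", "rec-003"))
})

test_that("non-Latin terms match as literal substrings", {
  spec <- keyword_spec("pangolin", include_terms = c("穿山甲"))
  recs <- make_records(2, abstracts = c(
    "一种含穿山甲的药物",
    "nothing relevant"))
  out <- filter_by_keywords(recs, spec)
  expect_equal(out$kept$record_id, "rec-001")
})

test_that("filtering partitions the input and is idempotent on its kept set", {
  set.seed(401)
  n <- 1000
  words <- c("pangolin", "drosophila", "bear", "scale", "powder", "gene")
  abstracts <- vapply(seq_len(n), function(i)
    paste(sample(words, 3, replace = TRUE), collapse = " "), "")
  recs <- make_records(n, abstracts = abstracts)
  spec <- keyword_spec("pangolin", "pangolin", "drosophila")
  out <- filter_by_keywords(recs, spec)
  expect_setequal(c(out$kept$record_id, out$excluded$record_id),
                  recs$record_id)
  expect_length(intersect(out$kept$record_id, out$excluded$record_id), 0)
  again <- filter_by_keywords(out$kept, spec)
  expect_equal(again$kept$record_id, out$kept$record_id)
  expect_equal(nrow(again$excluded), 0)
})

test_that("keyword specs reject overlapping include/exclude lists", {
  expect_error(keyword_spec("x", c("Rhino"), c("rhino ")), "overlap")
  expect_error(keyword_spec("x", character()), "non-empty")
})

test_that("bundled six-taxa keyword file loads and behaves like the table", {
  path <- system.file("extdata", "keywords_six_taxa.yaml",
                      package = "patenttrends")
  specs <- read_keyword_specs(path)
  expect_setequal(names(specs),
                  c("bear", "caterpillar_fungus", "horseshoe_crab",
                    "pangolin", "rhinoceros", "sturgeon"))
  recs <- make_records(2, abstracts = c(
    "pangolin scale medicine",
    "pangolin wingless signalling in drosophila"))
  out <- filter_by_keywords(recs, specs$pangolin)
  expect_equal(out$kept$record_id, "rec-001")
})

test_that("monthly aggregation counts by priority month with explicit zeros", {
  recs <- make_records(3, dates = as.Date(c("1990-01-15", "1990-01-20",
                                            "1990-02-01")))
  s <- aggregate_monthly(recs, window = c("1990-01", "1990-03"))
  expect_s3_class(s, "monthly_counts")
  expect_equal(s$counts, c(2L, 1L, 0L))
  expect_equal(series_months(s), c("1990-01", "1990-02", "1990-03"))

  # empty record list -> all-zero series of window length
  s0 <- aggregate_monthly(make_records(0), window = c("1990-01", "1990-04"))
  expect_equal(s0$counts, rep(0L, 4))

  expect_error(aggregate_monthly(recs, window = c("1990-02", "1990-01")),
               "empty")
})

test_that("aggregation conserves in-window records and reports dropped ones", {
  set.seed(77)
  n <- 1000
  dates <- as.Date("1990-01-01") + sample.int(3 * 365, n, replace = TRUE) - 1
  recs <- make_records(n, dates = dates)
  s <- aggregate_monthly(recs, window = c("1990-01", "1992-12"))
  expect_equal(sum(s$counts), n)
  expect_equal(attr(s, "dropped"), 0L)

  s2 <- aggregate_monthly(recs, window = c("1991-01", "1992-12"))
  expect_equal(sum(s2$counts) + attr(s2, "dropped"), n)
})

test_that("series CSV round-trips and rejects gappy month columns", {
  s <- monthly_counts(c(3, 0, 7), "2019-11", taxon = "bear")
  path <- withr::local_tempfile(fileext = ".csv")
  write_series(s, path)
  back <- read_series(path, taxon = "bear")
  expect_equal(back$counts, s$counts)
  expect_equal(back$start_month, "2019-11")

  gap <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("month,count", "2019-01,1", "2019-03,2"), gap)
  expect_error(read_series(gap), "contiguous")
})
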