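## End-to-end orchestration. Every stage reads and writes plain files
## (JSONL/CSV/JSON/YAML) in the output directory, so any stage can also be
## run standalone on another stage's outputs; the run report makes the run
## reproducible from the config alone.

#' Assemble a pipeline configuration
#'
#' Merges user settings over the defaults for a full analysis run:
#' simulate/ingest -> deduplicate + filter -> aggregate -> changepoint ->
#' topics -> label -> trends -> report. All stage seeds derive
#' deterministically from the single global `seed`.
#'
#' @param output_dir Directory for stage outputs (created if needed).
#' @param seed Global integer seed.
#' @param input List: either `type = "synthetic"` with `corpus` (arguments
#'   for [sim_corpus_config()]), or `type = "records"` with `records_path`
#'   and `format`.
#' @param keywords List: `path` to a keyword-spec YAML/JSON (default: specs
#'   are derived from the synthetic corpus config), `fields` searched.
#' @param window `c(from, to)` `"YYYY-MM"` aggregation window, or `NULL` to
#'   span the observed priority dates.
#' @param changepoint List of [changepoint_priors()] and [sampler_config()]
#'   settings (`mu_prior_mean`, `phi_prior_mean`, `iterations`, `chains`,
#'   `warmup_fraction`, `target_accept`).
#' @param topics List: `k_grid`, `eta`, `iterations`, `burn_in`,
#'   `min_term_count`, `extra_stopwords`.
#' @param labeling List: `codebook_path` (optional; otherwise the codebook
#'   is built from the selected topic model), `standard_terms`,
#'   `max_iterations`.
#' @param trends List: `start_year`, `end_year` (default: the complete
#'   calendar years inside the window), `median_period`, `smooth_window`.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(output_dir,
                            seed = 1L,
                            input = list(type = "synthetic"),
                            keywords = list(),
                            window = NULL,
                            changepoint = list(),
                            topics = list(),
                            labeling = list(),
                            trends = list()) {
  merge_defaults <- function(user, defaults) {
    for (nm in names(user)) defaults[[nm]] <- user[[nm]]
    defaults
  }
  input <- merge_defaults(input, list(type = "synthetic", corpus = list(),
                                      records_path = NULL, format = "jsonl"))
  keywords <- merge_defaults(keywords, list(path = NULL,
                                            fields = c("title", "abstract")))
  changepoint <- merge_defaults(changepoint, list(
    mu_prior_mean = 10, phi_prior_mean = 1, iterations = 2000, chains = 4,
    warmup_fraction = 0.5, target_accept = 0.95))
  topics <- merge_defaults(topics, list(
    k_grid = c(2, 3, 6), eta = 0.01, iterations = 400, burn_in = 200,
    min_term_count = 2, extra_stopwords = character()))
  labeling <- merge_defaults(labeling, list(
    codebook_path = NULL, standard_terms = list(), max_iterations = 5))
  trends <- merge_defaults(trends, list(
    start_year = NULL, end_year = NULL, median_period = NULL,
    smooth_window = 13))
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 input = input, keywords = keywords, window = window,
                 changepoint = changepoint, topics = topics,
                 labeling = labeling, trends = trends),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  keep <- intersect(names(raw), names(formals(pipeline_config)))
  do.call(pipeline_config, raw[keep])
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 97 * k) %% 2147483647)
}

pipeline_fail <- function(stage, msg, manifest) {
  stop(structure(class = c("pipeline_error", "error", "condition"),
                 list(message = sprintf("pipeline stage '%s': %s", stage, msg),
                      call = NULL, stage = stage, manifest = manifest)))
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order under one seeded configuration, writing
#' each stage's interface files into `config$output_dir`. Identical config
#' and seed reproduce all written artifacts byte-for-byte. Any stage
#' failure aborts with a `pipeline_error` carrying the partial manifest.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list: per-stage record counts, convergence flags,
#'   the output-file manifest, package version, and an echo of the config.
#'   The same report is written to `run_report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character()
  stages <- list()
  emit <- function(path) manifest[length(manifest) + 1L] <<- path
  say <- function(stage, ...) message(sprintf("[%s] %s", stage,
                                              sprintf(...)))

  ## fail-fast validation of referenced paths, before any sampling
  if (!is.null(config$labeling$codebook_path) &&
      !file.exists(config$labeling$codebook_path)) {
    pipeline_fail("label", paste0("codebook not found: ",
                                  config$labeling$codebook_path), manifest)
  }
  if (!is.null(config$keywords$path) && !file.exists(config$keywords$path)) {
    pipeline_fail("filter", paste0("keyword spec not found: ",
                                   config$keywords$path), manifest)
  }
  if (identical(config$input$type, "records") &&
      (is.null(config$input$records_path) ||
       !file.exists(config$input$records_path))) {
    pipeline_fail("ingest", "records_path missing or not found", manifest)
  }

  ## -- simulate / ingest ----------------------------------------------
  truth <- NULL
  if (identical(config$input$type, "synthetic")) {
    corpus_args <- config$input$corpus
    corpus_args$seed <- derive_seed(config$seed, 1)
    keep <- intersect(names(corpus_args), names(formals(sim_corpus_config)))
    ccfg <- tryCatch(do.call(sim_corpus_config, corpus_args[keep]),
                     error = function(e) pipeline_fail("simulate",
                                                       conditionMessage(e),
                                                       manifest))
    sim <- simulate_patent_corpus(ccfg)
    records <- sim$records
    truth <- sim$truth
    write_records(records, file.path(out_dir, "records.jsonl"))
    emit("records.jsonl")
    write_truth(truth, file.path(out_dir, "truth.json"))
    emit("truth.json")
    specs <- lapply(names(ccfg$series), function(tx)
      keyword_spec(tx, ccfg$taxon_keywords[[tx]], ccfg$decoy_terms))
    names(specs) <- names(ccfg$series)
    say("simulate", "%d records, %d taxa", nrow(records), length(specs))
  } else {
    records <- read_records(config$input$records_path,
                            format = config$input$format)
    specs <- NULL
    say("ingest", "%d records read, %d malformed rows",
        nrow(records), nrow(record_errors(records)))
  }
  if (!is.null(config$keywords$path)) {
    specs <- read_keyword_specs(config$keywords$path)
  }
  if (is.null(specs)) {
    pipeline_fail("filter", "no keyword specs: supply keywords$path",
                  manifest)
  }
  stages$ingest <- list(records = nrow(records))

  ## -- deduplicate + filter -------------------------------------------
  dd <- deduplicate_records(records)
  records <- dd$records
  kept_all <- list()
  excluded_n <- 0L
  for (tx in names(specs)) {
    sub <- records[!is.na(records$taxon) & records$taxon == tx, ,
                   drop = FALSE]
    if (!nrow(sub)) next
    fr <- filter_by_keywords(sub, specs[[tx]],
                             fields = config$keywords$fields)
    kept_all[[tx]] <- fr$kept
    excluded_n <- excluded_n + nrow(fr$excluded)
  }
  if (!length(kept_all)) pipeline_fail("filter", "no records kept", manifest)
  kept <- do.call(rbind, kept_all)
  rownames(kept) <- NULL
  class(kept) <- c("patent_records", "data.frame")
  write_records(kept, file.path(out_dir, "records_filtered.jsonl"))
  emit("records_filtered.jsonl")
  stages$filter <- list(duplicates_removed = dd$removed,
                        kept = nrow(kept), excluded = excluded_n)
  say("filter", "%d kept, %d excluded, %d duplicates removed",
      nrow(kept), excluded_n, dd$removed)

  ## -- aggregate -------------------------------------------------------
  window <- config$window
  if (is.null(window)) {
    window <- c(date_ym(min(kept$priority_date)),
                date_ym(max(kept$priority_date)))
  }
  taxa <- sort(unique(kept$taxon))
  series_by_taxon <- list()
  for (tx in taxa) {
    s <- aggregate_monthly(kept[kept$taxon == tx, , drop = FALSE],
                           window = window, taxon = tx)
    series_by_taxon[[tx]] <- s
    write_series(s, file.path(out_dir, sprintf("series_%s.csv", tx)))
    emit(sprintf("series_%s.csv", tx))
  }
  stages$aggregate <- list(window = window,
                           totals = lapply(series_by_taxon,
                                           function(s) sum(s$counts)))
  say("aggregate", "window %s..%s, %d taxa", window[1], window[2],
      length(taxa))

  ## -- changepoint -----------------------------------------------------
  priors <- changepoint_priors(config$changepoint$mu_prior_mean,
                               config$changepoint$phi_prior_mean)
  cp_flags <- list()
  for (i in seq_along(taxa)) {
    tx <- taxa[i]
    cfg <- sampler_config(iterations = config$changepoint$iterations,
                          chains = config$changepoint$chains,
                          warmup_fraction = config$changepoint$warmup_fraction,
                          target_accept = config$changepoint$target_accept,
                          seed = derive_seed(config$seed, 100 + i))
    fit <- tryCatch(
      sample_changepoint_posterior(series_by_taxon[[tx]], priors, cfg),
      error = function(e) pipeline_fail("changepoint", conditionMessage(e),
                                        manifest))
    tp <- data.frame(month = names(fit$tau_probs),
                     probability = as.numeric(fit$tau_probs))
    write.csv(tp, file.path(out_dir, sprintf("tau_probs_%s.csv", tx)),
              row.names = FALSE)
    emit(sprintf("tau_probs_%s.csv", tx))
    dr <- as.data.frame(matrix(aperm(fit$draws, c(1, 2, 3)),
                               ncol = 4,
                               dimnames = list(NULL, CP_PARAMS)))
    dr$chain <- rep(seq_len(dim(fit$draws)[2]), each = dim(fit$draws)[1])
    write.csv(dr, file.path(out_dir, sprintf("draws_%s.csv", tx)),
              row.names = FALSE)
    emit(sprintf("draws_%s.csv", tx))
    jsonlite::write_json(
      list(taxon = tx, map_month = fit$map_month,
           converged = fit$converged,
           rhat = setNames(as.list(fit$diagnostics$rhat),
                           fit$diagnostics$param),
           ess = setNames(as.list(fit$diagnostics$ess),
                          fit$diagnostics$param)),
      file.path(out_dir, sprintf("diagnostics_%s.json", tx)),
      auto_unbox = TRUE, digits = NA)
    emit(sprintf("diagnostics_%s.json", tx))
    cp_flags[[tx]] <- list(map_month = fit$map_month,
                           converged = fit$converged)
    say("changepoint", "%s: MAP %s, converged %s", tx, fit$map_month,
        fit$converged)
  }
  stages$changepoint <- cp_flags

  ## -- topics ----------------------------------------------------------
  stop_terms <- c(default_stoplist(), config$topics$extra_stopwords,
                  unlist(lapply(specs, `[[`, "include_terms")),
                  unlist(lapply(specs, `[[`, "exclude_terms")))
  corpus <- tryCatch(
    preprocess(kept, stoplist = stop_terms,
               min_term_count = config$topics$min_term_count),
    error = function(e) pipeline_fail("topics", conditionMessage(e),
                                      manifest))
  tcfg <- lda_config(n_topics = max(2L, min(config$topics$k_grid)),
                     eta = config$topics$eta,
                     gibbs_iterations = config$topics$iterations,
                     burn_in = config$topics$burn_in,
                     seed = derive_seed(config$seed, 200))
  sel <- select_topic_number(corpus, config$topics$k_grid, tcfg)
  model <- sel$models[[as.character(sel$k_star)]]
  write.csv(data.frame(term = colnames(model$topic_word),
                       t(model$topic_word)),
            file.path(out_dir, "topic_word.csv"), row.names = FALSE)
  emit("topic_word.csv")
  write.csv(data.frame(record_id = rownames(model$doc_topic),
                       model$doc_topic),
            file.path(out_dir, "doc_topic.csv"), row.names = FALSE)
  emit("doc_topic.csv")
  write.csv(sel$scores, file.path(out_dir, "topic_scores.csv"),
            row.names = FALSE)
  emit("topic_scores.csv")
  stages$topics <- list(k_star = sel$k_star,
                        documents = length(corpus$documents),
                        vocabulary = length(corpus$vocabulary))
  say("topics", "selected K=%d over grid {%s}", sel$k_star,
      paste(config$topics$k_grid, collapse = ","))

  ## -- label -----------------------------------------------------------
  gen <- c(generic_terms(corpus), stop_terms)
  if (!is.null(config$labeling$codebook_path)) {
    codebook <- read_codebook(config$labeling$codebook_path)
    label_map <- setNames(
      rep(codebook$labels, length.out = sel$k_star),
      as.character(seq_len(sel$k_star)))
  } else {
    label_map <- setNames(paste0("theme_", seq_len(sel$k_star)),
                          as.character(seq_len(sel$k_star)))
    codebook <- build_codebook(model, label_map,
                               standard_terms = config$labeling$standard_terms,
                               generic_stoplist = gen)
  }
  policy <- lda_expansion_policy(model, corpus, label_map,
                                 generic_stoplist = gen)
  res <- iterate_labeling(kept, codebook, policy,
                          max_iterations = config$labeling$max_iterations,
                          fields = config$keywords$fields)
  write_codebook(res$codebook, file.path(out_dir, "codebook.yaml"))
  emit("codebook.yaml")
  write.csv(res$labeled$matches, file.path(out_dir, "labels.csv"),
            row.names = FALSE)
  emit("labels.csv")
  props <- cumulative_label_proportions(res$labeled, kept, window = window)
  if (nrow(props)) {
    write.csv(data.frame(month = rownames(props), props,
                         check.names = FALSE),
              file.path(out_dir, "cumulative_proportions.csv"),
              row.names = FALSE)
    emit("cumulative_proportions.csv")
  }
  stages$label <- list(coverage = res$labeled$coverage,
                       status = res$status,
                       labels = length(res$codebook$labels))
  say("label", "coverage %.1f%% (%s)", 100 * res$labeled$coverage,
      res$status)

  ## -- trends ----------------------------------------------------------
  yrs <- full_years_in_window(window)
  start_year <- config$trends$start_year %||% yrs[1]
  end_year <- config$trends$end_year %||% yrs[length(yrs)]
  trend_out <- list()
  for (tx in taxa) {
    ts <- tryCatch(
      trend_summary(series_by_taxon[[tx]], start_year, end_year,
                    median_period = config$trends$median_period,
                    smooth_window = config$trends$smooth_window),
      error = function(e) pipeline_fail("trends", conditionMessage(e),
                                        manifest))
    jsonlite::write_json(
      list(taxon = tx,
           yearly_totals = as.list(ts$yearly_totals),
           yoy_changes = as.list(ts$yoy_changes),
           skipped_years = ts$skipped_years,
           mean_percent_change = ts$mean_percent_change,
           period_median = ts$period_median,
           peak = ts$peak,
           smoothed = ts$smoothed),
      file.path(out_dir, sprintf("trends_%s.json", tx)),
      auto_unbox = TRUE, digits = NA, na = "null")
    emit(sprintf("trends_%s.json", tx))
    trend_out[[tx]] <- list(mean_percent_change = ts$mean_percent_change,
                            peak = ts$peak)
    say("trends", "%s: mean yearly change %+.1f%%, peak %s (%d)", tx,
        ts$mean_percent_change, ts$peak$month, ts$peak$count)
  }
  stages$trends <- trend_out

  ## -- report ----------------------------------------------------------
  report <- list(package_version = as.character(utils::packageVersion("patenttrends")),
                 seed = config$seed,
                 stages = stages,
                 manifest = manifest,
                 config = config_echo(config))
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null")
  report$manifest <- c(manifest, "run_report.json")
  missing <- report$manifest[!file.exists(file.path(out_dir,
                                                    report$manifest))]
  if (length(missing)) {
    pipeline_fail("report", paste("manifest files missing:",
                                  paste(missing, collapse = ", ")),
                  manifest)
  }
  say("report", "%d artifact(s) in %s", length(report$manifest), out_dir)
  structure(report, class = "run_report")
}

full_years_in_window <- function(window) {
  i0 <- ym_index(window[1]); i1 <- ym_index(window[2])
  years <- seq.int(i0 %/% 12L, i1 %/% 12L)
  years[12L * years >= i0 & 12L * years + 11L <= i1]
}

config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$input$corpus <- lapply(cfg$input$corpus, function(x)
    if (inherits(x, "sim_series_config") || is.list(x)) unclass(x) else x)
  cfg
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report: seed %d, %d artifact(s)>\n", x$seed,
              length(x$manifest)))
  invisible(x)
}
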