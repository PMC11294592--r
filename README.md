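# patenttrends

Early-warning analysis of commercial wildlife trade from patent-filing
records.

Businesses trading wildlife-derived products — bear bile, rhinoceros
horn, pangolin scales, caviar, horseshoe-crab blood, caterpillar fungus —
file patents to protect their innovations, and those public filings
reveal market shifts years before new products appear in trade.
`patenttrends` implements the full analysis pipeline for this signal, for
conservation scientists and trade analysts:

* **Record handling** — JSONL/CSV patent records keyed by priority date,
  with line-numbered error reports, deduplication (earliest filing
  wins), and include/exclude keyword filtering (`"pangolin"` **NOT**
  `"drosophila"`-style rules; a ready spec for six traded taxa ships in
  `inst/extdata/keywords_six_taxa.yaml`).
* **Changepoint detection** — monthly filing counts are modelled as
  negative binomial (mean μ, dispersion φ, variance μ + μ²/φ) with one
  parameter set before an unknown changepoint τ and another at and after
  it; exponential priors (means 10 on the μ's, 1 on the φ's) and a
  uniform prior over candidate months. Inference marginalizes τ by
  log-sum-exp inside seeded MCMC (slice sampling within Gibbs) and
  reports the Rao-Blackwellized per-month changepoint probability, with
  split-R̂/ESS diagnostics, an exact quadrature oracle for validation,
  and recursive segmentation for multiple shifts.
* **Topic modelling** — LDA via collapsed Gibbs sampling (C++), with
  UMass semantic coherence, exclusivity, and topic-number selection by
  their normalized balance.
* **Thematic coding** — keyword codebooks built from LDA top terms plus
  standard category terms, multi-label coding with full audit triples,
  iterative expansion to 100% coverage, and cumulative label-proportion
  (diversification) curves.
* **Trend statistics** — January–December totals, year-on-year percent
  changes with zero-year skipping, period medians, peaks, smoothing.
* **Synthetic data** — a generator with planted changepoints, planted
  topics and decoy keywords, so the whole pipeline is testable without
  any scraped corpus.

## Worked example

Simulate ten years of monthly filings whose rate jumps from 2 to 10
patents/month at month 60 (December 1974), then locate the shift:

```r
library(patenttrends)

cfg <- sim_series_config(n_months = 120, changepoint_month = 60,
                         mu_early = 2, mu_late = 10, seed = 42)
series <- simulate_count_series(cfg)
series
#> <monthly_counts: 120 months 1970-01..1979-12, total 590>

fit <- sample_changepoint_posterior(series, config = sampler_config(seed = 1))
fit
#> <changepoint_posterior (mcmc): 120 months from 1970-01>
#>   MAP changepoint: 1974-12 (P = 0.381)
#>   max split R-hat: 1.0007; converged: TRUE
```

The fit recovers the planted month exactly: `1974-12` is month 60, and
the posterior puts probability 0.381 on that single month (the rest of
the mass sits on its close neighbours — `fit$tau_probs` holds the full
distribution). Diagnostics come from the post-warmup draws:

```r
fit$diagnostics
#>       param      rhat      ess
#> 1  mu_early 0.9997838 4000.000
#> 2   mu_late 0.9998582 3558.672
#> 3 phi_early 1.0007217 2842.477
#> 4  phi_late 1.0007304 3228.285
```

On series this short the sampler can be checked against the exact
quadrature posterior; here the total-variation distance is 0.0103:

```r
ex <- exact_changepoint_posterior(series)
0.5 * sum(abs(fit$tau_probs - ex$tau_probs))
#> [1] 0.0103
```

Keyword filtering with exclusion overriding inclusion:

```r
spec <- keyword_spec("pangolin",
                     include_terms = c("pangolin", "chuan shan jia"),
                     exclude_terms = "drosophila")
recs <- patent_records(
  record_id = c("CN-001", "CN-002"),
  title = c("Medicinal powder containing pangolin scales",
            "Expression of the pangolin gene in drosophila"),
  abstract = c("A pangolin scale decoction for treating disorders.",
               "We study the pangolin locus in drosophila embryos."),
  priority_date = as.Date(c("2013-05-02", "2014-01-20")),
  taxon = "pangolin")
filter_by_keywords(recs, spec)
#> kept: CN-001 | excluded: CN-002
```

`run_pipeline(pipeline_config(...))` chains every stage —
simulate/ingest, deduplicate + filter, aggregate, changepoint, topics,
label, trends — under one seed, writing each stage's CSV/JSON/JSONL/YAML
interface files plus a `run_report.json` manifest; identical config and
seed reproduce every artifact byte-for-byte. A thin command-line wrapper
with per-stage subcommands is installed at
`system.file("cli", "patenttrends.R", package = "patenttrends")`.

The methods vignette (`vignettes/patent-trend-pipeline.Rmd`) documents
the models, priors, selection scores, the synthetic-data generator and
its limits, and all numerical choices.

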