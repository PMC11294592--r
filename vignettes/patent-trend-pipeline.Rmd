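---
title: "Detecting shifts in wildlife-product patenting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting shifts in wildlife-product patenting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Businesses that trade wildlife-derived products file patents to protect
their innovations, and those filings leave a public trace of how markets
for rhinoceros horn, bear bile, pangolin scales, caviar, horseshoe-crab
blood or caterpillar fungus are moving — often years before new products
reach buyers. `patenttrends` packages the analytical pipeline for this
kind of early-warning work: ingest or simulate patent records, filter them
with include/exclude keyword rules, aggregate filings into monthly count
series, locate abrupt shifts in filing rate with a Bayesian changepoint
model, discover what the patents are about with LDA topic modelling,
code every patent against a thematic keyword codebook, and summarize
growth and diversification trends.

This vignette explains the models, the tunable parameters and the design
choices. It states no empirical result that the package's tests and
acceptance script do not themselves compute.

## The changepoint model

Monthly filing counts $y_1, \dots, y_n$ are modelled as negative binomial
in the mean/dispersion (NB2) form, $y_t \sim \mathrm{NB}(\mu, \phi)$ with
$\mathbb{E}[y] = \mu$ and $\mathrm{Var}[y] = \mu + \mu^2/\phi$. Patent
counts are strongly overdispersed — filings arrive in bursts around
product launches and legal deadlines — so a Poisson model would
understate the noise; small $\phi$ captures heavy overdispersion and
$\phi \to \infty$ recovers the Poisson.

A single changepoint $\tau$ splits the series into two regimes: months
before $\tau$ follow $\mathrm{NB}(\mu_e, \phi_e)$ and months at and after
$\tau$ follow $\mathrm{NB}(\mu_\ell, \phi_\ell)$. Throughout the package
$\tau$ is the 1-based index of the **first month under the late regime**,
so the candidate set is $\{2, \dots, n\}$ (both segments non-empty,
$n - 1$ candidates).

Priors, all configurable through `changepoint_priors()`:

* $\mu_e, \mu_\ell \sim \mathrm{Exp}(\text{mean} = 10)$ filings/month,
* $\phi_e, \phi_\ell \sim \mathrm{Exp}(\text{mean} = 1)$,
* $\tau \sim$ discrete uniform over the interior candidates.

Exponential priors were chosen because the rate and dispersion are
positive and only prior *means* are part of the model's standard
configuration; with 10 and 1 they are weakly informative at monthly
patent-count scale. Other positive families (half-normal, gamma) would
change little; the prior means matter more than the shape, and both are
exposed as knobs.

### Inference

`sample_changepoint_posterior()` runs MCMC over
$\theta = \log(\mu_e, \mu_\ell, \phi_e, \phi_\ell)$ with the discrete
$\tau$ **marginalized out** of the likelihood by log-sum-exp across all
candidates — this avoids trans-dimensional moves entirely. The kernel is
univariate slice sampling within Gibbs (stepping-out and shrinkage). A
slice kernel was preferred over adaptive random-walk Metropolis because
it is rejection-free and self-tuning: there is no proposal scale whose
adaptation could interact with the strongly skewed dispersion posteriors.
The `target_accept` field of `sampler_config()` is retained so that
configurations written for acceptance-rate-tuned samplers (where it plays
the role of `adapt_delta`) remain valid; the slice kernel records it but
has no acceptance rate to tune.

The per-month "probability of changepoint" is Rao-Blackwellized: for each
post-warmup draw the exact conditional $P(\tau \mid \theta, y)$ is
computed (a softmax over prefix/suffix log-likelihood sums), and these
conditionals are averaged over draws and chains. This gives a smooth,
low-variance posterior over months rather than a histogram of sampled
$\tau$ values.

Defaults follow standard practice for this model class: 2000 iterations,
4 chains, first half discarded as warmup. Convergence is assessed by
split-$\hat R$ and effective sample size (`compute_diagnostics()`),
computed from the package's own implementation of the half-chain
formulas; a fit with any split-$\hat R \ge 1.01$ is flagged
`converged = FALSE` (and warned about), never hidden. Zero-variance
chains yield an `NA` sentinel rather than an error. The post-warmup draws
are returned as an iterations × chains × parameters array, ready for
traceplots.

### The exact oracle

`exact_changepoint_posterior()` computes the same posterior by
deterministic quadrature for series up to 120 months. Because the early
block depends only on $(\mu_e, \phi_e)$ and the late block only on
$(\mu_\ell, \phi_\ell)$, the 4-D integral factorizes into two 2-D
integrals per candidate. Each is evaluated by averaging the block
likelihood over prior-quantile midpoints (64 points per dimension by
default), which turns "integrate against the prior" into a plain mean.
The oracle exists so the sampler can be validated against ground truth:
the test suite requires total-variation distance below 0.05 between the
two on every test series, checks that the oracle is exactly mirror
symmetric under time reversal (a structural property of the uniform
$\tau$ prior with exchangeable early/late priors), and checks argmax
stability under grid refinement. It is also cross-checked in the test
suite against a from-scratch brute-force enumeration written in plain R.

### Segmentation

`segment_changepoints()` extends the single-changepoint model to several
shifts by recursive splitting: fit, split at the MAP month, re-fit each
half, breadth-first, spending at most `max_segments` fits. Breadth-first
order matters: both halves of a split are examined before any
grandchildren, so the fit budget cannot be exhausted inside one noisy
half. Recursion stops when a segment is shorter than
`min_segment_length` (no split is attempted below twice that), and a
segment whose posterior maximum falls below twice the uniform value
($2/(n_\text{cand})$) is treated as changepoint-free and dropped — the
posterior is then barely more informative than its prior.

## Topic modelling

`fit_lda()` implements latent Dirichlet allocation by collapsed Gibbs
sampling (in C++): topic-word and document-topic Dirichlet parameters are
integrated out and only token-topic assignments are sampled. Point
estimates are the Dirichlet-smoothed final-sweep count tables. Defaults:
$\alpha = 50/K$ (the classical heuristic; override it downward for short,
single-theme texts like abstracts), $\eta = 0.01$, 1000 sweeps with the
first half treated as transient in the log-likelihood trace. The sampler
records the collapsed log joint and the assigned-token total at every
sweep; the latter must equal the corpus size at every sweep, and the
tests assert exactly that.

Collapsed Gibbs can lock into local modes — a classic one drops a theme
entirely while splitting another. `fit_lda(restarts = k)` runs `k`
independently initialized chains and keeps the one with the highest final
collapsed log joint.

`preprocess()` tokenizes abstracts on unicode word boundaries,
lowercases, removes stopwords (a small built-in function-word list,
`default_stoplist()`) and terms occurring fewer than `min_term_count`
times corpus-wide, and drops (with a report) documents left empty. In
pipelines the taxon search keywords themselves are added to the stoplist:
a term that was a retrieval criterion appears in essentially every
record, so it carries no topical information.

### Model selection by coherence and exclusivity

Two corpus-internal scores grade a fitted model, per topic:

* **Semantic coherence** (UMass form): over the topic's top terms,
  $\sum_{i>j} \log\left[ (D(w_i, w_j) + 1) / D(w_j) \right]$, where $D$
  counts documents containing the term(s). Topics whose top terms
  co-occur score higher; the $+1$ keeps absent terms finite.
* **Exclusivity**: the mean over top terms of
  $P(w \mid k) / \sum_{k'} P(w \mid k')$, in $(0, 1]$; 1 means the top
  terms carry no mass under any other topic, $1/K$ means all topics are
  identical.

`select_topic_number()` fits each candidate $K$, min-max normalizes the
two mean scores across the grid, and picks the $K$ maximizing their
unweighted mean — too few topics merge unrelated themes (coherence
falls), too many split themes into duplicates (exclusivity falls). Ties
go to the smaller $K$, and the full score table is returned for human
review. Selection scores the top 30 terms per topic rather than the
reporting default of 5–10: a topic that merges two themes can rank one
theme's terms entirely above the other's, so a narrow scoring window can
miss the merge; a wider window reaches past the first run of near-tied
terms. Selection also uses 3 restarts per candidate, since score
comparisons across $K$ are only meaningful at each $K$'s posterior mode.

## Keyword filtering and thematic coding

`filter_by_keywords()` applies the include/exclude rule used when
refining taxon search terms: keep a record iff at least one include term
matches and no exclude term matches, exclusion overriding inclusion.
Matching is case-insensitive; Latin-script terms match on word boundaries
(multi-word terms as contiguous phrases, whitespace-flexible), while
terms containing non-Latin characters (pinyin with diacritics, CJK) match
as literal substrings, since word boundaries are not meaningful there. A
ready-made specification for six heavily traded taxa ships in
`inst/extdata/keywords_six_taxa.yaml`, including classic confounders such
as the fruit-fly gene that shares the pangolin's name.

Thematic coding (`build_codebook()`, `label_records()`,
`iterate_labeling()`) mirrors how analysts code patents against use
categories: each label's keywords are the top five non-generic LDA terms
of its topics plus configured standard terms (e.g. "disorders", "pain"
under medicine), with provenance recorded per keyword. "Generic" means
the stoplist plus terms in more than half of all documents
(`generic_terms()`). Labels are non-exclusive, every assignment is backed
by a stored (record, label, keyword) triple, and labeling iterates: while
any record is uncovered, an expansion policy proposes new keywords and
the corpus is re-labelled. The shipped automated policy
(`lda_expansion_policy()`) appends each uncovered record's most frequent
non-generic term to its dominant topic's label — a deterministic,
testable stand-in for the manual review round the workflow normally
includes; passing a custom policy function is the hook through which
human keyword edits enter. Coverage is monotone because keywords are only
ever added, and a policy that adds nothing while coverage is below 1
terminates with an explicit `"stalled"` status.

`cumulative_label_proportions()` produces diversification curves: for
each month, each label's share of all label **assignments** to patents
filed so far. The denominator counts assignments, not records — a patent
coded both medicine and synthetics contributes to both — so the curves
describe the composition of commercial attention, and rows sum to 1 from
the first labeled filing onward.

## Trend statistics

`yearly_percent_changes()` computes January–December totals and
year-on-year percentage changes, skipping (and recording) years whose
previous year had zero filings, and `mean_percent_change()` averages the
defined changes. The comparison window's start and end years are
deliberately **required** arguments: different analyses legitimately
start such comparisons at different times (e.g. the first year all taxa
are present vs. the first year all are actively patenting), so the
package never picks one silently. `period_median()`, `peak_month()`
(earliest month at the maximum) and `smooth_series()` (centered moving
average, truncated at the edges) complete the summary. The smoothing
window must be odd for a centered average; the default of 13 months is
the odd window closest to one year.

## The synthetic-data generator

Real patent scrapes are encumbered by the filing entities' copyright, so
every stage is exercised against `simulate_patent_corpus()`, which
generates corpora with known ground truth:

* per-taxon monthly counts from the NB2 changepoint process above
  (defaults: 120 months, jump from 2 to 10 filings/month at month 60,
  $\phi = 1$ both sides — a strong but realistically noisy shift);
* abstracts as bags of pseudo-word tokens from a planted LDA process
  (default 3 topics over a 400-term vocabulary, ~50 tokens per document,
  document-topic concentration 0.2 so documents are mostly single-theme,
  as short abstracts are; `disjoint_topics = TRUE` partitions the
  vocabulary among topics for fully separable ground truth);
* one taxon include keyword injected into every record, and a
  `decoy_fraction` (default 0.1) of records additionally carrying an
  exclusion term such as "drosophila";
* priority dates uniform within each record's month (monthly aggregation
  is the only consumer of the day), CN-weighted jurisdictions.

What the generator does **not** emulate: real legal language (tokens are
Latin-script pseudo-words, so tests are tokenizer-neutral), multilingual
text, patent families, duplicated filings across offices, or
non-stationary vocabulary drift. Passing tests therefore demonstrate
that the algorithms recover planted structure under realistic noise, not
that any particular real-world corpus is free of confounding.

## Numerical choices and degenerate inputs

* Truth-recovery comparisons align fitted to planted topics by
  best-match over permutations of per-topic total-variation distance.
* The quadrature oracle refuses series longer than 120 months rather
  than silently degrading.
* `nb_log_pmf()` validates its domain and delegates the evaluation to R's
  `dnbinom(size = phi, mu = mu)`; the test suite checks it against an
  independent term-by-term log-gamma evaluation.
* Earliest-month tie-breaks: `peak_month()` and `which.max` over
  `tau_probs` both return the earliest maximum.
* Records with unparseable or impossible dates (e.g. month 13) are
  collected into a line-numbered error report, never silently dropped;
  deduplication keeps the earliest priority date per identifier.
* All stochastic stages are seeded; the pipeline derives every stage
  seed deterministically from one global seed, and stage outputs are
  plain files, so a run is a pure function of (config, seed) at the level
  of written artifacts.

## Problem sizes

The shipped tests and the acceptance script run the changepoint
experiments at 120-month series (20 replicate fits), oracle comparisons
at 48 months, and topic experiments at roughly 500 documents of ~50
tokens — sizes at which the planted-truth experiments are decisive while
a full run of suite plus script stays in the ten-minute range on a
single core. All of them scale up by configuration only.

## Known limitations

* The changepoint model fits one shift per (sub)segment; gradual ramps
  are approximated by the nearest abrupt shift, and the segmentation
  heuristic inherits the MAP split's errors.
* With heavy overdispersion ($\phi \approx 1$) even the exact posterior
  localizes a 5× rate jump only to within a few months on a minority of
  realizations; single months simply carry little information at
  variance $\mu + \mu^2$. Uncertainty statements should come from the
  full `tau_probs` distribution, not the MAP month alone.
* UMass coherence and probability-share exclusivity are corpus-internal
  proxies; they say nothing about human interpretability of topics.
* Keyword labeling is lexical: it cannot code a patent whose abstract
  expresses a theme only in words absent from the codebook, which is why
  the iteration-with-review loop exists.
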