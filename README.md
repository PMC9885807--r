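# vitroscreen

Citation-screening strategies for systematic reviews of *in vitro*
research, with the evaluation machinery to compare them.

Reviews of in vitro studies suffer from a specific failure mode: the
abstract often under-describes the in vitro experiments a paper contains,
so title/abstract (TiAb) screening — the standard first stage of a
systematic review — silently discards a meaningful share of relevant
records. `vitroscreen` is for meta-researchers and review teams who want
to quantify that loss and to automate around it. It implements:

* **Dictionary screening** — compile a term set (e.g. the oxygen–glucose
  deprivation exemplar: "oxygen–glucose deprivation", "OGD", "deprived of
  oxygen and glucose", …) into a single pattern, count non-overlapping
  matches in TiAb or full text, and include a record iff
  `count ≥ threshold` (1 for TiAb, 2 for full text at the packaged
  operating points).
* **Diagnostic-accuracy evaluation** — confusion matrices against a gold
  standard; sensitivity, specificity, precision; the distance to the
  perfect operating point
  `d = sqrt((1 − sens)² + (1 − spec)²)` (smaller is better, 0 is
  perfect); step-curve ROC with trapezoidal AUC (equal to the
  Mann–Whitney statistic); threshold selection by minimal `d` or by a
  target sensitivity (default 0.95); corpus-scale projection of an
  operating point (expected wrong inclusions/exclusions in a corpus of
  millions).
* **A trainable screening classifier** — word 1–3-gram bag-of-words
  features, a linear SVM trained by stochastic gradient descent (hinge
  loss, L2 penalty, seeded shuffles; compiled inner loop), and
  Platt-calibrated inclusion scores in \[0, 1\] fitted on out-of-fold
  margins, plus recall-targeted thresholding.
* **Error correction** — rank records by `|human label − machine score|`,
  rescreen the top *k* through an oracle, retrain, and report the
  before/after validation metrics.
* **Dual-reviewer reconciliation** — two independent reviewers plus
  third-reviewer arbitration, and gold-standard construction that routes
  cross-method conflicts to a senior re-evaluation oracle.
* **A seeded synthetic corpus generator** — labeled corpora with
  realistic prevalence (~6%), long-tailed match-count distributions,
  abstract omission (~14% of relevant records carry no TiAb signal), an
  overlapping two-pool topic vocabulary, and simulated reviewers with
  independent error rates — so the whole pipeline is testable offline.

## Worked example

Generate a synthetic review corpus, run the four-method comparison, and
train the classifier:

```r
library(vitroscreen)

corp <- generate_corpus(synthetic_spec(n_records = 2000,
                                       prevalence = 0.062), seed = 42)
run_comparison(corp, seed = 42)
#> Screening-method comparison over 2000 records ( 2000 with full text )
#>          method    n  tp   tn fp fn sensitivity specificity precision     d   auc threshold
#>      human_tiab 2000  98 1860  1 41       0.705       0.999     0.990 0.295    NA        NA
#>  human_fulltext 2000 132 1861  0  7       0.950       1.000     1.000 0.050    NA        NA
#>      regex_tiab 2000 121 1849 12 18       0.871       0.994     0.910 0.130 0.934         1
#>  regex_fulltext 2000 139 1830 31  0       1.000       0.983     0.818 0.017 1.000         2
```

The pattern of the real study reappears: human TiAb screening has the
worst sensitivity (here 0.705 — the generator omits the term from ~14% of
relevant abstracts, and simulated reviewers add their own errors), while
the full-text dictionary screen recovers essentially all relevant records
at a modest precision cost. `d` summarizes each row's distance from
perfect performance.

Counting matches directly:

```r
p <- build_term_pattern(ogd_term_set())
count_matches("Cells deprived of oxygen and glucose (OGD) for 4 h; OGD reduced survival.", p)
#> [1] 3
```

Evaluating published-style confusion counts:

```r
metrics(confusion_matrix(tp = 275, tn = 4846, fp = 7, fn = 44))
#> sensitivity: 0.862  specificity: 0.999  precision: 0.975  d: 0.138
```

Training the classifier with one error-correction round:

```r
study <- run_classifier_study(
  generate_corpus(synthetic_spec(n_records = 2500, prevalence = 0.30),
                  seed = 42), seed = 42)
study
#> Classifier study (seed 42 )
#>  initial   (threshold 0.83 ): sensitivity: 0.955  specificity: 0.997  precision: 0.993  d: 0.045
#>  corrected (threshold 0.83 ): sensitivity: 0.955  specificity: 0.997  precision: 0.993  d: 0.045
#>  decisions reversed in correction: 0
```

(The default oracle confirms every label, so nothing is reversed; supply
rescreening verdicts via `oracle =` to exercise the correction loop.)

A thin CLI over the same functions ships in `inst/scripts/vitroscreen`
(`screen`, `evaluate`, `simulate` subcommands).

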