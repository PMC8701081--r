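# litprior

Identifying research priorities from a time-stamped literature corpus.

When a health emergency hits, thousands of papers appear within months.
Funders, journal editors and research strategists need to know: which
research fields (hotspots) is the community working on, how is effort
shared between them over time, and which fields responded fastest?
`litprior` implements a complete metric pipeline for these questions over
any table of publication records with abstracts and day-level publication
dates (e.g. a CORD-19-style metadata CSV), and ships a synthetic corpus
generator with planted ground truth so every stage can be validated end
to end.

## The model

**Hotspot discovery.** Abstracts are cleaned (stopwords and scientific
boilerplate removed, lemmatized; lemmas with absolute frequency < 4 or
document frequency > 80% pruned) and encoded as a TF-IDF matrix
`R (n docs x m lemmas)`. Non-negative matrix factorization finds
`W (n x k)` and `H (k x m)` minimizing

    f(W, H) = 1/2 * sum_ij (R_ij - (WH)_ij)^2,   W, H >= 0

solved by alternating nonnegative least squares (HALS; monotone in the
objective) from a deterministic NNDSVD-ar start. Each row of `H` is a
topic; its top-5 lemmas are the hotspot keywords. The number of topics is
chosen on a grid by combining a subsample top-term stability score (mean
Hungarian-matched average-Jaccard agreement) with a symmetric
Kullback–Leibler divergence between the singular-value spectrum of `H`
and the column-norm spectrum of `W`.

**The metric suite.** The study period is cut into `w`-day windows
(default 7). For topic `t` and window `w`:

- `REC(t, w)` — Research Effort Coverage: the fraction of the window's
  publications assigned to `t`; its monotone trend is tested by the
  tie-corrected Mann–Kendall test (`Z_MK`, 95% confidence).
- `B(t, w)` — research time distance: mean days from the outbreak
  starting point to the cell's publication dates.
- `E(t, w)` — topic information entropy: Shannon entropy of the cell's
  renormalized membership probabilities `p(d|t)`, damping topics whose
  membership is carried by a handful of documents.
- `RRR(t, w) = sum_{d in D(t,w)} p(d|t) / (B(t,w) * E(t,w))` — the
  Research Response Rate: probability mass published per unit delay and
  uncertainty; high early values mark urgent fields.

**Classification.** Each topic's RRR trajectory is typed as *emergency*
(peak in window 1, then decay), *persistent* (peak in window 2, slow
decline) or *fluctuating* (large swings), and combined with the REC trend
into a priority region `<E|P|F>-<1|2|3>` (1 = significantly decreasing
coverage, 2 = stable, 3 = significantly increasing).

## Worked example

Generate a synthetic stream with three planted archetypes, fit the
pipeline, and classify:

```r
library(litprior)

spec   <- synthetic_spec(k_true = 3,
                         profiles = c("emergency", "persistent", "fluctuating"),
                         seed = 2024)
corpus <- generate_corpus(spec)

tokens <- tokenize_abstracts(corpus$records)
tm     <- build_tfidf(tokens, build_vocabulary(tokens))
tm
#> <term_matrix> 1272 documents x 220 lemmas (TF-IDF, 35,004 nonzeros)

model <- fit_nmf(tm, k = 3, seed = 1)
model
#> <nmf_model> k = 3, 1272 documents x 220 lemmas
#>   objective = 78396 after 4 sweeps (converged)

rpm <- rpm_table(assign_documents(model), doc_topic_probability(model),
                 corpus$records,
                 partition_windows(spec$period, w_days = 7, n_windows = 10),
                 "2019-12-12")
priority_report(classify_priorities(rpm), top_terms(model))
#> # A tibble: 3 x 5
#>   topic_id keywords                          type        trend_symbol region
#>      <int> <chr>                             <chr>       <chr>        <chr>
#> 1        0 vjnax, vkhax, vwoax, vblax, vtlax fluctuating o            F-2
#> 2        1 vkmax, vsjax, vyaax, vqeax, vhdax persistent  o            P-2
#> 3        2 vibax, vojax, vcbax, vonax, vkgax emergency   o            E-2
```

Each fitted topic recovers the temporal archetype that was planted for
it: the emergency topic's RRR peaks in the first window (0.00106,
falling to 0.00043 by window 2 and onward), the persistent topic peaks
in window 2, and the fluctuating topic alternates. The `o` trend symbol
says no topic's coverage trend is significant here (all three archetypes
were generated at comparable overall volume); significant trends are
marked `+**` / `-**`. `autoplot(rpm, metric = "rrr")`,
`autoplot(classify_priorities(rpm))` and `autoplot(select_k(tm, 2:8))`
draw the corresponding trajectory, region-grid and diagnostic figures.

Real corpora enter through `read_metadata(path, "cord19_csv")` (columns
`abstract`, `publish_time`) or a JSONL dialect, then
`filter_records()` for the empty/non-English/out-of-period cleaning, or
through `run_pipeline(pipeline_config(...))`, which chains every stage
and writes CSV/JSON artifacts plus a reproducibility manifest
(`inst/scripts/run-pipeline.R` is a shell wrapper around it).

## Acceptance script

`scripts/acceptance.R` regenerates a planted-truth synthetic corpus from
the given seed and runs the complete pipeline — preprocessing,
topic-number selection over a grid, NMF, the RPM metric suite, and
type/region classification — writing its result JSON to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Pipeline artifacts (diagnostics, RPM table, priority report, manifest)
land next to the output file under `pipeline-artifacts/`.
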