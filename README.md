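# ehrwindows

Tools for asking a clinical question of electronic health records (EHRs)
linked to hospital admission data: **does the month before a hospitalised
suicide attempt look different — in how much clinicians document, and in
the language they use — from a low-risk period a year earlier?**

The package is aimed at mental-health informatics researchers working
with case-register EHR data (free-text clinical notes with timestamps)
linked to Hospital Episode Statistics (HES) style admission records. The
real data behind such studies are access-restricted, so `ehrwindows`
ships a seeded synthetic-EHR generator with known ground truth; every
analysis stage is exercised and validated against planted structure
without any clinical data.

## What it computes

* **Cohort.** HES consultant episodes are consolidated into admission
  spells (episodes that overlap or abut merge); a spell is
  suicide-related if any episode's ICD-10 code falls in X60–X84, Y10–Y34,
  or is exactly Y87.0/Y87.2. Patients are aligned at their first
  suicide-related admission.
* **Documentation rate.** MonitoringLevel_W — documents in the preceding
  W days divided by W (30 documents in the preceding 30 days ⇒ level 1) —
  and attempt-aligned coverage trajectories: at each day offset, the
  fraction of monitored patients with a recent document.
* **Proximal / distal corpora.** Documents 31–1 days before a
  suicide-related admission (proximal) versus 365–300 days before one
  with a 300-day clearance from any earlier suicide-related discharge
  (distal); documents of ≤ 100 characters are dropped.
* **Word discrimination.** Per word w, the document-level 2×2 table
  (a = proximal documents containing w, b without; c, d distal), odds
  ratio ad/bc with Haldane–Anscombe +0.5 on zero cells, two-sided Fisher
  exact p-value, and the retention rule p ≤ 0.05 with OR < 0.66 or
  OR > 1.50.
* **Categories and agreement.** Exposure odds ratios for clinician-defined
  word groups; inter-annotator confusion matrix, per-category
  precision/recall/F1, Cohen's kappa.
* **N-gram Naive Bayes.** Two-class multinomial models over uni/bi/tri-
  grams (additive smoothing), top-k features by class log-likelihood
  difference, each with its OR, mean per-document frequency, and
  distinctiveness threshold t\* (the smallest per-document count at which
  presence-at-≥t passes the retention rule).

## Worked example

```r
library(ehrwindows)

cfg <- simulation_config(n_patients = 200, seed = 11)
bundle <- run_pipeline(cfg, offsets = c(-180, -90, -30, -1))
bundle
#> ehrwindows report bundle
#>   80 patients with documents, 16711 documents, 512 episodes -> 341 admissions (200 suicide-related)
#>   corpus: 2239 labelled documents from 63 patients
#>   words retained by OR/p filter: 26 of 41
#>   annotator agreement kappa: 1.000

bundle$trajectory
#> # A tibble: 4 x 4
#>   offset numerator denominator fraction
#>    <int>     <int>       <int>    <dbl>
#> 1   -180        40          72    0.556
#> 2    -90        46          76    0.605
#> 3    -30        50          78    0.641
#> 4     -1        57          79    0.722
```

The trajectory rows read: 180 days before the attempt, 72 patients were
under monitoring and 40 of them (55.6%) had a document in the preceding
30 days; by the day before the attempt that coverage has risen to 72.2% —
the generator's planted documentation ramp, recovered by the monitoring
stage. The word table from the same run recovers the planted enrichment:

```r
head(bundle$word_stats[, c("word", "a", "c", "odds_ratio", "p_value", "retained")], 6)
#>   word          a     c odds_ratio   p_value retained
#> 1 overdose   1201   484     13.0   1.07e-119 TRUE
#> 2 plan        164   505      0.128 1.09e- 96 TRUE
#> 3 tablet     1065   372      7.34  5.44e-101 TRUE
#> 4 self-harm  1070   391      6.94  1.08e- 94 TRUE
#> 5 review      161   452      0.157 1.39e- 76 TRUE
#> 6 take        613   122      6.14  1.44e- 71 TRUE
```

"overdose" appears in 1,201 proximal versus 484 distal documents
(OR 13.0, proximal-enriched, retained); "plan" and "review" lean the
other way (OR ≪ 0.66, the planted "protective" direction). The
`feature_reports` element carries the analogous Naive Bayes n-gram
rankings.

The methods vignette (`vignettes/ehr-documentation-windows.Rmd`)
documents the model, every boundary convention, the generator's design
and its limitations.

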