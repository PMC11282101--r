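# metsubtype

Transcriptomic subtype discovery and classification for **MET exon 14
skipping (METex14) non-small cell lung cancer**, as a reusable, tested R
pipeline.

METex14 NSCLC is treated as a single entity when MET inhibitors are
prescribed, yet patients respond very differently. This package implements
a complete molecular-subtyping workflow that explains that heterogeneity
from bulk (targeted) RNA-seq: per-sample pathway enrichment scores feed a
consensus-clustering subtype discovery step; the resulting subtypes are
characterized statistically (differential expression, tumor
microenvironment signatures, somatic variant filters, mutational-signature
refitting, survival association); and an odds-ratio-screened
lasso-multinomial classifier makes the subtypes portable to new cohorts.
A synthetic-cohort generator reproduces the statistical structure of the
motivating study — four pathway-programmed subtypes (MET-driven,
FGFR-activated, immune-activated, bypass/multi-pathway), subtype-linked
disease-free-survival hazard (subtype A worst), and per-sample METex14
variant allele frequency (subtype A highest) — so the whole pipeline is
exercised end-to-end without restricted patient data.

## The methods in brief

* **Normalization** — `log2(FPKM + 1)` followed by column quantile
  normalization (ties receive the mean of the reference values they span).
* **Per-sample enrichment (ssGSEA-style)** — for sample *j* and gene set
  *S*, genes are ranked by expression and the score is
  `ES(S, j) = Σ_i [ P_in(i) − P_out(i) ]`, the summed gap between the
  rank-weighted (`rank^τ`, default τ = 0.25) in-set CDF and the uniform
  out-of-set CDF along the ranking.
* **Consensus clustering** — columns are subsampled (fraction 0.8, 250
  resamples) and partitioned per resample (average-linkage hierarchical by
  default, k-means++ optional) for k = 2…6; consensus(i,j) = co-cluster
  count / co-sample count. k is selected by the relative Δ-AUC of the
  consensus CDF (largest k with Δ > 0.05); final labels cut an
  average-linkage tree on 1 − consensus.
* **Classifier** — per subtype, one-vs-rest univariate logistic
  regressions on z-scored genes rank genes by odds ratio; top 10 + bottom
  10 per subtype form an 80-gene panel; lasso-multinomial regression
  (λ by stratified CV, 1-SE rule) selects the final genes; a
  ridge-stabilized multinomial refit is serialized as JSON. Validation is
  by repeated stratified 5-fold CV (full pipeline re-run inside every
  fold) and leave-one-out CV.
* **Survival** — Kaplan–Meier, log-rank, and Cox proportional hazards
  (Efron ties) via the `survival` package.
* **Genomics** — the four-step somatic variant filter (≥5 alt reads & ≥5%
  VAF; ≤2% population frequency; CDS; oncogenic) with first-failure
  attribution, and non-negative least-squares refitting of 96-context
  mutational-signature exposures with cosine quality-of-fit.
* **In-silico RT-PCR** — exon-skipping transcript models and amplicon
  sizing reproduce the canonical 246-bp wild-type / 106-bp
  exon-14-skipped band shift.

## Worked example

```r
library(metsubtype)

cohort <- simulate_cohort(cohort_config(seed = 7))
#> synthetic_cohort: 120 samples x 2000 genes; subtypes A=42 B=15 C=24 D=39

norm   <- log_quantile_normalize(cohort$expression)
scores <- ssgsea_scores(norm, fixture_gene_sets(cohort))
cons   <- consensus_cluster(scores, seed = 11)
#> consensus_result: k in [2, 6], selected k = 4
#>   k       auc   delta_auc
#> 1 2 0.3563477 0.356347704
#> 2 3 0.6340336 0.779255504
#> 3 4 0.7222689 0.139165010
#> 4 5 0.7308656 0.011902395
#> 5 6 0.7377993 0.009486858
```

The Δ-AUC column is the model-order evidence: big gains up to k = 4, then
~1% — so four subtypes are selected, matching the four planted programs.

```r
scr <- screen_leading_genes(norm, cons$labels)
#> screen_result: 4 subtypes x (10 top + 10 bottom) -> 80-gene panel
las <- fit_lasso_multinomial(unclass(norm)[scr$panel, ], cons$labels,
                             seed = 11)
#> lasso: 71 of 80 genes selected (rule 1se)
model <- refit_final(norm, cons$labels, genes = las$selected)
cv <- repeated_cv(norm, cons$labels, iterations = 2, seed = 11)
#> repeated 5-fold CV accuracy (2 iterations): 1.000

d <- data.frame(time = cohort$survival$time, event = cohort$survival$event,
                subtype_A = as.integer(cons$labels == "A"))
cox_fit(d, "subtype_A")
#>   covariate      term       hr ci_lower ci_upper            p
#> 1 subtype_A subtype_A 8.478515 4.503947  15.9605 3.523335e-11
```

Subtype A carries the planted excess hazard (true HR 6.68 lies inside the
Wald CI). The exon-skipping sanity check:

```r
tm   <- metex14_transcript_model()
pair <- build_skipping_pair(tm)
insilico_pcr(pair$wildtype, tm$primer_fwd, tm$primer_rev)  # 246
insilico_pcr(pair$skipped,  tm$primer_fwd, tm$primer_rev)  # 106
```

## Command line

```sh
exec/metsubtype simulate --seed 3 --out cohort_dir
exec/metsubtype discover --config cfg.json
exec/metsubtype validate --config cfg.json --model out/model.json
```

`cfg.json` is the JSON form of `pipeline_config()`; `discover` writes
labels, enrichment scores, consensus statistics, DGE tables, the
serialized model, CV metrics, survival associations and a run report into
the configured output directory.

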