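# tlsmeta

Tools for evaluating and discovering **tertiary lymphoid structure (TLS)**
gene-expression signatures across immune-checkpoint-blockade (ICB) cohorts.

TLS — organized lymphoid aggregates forming inside tumors — predict favorable
prognosis and ICB response, but are usually assessed through small surrogate
gene signatures. `tlsmeta` is for computational oncologists who want to
benchmark such signatures across many cohorts, or derive a new one, with
every statistical step testable against ground truth:

* **Scoring** — per-cohort z-scoring, a deterministic rank/running-sum
  single-sample enrichment score (ssGSEA family, "maxdiff" statistic on
  z-scored values), the COX-IS pro/anti-tumor inflammation log-ratio, TMB
  (nonsynonymous mutations per Mb), and median stratification.
* **Per-cohort effects** — univariate Cox (Breslow ties) for survival and
  univariate logistic regression for R/NR response with an automatic Firth
  (Jeffreys-prior) fallback under separation; responder labels follow RECIST
  plus the 6-month PFS rule.
* **Meta-analysis** — fixed-effect inverse-variance and DerSimonian–Laird
  random-effects pooling of per-cohort log hazard/odds ratios:
  ω<sub>k</sub> = 1/s<sub>k</sub>², θ̂ = Σθ̂<sub>k</sub>ω<sub>k</sub>/Σω<sub>k</sub>,
  τ² = max(0, (Q − (K−1))/(Σω − Σω²/Σω)), with Cochran's Q, I², z-test,
  BH-FDR and hot/cold subgroup pooling.
* **Discovery** — zero-expression filtering, per-gene meta-analyzed log odds
  ratios, and a cutoff sweep (0 → 0.5, step 0.005) over the signed pooled
  logOR that selects the signature maximizing mean discovery-cohort response
  AUC (ties toward the smaller signature), validated on held-out cohorts by
  AUC, DeLong comparisons, Cox OS association and Kaplan–Meier splits.
* **Spatial evaluation** — spot-level enrichment scoring and TLS-detection
  AUC against spot annotations, summarized by TLS maturity.
* **Synthetic ground truth** — a multi-cohort generator planting a latent TLS
  program (plus an outcome-free decoy module) into expression, response,
  survival, mutation and spatial-grid data, fully seed-deterministic.

The bundled `predict_tls_signature()` carries the 17-gene PredictTLS set
(CCL8, CXCL9, CXCL10, CXCL11, CXCR3, CCR3, CCR5, ICAM1, CXCL13, CD40, CD38,
DERL3, SSR4, PDCD1, TIGIT, CD274, PIM2) and `coxis_genes()` the COX-IS CP/CI
lists, both as GMT fixtures.

## Worked example

The end-to-end demonstration simulates 6 discovery + 3 validation ICB cohorts
with a 15-gene planted program among 74 candidates, runs the full
benchmark — scoring, per-cohort effects, meta-analysis, discovery sweep,
held-out validation, spatial evaluation — and reports recovery against the
planted truth:

```r
library(tlsmeta)
res <- run_benchmark(default_config(seed = 1))

cat("selected cutoff: ", res$sweep$selected_cutoff, "\n")
cat("signature size:  ", length(res$sweep$signature), "\n")
cat("jaccard vs truth:", round(res$recovery, 3), "\n")
cat("validation AUC:  ", round(res$validation$mean_auc, 3), "\n")
print(res$signature_meta$response$per_signature$planted_program$random)
print(res$spatial$summary)
#> selected cutoff:  0.15
#> signature size:   21
#> jaccard vs truth: 0.714
#> validation AUC:   0.847
#> <meta_result> random-effect pooling of 9 studies
#>   pooled = 1.6370 (se 0.1782), z = 9.19, p = 3.99e-20
#>   Q = 13.847, tau2 = 0.1163, I2 = 42.2%
#>   maturity_label n_samples   min_auc median_auc   max_auc
#> 1       immature         2 0.9928392  0.9946028 0.9963663
#> 2         mature         2 1.0000000  1.0000000 1.0000000
#> 3       negative         2        NA         NA        NA
```

Reading the output: the sweep picked cutoff 0.15, yielding a 21-gene
signature that overlaps the planted truth at Jaccard 0.714 and predicts
response in the held-out cohorts with mean AUC 0.847. The random-effects
meta-analysis pools the planted program's per-cohort log odds ratios to 1.64
per z-unit (strongly positive, as planted), with moderate heterogeneity
(I² = 42%). Spot-level detection is near-perfect for mature TLS disks and
slightly weaker for immature ones, mirroring the expected maturity ordering.
At this deliberately small demo scale a few noise genes ride along; the
larger benchmark below recovers the planted set exactly.

Passing `out_dir =` writes the artifact bundle (effect tables, gene meta
table, sweep curve, signature GMT, validation JSON, spatial reports) plus a
manifest with per-file MD5 hashes; identical config + seed reproduces
identical files. The methods vignette
(`vignettes/tls-signature-meta-analysis.Rmd`) documents the models,
parameter choices and limitations.

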