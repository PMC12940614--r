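---
title: "TLS signature scoring, meta-analysis and discovery: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TLS signature scoring, meta-analysis and discovery: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlsmeta)
```

## The problem

Tertiary lymphoid structures (TLS) are organized lymphoid aggregates that form
inside tumors and are associated with favorable prognosis and response to
immune checkpoint blockade (ICB). Because direct histological TLS assessment
is expensive and observer-dependent, transcriptomic TLS signatures — small
gene sets whose coordinated expression marks TLS presence — are used as
surrogates. `tlsmeta` implements the full statistical workflow for evaluating
such signatures across many ICB cohorts and for constructing a new one:
single-sample scoring, per-cohort effect estimation, random-effects
meta-analysis, a log-odds cutoff sweep for de novo signature selection,
held-out validation by response AUC and survival association, and spot-level
evaluation on spatial transcriptomics. A synthetic multi-cohort generator
with a planted TLS program provides ground truth for every stage, so each
claim the package makes about its methods is checked against a known answer.

## The data model

Expression arrives as a genes × samples matrix on the log2(x + 1) scale (the
convention of RSEM-normalized public compendia). Clinical records carry RECIST
response categories, progression-free survival (PFS) and overall survival
(OS) with event indicators, and tumor mutational burden (TMB). Responders are
CR/PR or SD without a PFS event within 6 months; non-responders are PD or SD
with an event by month 6; SD with missing PFS is non-assessable and excluded
from response models (`classify_response()`). This rule is also the exact
inverse of the RECIST assignment in the simulator, so labels and ground truth
never drift apart.

## Scoring

**Z-scoring** (`zscore_expression()`) centers and scales each gene over the
samples of one cohort, with the population-SD (divisor *n*) convention and
constant rows mapped to zero and flagged. Scoring is always per cohort, never
pooled: ICB cohorts differ in platform and depth, and pooled z-scores would
let cohort effects masquerade as biology.

**Enrichment** (`gsva_like_score()`) is a deterministic rank/running-sum
statistic of the ssGSEA family, applied to z-scored values. For each sample,
genes are ranked by z descending (stable tie-break by input order); the
running sum gains $|z|^\tau$ (normalized over the in-set genes) at in-set
positions and loses $1/(G-m)$ at out-of-set positions; the score is the
maximum positive plus the minimum negative deviation ("maxdiff"), bounded in
$[-1, 1]$. We chose this statistic over a kernel-CDF variant because it is
fully specifiable — every value is reproducible from the definition with no
density-estimation dialect — and because all downstream analyses only require
a monotone measure of coordinated set activity. $\tau = 1$ is the default;
$\tau = 0$ gives a purely rank-based score. Degenerate cases are pinned down:
a set spanning all genes scores +1, and all-zero z-columns fall back to
uniform increments.

**COX-IS** (`coxis_score()`) summarizes the balance of pro-tumor (CP, 9
genes) versus anti-tumor (CI, 15 genes) inflammation as
$\log_2\!\big(\overline{2^{x}-1}^{\,CP} + \varepsilon\big) -
\log_2\!\big(\overline{2^{x}-1}^{\,CI} + \varepsilon\big)$ with
$\varepsilon = 10^{-6}$: expression is mapped back to the linear scale,
averaged within each list, and contrasted as a log ratio. The log-ratio form
makes the score invariant to global multiplicative rescaling, which is the
property a cross-cohort inflammation-balance score must have.

**TMB** (`tmb()`) is nonsynonymous mutations (missense + frameshift indel +
stop codon) per megabase, 38 Mb by default. `median_stratify()` splits any
score at its median with ties deterministically assigned to "low"; the
alternative (ties high) changes nothing downstream except group labels at
exactly the median, and a fixed rule keeps runs reproducible.

## Per-cohort effects and meta-analysis

Response is modeled by univariate logistic regression of R/NR on the
(z-scaled) score; survival by a univariate Cox model with Breslow tie
handling (Efron available by option). Both report the log-scale effect with
its Wald standard error and two-sided p. Small ICB cohorts make complete
separation a real possibility, so the logistic path detects it (divergent
coefficient or exploding SE) and refits with Firth's Jeffreys-prior
penalization, returning a finite flagged estimate instead of silently
diverging.

Cohort effects $\hat\theta_k$ with standard errors $s_k$ are pooled by
inverse variance: fixed-effect weights $\omega_k = 1/s_k^2$,
$\hat\theta = \sum_k \hat\theta_k \omega_k / \sum_k \omega_k$. The
random-effects model uses the DerSimonian–Laird moment estimator
$\tau^2 = \max\!\big(0, (Q - (K-1)) / (\sum\omega_k -
\sum\omega_k^2/\sum\omega_k)\big)$ and weights $1/(s_k^2+\tau^2)$. The
overall-effect test is a plain normal z-test (no Knapp–Hartung adjustment),
and both models are always available side by side, since fixed- and
random-effects summaries answer different questions when cohorts are
heterogeneous. Multiplicity is controlled by Benjamini–Hochberg FDR, one
family per outcome × cohort-set analysis, significance at FDR ≤ 0.05.
Subgroup pooling (`subgroup_meta()`) runs the same machinery within strata
such as the bundled hot/cold cancer-type lists.

## De novo discovery

Candidates are first filtered: a gene with more than 50% zero expression in
any discovery cohort is dropped (exactly 50% is kept). Each surviving gene is
z-scored within cohort, fit against response by the logistic model, pooled by
DL meta-analysis, and FDR-adjusted across genes (`per_gene_meta_logor()`).
Genes are then ranked by *signed* pooled log odds ratio and swept over
cutoffs 0 to 0.5 in steps of 0.005 (101 cutoffs): at each cutoff the
signature is the set of genes with pooled logOR at or above it
(`rank_and_sweep()`). Negatively associated genes are reported but never
included — a sweep on the positive scale is only meaningful for a signature
whose activity should predict response.

The selection criterion is the package's own design choice: the cutoff
maximizing the mean response AUC of the signature's enrichment score across
the discovery cohorts, with ties broken toward the larger cutoff (smaller
signature). Maximizing discovery AUC matches the stated goal of the sweep —
association with immune response — and the parsimony tie-break protects
against dragging in weakly associated genes that cannot hurt the training
AUC but add noise at validation. `validate_signature()` evaluates the result
only on cohorts disjoint from discovery (overlap is a hard error, not a
warning), reporting per-cohort AUC, DeLong comparisons against competitor
signatures, pooled Cox association with OS, and Kaplan–Meier summaries at the
median split.

## Spatial evaluation

`score_spots()` z-scores genes across the spots of one section and computes
the same enrichment score per spot; `spot_auc()` measures how well spot
scores recover the annotated TLS regions, with the positive class defined as
*any* annotated TLS spot (mature or immature). The alternative — excluding
immature spots in mature sections — was considered and rejected: it changes
the denominator between sections and makes per-section AUCs incomparable.
Sections whose annotation has a single class (TLS-negative samples) report a
missing AUC rather than an error, and `maturity_summary()` aggregates
min/median/max AUC per maturity group.

## The synthetic generator

`simulate_cohorts()` draws, per patient, a latent TLS activity
$a \sim N(0,1)$. Signature genes load on it
($x_g = \text{baseline}_g + \beta_g a + N(0, \sigma)$, clipped at 0 on the
log2 scale); one decoy module of genes shares its own latent factor but has
no link to outcome, so mere co-expression cannot masquerade as signal in the
discovery sweep; all remaining genes are independent noise. Response is
Bernoulli with logit $\alpha_k + \gamma a$ (cohort intercepts $\alpha_k$ are
exposed rather than fixed, because real ICB cohorts do not pin down response
prevalence); OS is exponential with hazard $\lambda e^{\delta a}$ under
uniform censoring on $[0.01, 2/\lambda]$, which yields roughly 30–50%
censoring, typical of ICB trials. RECIST categories and PFS are drawn
consistently with the responder rule. `simulate_spatial()` places
non-overlapping disks on a full grid and raises signature-gene expression
inside them by `effect` (mature) or `effect/3` (immature);
`simulate_mutations()` draws lognormal nonsynonymous totals split into
consequence classes. Every generator takes a mandatory seed, runs on a
private RNG stream, and is byte-reproducible.

What the generator does **not** emulate: single-cell count sparsity and
library-size variation, batch effects, platform differences between cohorts,
correlated clinical covariates (age, stage), or irregular TLS shapes.
Passing tests therefore demonstrate that the statistical machinery is
correct and calibrated under the stated model — not that any fixed gene set
generalizes to real tumors.

## Study conditions used by the tests and the acceptance script

The discovery benchmark uses 10 discovery cohorts of 80 samples and 5
validation cohorts of 100 samples, 15 planted genes among 74 candidates in a
300-gene universe, $\gamma = 2$, $\delta = -0.5$ (a protective program),
noise SD 1. Under these conditions the sweep recovers the planted program
(Jaccard ≥ 0.8 against truth) and the held-out mean response AUC exceeds
0.75. The no-overfitting calibration reruns the identical pipeline with
$\gamma = 0$ on 6 + 3 cohorts of 50 samples, 100 replicates: selected
signatures must score chance-level (validation AUC within [0.4, 0.6] in at
least 90% of replicates). Null calibration of the testing paths uses 1000
replicates each. Spatial evaluation uses 20 × 20 grids with two disks of
radius 3 and effect 3; these sizes keep a full run in seconds while leaving
all comparisons informative.

## Numerical choices and edge cases

* Population-SD z-scores; constant genes flagged, scored as zero signal.
* Enrichment ties broken by stable input gene order; with $\tau = 1$ tied
  z-values carry equal weight, so scores do not depend on tie order.
* Median-split ties to "low"; degenerate (constant) inputs warn.
* Logistic IRLS converges on a step norm below 1e-10 with damped steps; Firth
  fallback triggers on non-convergence, |logOR| > 15, or SE > 50.
* Cox uses Breslow ties (simple, exactly matched by a brute-force partial
  likelihood); `ties = "efron"` is available.
* $\tau^2$ truncates at zero; $K = 1$ pooling returns the study itself.
* DeLong variance below 1e-14 with a zero AUC difference returns p = 1;
  with a nonzero difference it is an error.
* Permutation tests enumerate exactly when $\binom{n}{k} \le 20000$,
  otherwise seeded Monte Carlo with the add-one correction.
* All floating-point table output is written at 6 significant digits so that
  artifact hashes are portable across platforms.

## Known limitations

The enrichment statistic is one member of the ssGSEA family; other dialects
(kernel CDF, different normalizations) will give different absolute values,
though rank-consistent ones under strong signals. The generator's single
latent factor is a deliberate simplification — real TLS programs are
multi-factorial and partially confounded with overall immune infiltration.
Validation here is internal (held-out synthetic cohorts); nothing in the
package substitutes for validation on real ICB cohorts. The bundled 17-gene
PredictTLS set and COX-IS lists are fixtures for scoring real data; their
clinical utility is an empirical question outside the package's scope.
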