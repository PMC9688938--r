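---
title: "Scoring EMT, metabolic and immune-checkpoint programs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring EMT, metabolic and immune-checkpoint programs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

plastiscore quantifies, per sample, the activity of transcriptional
programs tied to epithelial–mesenchymal plasticity (EMT), energy
metabolism (glycolysis, OXPHOS, fatty-acid oxidation) and immune
checkpoints (PD-L1/CD274 and related genes), then aggregates pairwise
associations among those programs across many datasets and relates joint
PD-L1/glycolysis status to overall survival. This vignette explains each
model, the parameters that matter, the synthetic data used for
validation, and the design choices made where conventions diverge.

## Per-sample scoring models

### ssGSEA (integral running sum)

For one sample, genes are ordered by decreasing expression. Walking down
the ordered list, a running sum increases at each in-set gene by
$w_g / \sum_{g' \in S} w_{g'}$ and decreases at each out-of-set gene by
$1/(N - |S|)$, where the weight $w_g = r_g^{\alpha}$ uses the gene's rank
value $r_g$ (largest for the most highly expressed gene; ties receive
average ranks, and tied positions are ordered by gene symbol so results
are deterministic). The score is the **sum of the running-sum values over
all $N$ positions** — the integral form — not the maximum deviation used
by classical GSEA. The exponent defaults to $\alpha = 0.75$, the de-facto
convention of the ssGSEA tool family; it is exposed because published
descriptions rarely state it. Because only ranks enter, the score is
exactly invariant under any strictly increasing per-sample transform.

The normalized enrichment score (NES) divides all samples' raw scores by
$\max - \min$ across the scored cohort. **NES values are therefore
cohort-relative**: a sample's NES changes if the cohort around it
changes. This matters when comparing scores across datasets, which is why
the meta-analysis works with within-dataset correlations only.

### EMT metrics

Four complementary EMT quantifications are provided:

* **76GS** — a CDH1-anchored weighted sum over a 76-gene EMT list. Each
  list gene's weight is the Pearson correlation (Spearman by option) of
  its expression with CDH1 across the cohort; the per-sample score is
  $\sum_g w_g (x_g - \bar{x}_g)$ with per-gene mean-centering, so the
  cohort mean is zero. Higher = more epithelial. Mean-centering is
  applied even though some descriptions omit it: without it the score
  inherits platform-specific intensity offsets. Weights are cohort-level
  estimates, so the score needs at least two samples (in practice
  $n \ge 20$ for stable weight signs) and is cohort-relative.
* **Signed KS** — per sample, the empirical CDFs of the epithelial-list
  and mesenchymal-list expression values are compared; the score is the
  two-sample Kolmogorov–Smirnov statistic signed positive when the
  mesenchymal values dominate. It lives in $[-1, 1]$, hits $\pm 1$ on
  perfectly separated value sets, and is the only metric here that is
  purely within-sample (no cohort dependence). The sign is resolved by
  the one-sided deviations $D^+$ / $D^-$; in the measure-zero case where
  they tie within $10^{-9}$ a note is logged and the non-negative side
  wins. The two-sided p-value uses the asymptotic KS distribution.
* **Epi / Mes / pEMT** — ssGSEA NES on the epithelial list, the
  mesenchymal list, and a partial-EMT signature. Hybrid E/M samples
  co-expressing both programs score intermediate on KS but high on pEMT,
  which is the defining behaviour of the partial-EMT signature and is
  exercised directly in the test suite.

### AUCell-style activity (single cell)

Per cell, genes are ranked by decreasing expression and the recovery
curve counts set genes among the top $k$ ranks,
$k = 1..\lceil \text{top\_fraction} \cdot N \rceil$ (default top 5%). The
score is the area under this step curve normalized so that packing the
set into the top ranks gives 1. Ties are broken deterministically by gene
symbol; with dense post-imputation matrices ties are rare anyway.

### Target-set and FAO activities

Regulator activities (AMPK, HIF-1α) are proxied by downstream target
genes. The default method z-scores each target across samples and
averages (`mean_z`); a first-principal-component projection
(`first_pc`, sign-aligned with `mean_z`) is provided because PCA-style
summaries are common for this purpose and the literature rarely pins the
choice down. The FAO score is a weighted sum of z-scored FAO enzyme-gene
expression. The published FAO equation's exact per-gene weights live in
its original source and are not reproduced here; the default is uniform
$1/|S|$ weights, documented as a stand-in, with user-supplied weights
(two-column TSV) as the faithful path.

### Coverage rules

Gene sets rarely match a matrix exactly. Missing set genes are dropped
with a warning; below a minimum coverage fraction (default 0.5) scoring
refuses rather than silently score a fragment. Zero-variance genes are
dropped from correlation-weighted and z-scored metrics.

## PD-L1 signature curation

Across a compendium of cohorts, every gene is Spearman-correlated with
the anchor (CD274). A gene qualifies in a cohort iff $\rho > 0.5$ and
$p < 0.01$ (strict, raw p — the published rule applies no multiple-testing
correction), and enters the signature if it qualifies in at least 15
cohorts (of 27). p-values use the large-sample t-approximation; cohorts
under 4 samples are excluded with a warning. The anchor itself is
excluded from the returned signature by default, since keeping it would
make later anchor-vs-signature correlations partially circular.

## Meta-analysis

Within each dataset, metric pairs are correlated (Spearman by default;
Pearson by option — sources using plain "R" are ambiguous, so both are
exposed). Across datasets, a correlation is *significant* iff
$|R| > 0.3$ and $p < 0.05$, both strict, and is then counted positive or
negative by sign — the volcano classification. Quadrant summaries join
two metric pairs by dataset and count sign combinations **only over
datasets significant in both pairs**. A Benjamini–Hochberg column is
emitted alongside for transparency but never drives the headline counts.
Constant-score datasets yield an undefined-correlation record and are
excluded from totals with a logged reason.

## Survival stratification

Samples are median-split on a PD-L1 metric and a glycolysis metric:
*high* means strictly above the cohort median, ties go to *low* (the tie
rule is explicit because it is rarely stated; thresholds are recorded in
the assignment object). P+G+ (high/high) and P+G− (high/low) are
compared; all other samples are excluded from the two-group analysis.
Kaplan–Meier estimation, the log-rank test and the binary-covariate Cox
fit go through the survival package (Efron handling of tied event
times). Results report HR, Wald 95% CI, $\log_2$HR (positive = increased
risk in P+G+) and the log-rank p. Monotone likelihood (complete
separation) is flagged on the result rather than raised as an error.

## Synthetic data: what it emulates, what it does not

All validation runs on generated data, because the real compendia behind
this kind of analysis (hundreds of expression series plus pan-cancer
cohorts) are not shippable. The generator plants exactly the structure
the analysis assumes:

* a latent activity per program and sample, drawn from a multivariate
  normal whose correlation matrix is the configurable **coupling**
  (default signs: PD-L1 positive with Mes, pEMT, glycolysis and HIF-1α,
  negative with OXPHOS, orthogonal to Epi);
* epithelial / hybrid / mesenchymal populations (default fractions
  0.4/0.2/0.4) shifting the EMT latents, hybrids receiving simultaneous
  partial epithelial and mesenchymal activity plus full pEMT activity;
* member genes emitted as `baseline + effect_size × latent + noise` on
  log2 scale (defaults: baseline N(6, 1), effect 2, noise sd 1 —
  log2-intensity-like values with clearly detectable but not degenerate
  programs); CDH1 rides the epithelial latent, CD274 the PD-L1 latent;
* exponential survival with a hazard multiplier (default 2) for P+G+ and
  exponential censoring calibrated to the target censored fraction
  (default 20%).

Homoscedastic Gaussian noise on log2 scale is a deliberate
simplification: the generator does **not** emulate count noise,
single-cell dropout, batch effects, or platform-specific distortions.
Passing tests therefore demonstrate correctness of the computations and
recoverability of planted structure, not robustness to every artefact of
real data. One consequence worth knowing: because all in-set genes share
one latent, a population's score distributions overlap at the latent
level no matter how many genes are averaged, so population-separation
checks on generator output plateau (AUROC ≈ 0.92 at the default effect
size) below what a fixed per-gene shift would give.

A second, subtler effect is compositional: rank-based scores compete for
ranks, so two scored sets in one matrix acquire a small negative
correlation even with independent latents (about −0.16 at a 400-gene
universe, −0.05 at 2000 genes). Validation experiments therefore use the
2000-gene default universe, where the effect is small against the
planted couplings; on real transcriptome-wide matrices it is negligible.

## Problem sizes and numerical choices

The validation suite uses: 200 per-sample KS fixtures (25+25 genes)
against a brute-force CDF sweep at $10^{-12}$; 100 ssGSEA fixtures
(300-gene universe, sets of 10–50) against position-by-position
recomputation at $10^{-9}$; 100 AUCell cells against explicit step-curve
integration; a 27-cohort compendium (150 samples each) for curation
recall; 50 datasets (2000 genes × 100 samples) for the 80/20
positive-coupling recovery and 200 for null calibration; 100 log-rank
replicates at n = 300 and 200 Cox replicates at n = 1000/group. These
sizes make every recovery estimate stable at the asserted tolerances
while keeping a default run comfortably fast on one core.

Other numerical choices: correlation p-values are floored at the smallest
positive double so that $-\log_{10} p$ stays finite for perfect
correlations; Spearman p uses the t-approximation (`exact = FALSE`)
everywhere for consistency between implementation and tests; probe
collapsing uses exact arithmetic means; pipeline TSVs format doubles with
10 significant digits so identical runs are byte-identical.

## Known limitations

* 76GS and NES values are cohort-relative; never compare them across
  datasets directly — compare within-dataset statistics instead.
* No quantile or cross-sample renormalization is applied beyond log2;
  matrices are assumed preprocessed to log2 scale.
* The FAO default weights are a documented stand-in (see above).
* Survival analysis is limited to the two-group median-split design with
  a single binary covariate; no multivariable or competing-risk models.
* The package is a library: orchestration happens through `run_all()`
  and ordinary R scripts rather than a shell executable.
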