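---
title: "Hybrid prognostic signature discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid prognostic signature discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(progsig)
```

# The method

`progsig` discovers small prognostic gene signatures from a
probes-by-samples intensity matrix and right-censored follow-up, and turns
them into a per-patient risk score. This vignette documents the underlying
models, every tunable parameter that matters, the synthetic data model the
test suite relies on, and the design decisions taken where the method
leaves room.

## Prognosis labels

Survival is dichotomized at a horizon (default 60 months): deaths at or
before the horizon are `high_risk`, follow-up beyond it (any event status)
is `low_risk`, and censored-before-horizon samples are excluded because
their five-year status is unknown. Two boundary conventions are fixed and
configurable only through the horizon itself: a death exactly at the
horizon is high risk, and a censoring exactly at the horizon counts as
having reached it alive, hence low risk. Times are handled in months
throughout.

## Candidate screening: t-tests ∩ SAM

Per-gene two-sample t-tests come in two variants: `different_variance`
(Welch statistic with Welch–Satterthwaite degrees of freedom, the default)
and `pooled` (pooled variance, n₁+n₂−2 df). p-values are two-sided. A gene
with zero spread in both classes is reported as t = 0, p = 1 and flagged
rather than erroring, so degenerate probes cannot crash a screen.

The SAM relative difference is

d_i = (x̄₁ − x̄₂) / (s_i + s₀),

with s_i the gene-specific pooled standard error and s₀ an
exchangeability constant that prevents low-variance genes with tiny
differences from dominating. With s₀ = 0, d_i is *exactly* the pooled
t-statistic — the test suite asserts this per gene on random matrices. The
null distribution comes from permuting class labels (`n_perm`, default
300, minimum 25); the expected relative difference is the mean of the
permutation order statistics. Significance at a threshold delta uses the
standard upper/lower cut construction on the sorted observed-vs-expected
plot, and the FDR estimate is the median permutation count of genes beyond
the cuts divided by the observed count (a 90th-percentile variant sits
behind the `false_count` flag; the π₀ factor defaults to 1).

Numerical choices:

* `s₀` is chosen by the percentile search: candidate values are the 0, 5,
  …, 100th percentiles of s_i, and the winner minimizes the coefficient of
  variation of the d-statistic spread (MAD) across 100 equal-count bins of
  s_i. A fixed `s0` can be supplied instead (the equivalence test uses 0).
* delta is searched on the grid of observed |d − d̄| deviations rather
  than a fixed step, removing an arbitrary resolution choice. The grid
  scan is vectorized (prefix-max cut construction plus binary-search
  counting) and is verified in the tests against a literal linear scan.
* An empty significant set never "achieves" a target FDR: if no delta
  with at least one called gene reaches the target, the error reports the
  minimum achievable FDR.

Candidates are the probes meeting both criteria (default t-test p < 0.01
and SAM FDR ≤ 25%), in expression-matrix order.

## Relief ranking

Relief scores each candidate by how well it separates nearest neighbours
across classes: for each instance, the k nearest hits (same class) and k
nearest misses (other class) under Manhattan distance on range-normalized
attributes contribute ±|xᵢ − yᵢ|/range(A), each divided by m·k. We use the
multi-neighbour variant (default k = 10, all instances used once in input
order) because single-neighbour Relief is fragile on noisy continuous
expression data; `k = 1` reproduces classic Relief and is what the
hand-enumerated oracle tests use. Constant attributes have zero diff and
therefore weight exactly 0; distance ties break by sample order and weight
ties preserve input probe order, making the ranking fully deterministic.
Range normalization makes the ranking invariant to positive affine
rescaling of any single gene.

## Stepwise forward selection

Starting from the top-ranked candidate, each next gene is accepted only if
it *strictly* increases stratified k-fold (default 10) cross-validated
Gaussian Naive Bayes accuracy, and the first rejection stops the search —
no patience window, matching a literal reading of "stop when adding a gene
does not improve accuracy". The fold partition is drawn once from the seed
and reused at every step so that accuracy differences reflect gene sets,
not fold noise; a single fixed partition (no repeated CV) is used. The
first gene is always accepted and anchors the baseline.

## Naive Bayes risk scoring

Training estimates maximum-likelihood class priors (no smoothing) and
per-class, per-gene means and standard deviations (n−1 denominator). Each
gene's SD is floored at 1e-6 of its pooled range (absolute fallback 1e-6
for globally constant genes) so densities never degenerate. All likelihood
arithmetic runs in the log domain — published parameter magnitudes (means
in the thousands, SDs in the hundreds) underflow raw 12-gene density
products — and the tests require agreement with direct density-product
evaluation to 1e-10 relative on inputs where the direct product is
representable. The decision rule is strict: a posterior above the
threshold (default 0.5) is high risk; exactly at the threshold is low
risk.

The bundled 12-probe lung adenocarcinoma model is stored as a plain-text
parameter table (gene, class, mean, SD, plus a priors header line — the
same shape any trained model serializes to) and is checksum-verified on
load. Whether the original training software floored variances is unknown,
so posteriors computed from the bundled parameters may diverge from the
original implementation in degenerate regions; this is documented rather
than guessed.

Calibration curves bin scored samples (default width 0.05), estimate
per-bin death probability at the horizon by Kaplan-Meier with a log-log
Greenwood interval, and flag bins under 5 samples as unstable.

## Survival evaluation

Kaplan-Meier estimation, log-rank testing and Cox fits delegate to the
`survival` package; Cox models use Efron tie handling because
month-resolution times are heavily tied. Categorical covariates expand
against declared reference levels, so stage/race/differentiation contrasts
match the reporting convention of multivariate prognostic tables, and the
continuous risk score enters as an ordinary covariate. The concordance
probability estimate is the Gönen–Heller form computed from pairwise
linear-predictor differences, mean over pairs of 1/(1+exp(−|Δη|)) — it is
censoring-independent, equals exactly 0.5 for a null predictor, and is the
canonical "concordance probability" for Cox models. Horizon
sensitivity/specificity takes its ground truth from the same
dichotomization rule, excluding censored-before-horizon samples from both
denominators (the handling of such samples is not standardized; exclusion
is our declared rule).

## Enrichment

Gene ranking uses the signal-to-noise ratio with the usual variance floor
(per-class SD at least 0.2·|class mean|) or a t-like statistic; ties break
by probe id. The enrichment score is the weighted Kolmogorov–Smirnov
running sum (hit increments ∝ |score|^p, default p = 1; p = 0 gives the
classic unweighted KS walk used by the hand-checkable oracles — with a
caveat that a contiguous top-k set walks straight to ES = 1). Null
distributions come from phenotype-label permutation (minimum 100); NES
divides the observed ES by the mean magnitude of same-sign permutation
scores, and FDR q follows the standard pooled positive/negative NES
procedure. Gene sets are read and written in GMT format.

## Chemoresponse

Per drug, log₁₀(GI50) activities are z-normalized over the lines with
non-missing data (missing values are excluded, never imputed; whether the
original normalizations used the full panel or only screened lines is not
recoverable, so per-drug non-missing normalization is our rule). Lines at
least 0.5 SD above the mean are resistant, at least 0.5 SD below
sensitive — both boundaries inclusive — and the rest intermediate.
Classification excludes intermediates and evaluates by leave-one-out CV;
the reference classifier is k-nearest neighbours (k = 3, Euclidean on
z-scored gene profiles, vote ties broken by the nearest neighbour), with a
pluggable function interface for alternatives since the original per-drug
classifier configurations are unspecified. Significance compares the
observed overall accuracy with `n_random` (default 1000) random
same-size signatures drawn from the profiled universe excluding the
observed genes; the p-value uses the +1 correction so the floor is
1/(n_random+1), matching a "<0.001" convention at 1000 draws.

# The synthetic data model

`simulate_cohort()` draws a two-class Gaussian cohort: a latent risk class
per sample (default 50/50), informative genes shifted between classes by
`effect_size` within-class SDs (default 1.0; high-risk up), uninformative
genes class-independent, all truncated at zero (truncation, not
resampling, keeps draws reproducible). Survival is exponential (Weibull
shape as an option) with the class hazard ratio; censoring is uniform on
[0, c] with c solved numerically for the target censoring rate. One root
seed expands into per-component child seeds, so changing the gene count
does not perturb the survival draws.

Default survival parameters were fixed from published cohort-level
numbers for resectable lung adenocarcinoma: a low-risk hazard of 0.004
events/month and a high-risk hazard ratio of 4 reproduce the reported
~87% vs ~55% three-year survival of good- and poor-prognosis groups, and
a 20% censoring rate leaves roughly a tenth of a cohort
censored-before-horizon. These are the package's fixed study conditions,
not tuning knobs.

`simulate_panel()` gives each cell line a latent standard-normal
chemoresponse score, reported (shifted to around 1 µM) as its log₁₀(GI50);
each signature gene tracks the score with strength `response_effect` (mean
shift per score SD, in units of the expression SD). `response_effect = 0`
makes expression independent of activity — the null used for permutation
calibration — while effects ≥ 2 make panels essentially separable.

What the generator does *not* emulate: probe-level array noise, batch
effects, correlated gene blocks, non-Gaussian intensity distributions,
informative censoring, or continuous risk heterogeneity within a class.
Passing tests therefore demonstrate correctness of the machinery under the
assumed two-class Gaussian model, not performance on real cohorts.

## A known limitation: label attenuation

The pipeline trains on dichotomized survival, not on the latent class.
Under exponential survival with a class hazard ratio of 4, five-year death
probabilities are ≈0.21 (low-risk class) and ≈0.62 (high-risk class), so
the five-year labels agree with the latent class for only ~70–75% of
samples. A between-class shift of 1.0 SD therefore appears as only
~0.4 SD between the *label* groups. Two consequences follow:

* genes that pass both screens by chance look exactly as strong in-sample
  as truly informative genes (selection bias), so Relief and the
  cross-validated stepwise search cannot reliably prefer the planted
  genes among the candidates;
* with strict first-failure stopping the selected signatures are small
  (typically 1–7 genes), and small, partially spurious signatures
  stratify independent cohorts inconsistently.

This is a property of the emulated study design — heavily dispersed
exponential survival around a five-year cut — not of any single
implementation step; each step's own behaviour is verified separately
against oracles and clean-label simulations, where e.g. Relief ranks all
planted genes first. Training the risk model directly on the informative
genes transfers across cohorts essentially always, which the test suite
also checks.

# Simulation sizes used by the test suite

The suite exercises the pipeline at the default study conditions (n = 300
samples, 2000 genes, 20 informative at 1.0 SD) across 25 seeds for
signature recovery and 20 train/held-out cohort pairs for transfer;
calibration checks use pooled Welch p-values from five null cohorts of
2000 genes, 500 log-rank replicates on cohorts of 100 (inside the
asymptotic regime of the chi-square reference), 500 Cox interval-coverage
replicates at n = 100, and 200 null chemoresponse panels with 100 random
signatures each. These sizes are the package's chosen trade-off between
Monte-Carlo error and a test suite that runs in minutes.
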