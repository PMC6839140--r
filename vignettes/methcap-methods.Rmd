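---
title: "methcap: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methcap: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methcap)
```

## Scope and model

`methcap` derives a triple-negative (TN) specific CpG signature from
probe × sample beta-value matrices whose samples carry receptor-defined
subtype labels (TN = ER−PR−HER2−, HER2p = ER−PR−HER2+, luminal = ER+ or
PR+; luminal A/B are deliberately merged into one class, and samples whose
deciding receptor status is unknown are excluded rather than imputed,
because the labels are the ground truth the pipeline is judged against).
The signature is then evaluated unsupervised (cluster purity), supervised
(tree-ensemble classification), and clinically (survival stratification by
an averaged 0/1 prognostic score).

## Preprocessing

**Probe filtering.** Entries with detection p above a threshold (default
0.01, configurable; the analysis convention leaves this unstated) are
masked to missing; SNP-associated, cross-reactive and sex-chromosome
probes are removed; finally any probe still carrying a missing value is
dropped (complete-case), keeping every downstream matrix dense.
"Heterochromosomic" probes are interpreted as chromosome X/Y probes — the
standard 450k QC reading and the only one that yields a well-defined
filter. Each removed probe is tallied once, attributed to the first
matching category in the order detection → SNP → cross-reactive → sex
chromosome.

**Peak-based normalization.** Betas are mapped to M-values
(M = log2(β/(1−β))), each sample's unmethylated and methylated density
modes are located by kernel density estimation (highest mode below /
above 0), and the sample's M-values are affinely rescaled so its two
peaks land on the cohort-median peak positions, then mapped back. This is
a deliberate simplification of Infinium type-II peak correction: probe
chemistry types are not modeled here, so the correction operates on the
overall bimodal M density instead of per-type densities. The affine map
is monotone, so within-sample rankings are preserved; unimodal samples
are passed through unscaled with a warning rather than being rescaled
with an undefined anchor.

**Probe-to-gene collapse.** When expression is available, each gene keeps
the single candidate probe whose betas have the *minimum* Pearson
correlation with the gene's expression (the "strongest negative"
candidate). When no candidate is negative the minimum is still kept and
flagged (`all_nonnegative`), rather than dropping the gene — the
gene-level matrix then stays complete, and the flag lets callers filter.
Genes with zero-variance expression are skipped with a reason.

## Differential methylation and the signature

The per-probe statistic is the empirical-Bayes moderated t: pooled
two-sample variance s² with d = n_A + n_B − 2 degrees of freedom, prior
(d₀, s₀²) estimated by matching the mean and variance of log s² to a
scaled log-F distribution (closed-form moment matching with a Newton
inversion of the trigamma function — deterministic, and numerically the
same estimator family as the standard implementation; the test suite
checks agreement with `limma::eBayes` to ~3 significant digits and exact
agreement with the ordinary pooled t when d₀ is forced to 0). Zero-variance
probes are safe by construction: the posterior variance is bounded below
by d₀s₀²/(d₀+d).

**Direction convention.** `delta_beta` is mean(contrast group) − mean(TN),
so `hyper` means *higher methylation in the non-TN group*. The convention
is arbitrary (the analysis being reproduced never fixes one) but is used
consistently everywhere, including the synthetic generator's truth tables.

**BH adjustment** is applied per contrast, not pooled across contrasts,
because each comparison is thresholded before intersecting. The signature
is the intersection of BH-significant probes (adj. p < alpha, default
0.01) across luminal-vs-TN and HER2p-vs-TN with concordant directions;
discordant probes are excluded — "shared" differential CpGs are read as
direction-concordant.

## Clustering, purity, PCA

Samples are clustered with Ward linkage (`ward.D2` heights, which the
tests verify against a hand-written Lance–Williams recurrence) on either
Euclidean or 1 − r distance; Euclidean is the default since the source
analysis names both without choosing. Cutting the tree at k = 1…10 gives
per-cluster purity (majority-label fraction); both the size-weighted mean
and the per-cutoff maximum are reported because the purity figure being
mirrored does not state which it plots. Majority ties break by the fixed
label priority TN > HER2p > luminal. PCA is probe-centered SVD with a
deterministic sign convention (largest-magnitude loading positive). The
linear separation check fits an L2-regularized squared-hinge (smooth SVM
surrogate) boundary with BFGS in the leading component scores — the
environment provides no SVM implementation, and for a 2–3-dimensional
maximum-margin-style boundary the smooth surrogate is deterministic and
adequate; reported accuracy is *training* separation, which on pure noise
sits above 0.5 (a fitted boundary always captures some noise), a fact the
tests assert honestly (mean within 0.45–0.7 across seeds) rather than
pretending chance level.

## Classification and its metrics

The classifier is bootstrap-aggregated binary decision trees (Gini
splits, per-split feature subsampling with mtry = floor(sqrt(p)),
implemented in compiled code with a self-contained deterministic RNG).
"Number of nodes in a tree" is interpreted as a per-tree maximum-leaf cap
grown best-first; the cap is tuned by scanning 1…n−1 and keeping the
minimum out-of-bag error (ties to the smallest cap). Tuning the scan with
a smaller forest (default 50 trees) and refitting the final forest
(default 200) keeps the n−1-point scan affordable without changing the
selection rule. F1 per class, MCC and the TP+TN correct count follow the
standard formulas; any zero denominator defines the metric as 0 with a
`degenerate` flag. Display rounding is half-up to 2 decimals, matching
how such tables are printed. AUC is computed by trapezoid over observed
score thresholds and equals the Mann–Whitney concordance probability with
ties counted half (verified against an all-pairs oracle). Whether ROC
scores come from out-of-bag votes or a held-out cohort is the caller's
choice; the pipeline defaults to held-out validation scores.

## Survival

Cox proportional hazards is fit by Newton–Raphson on the Breslow-ties
partial likelihood (gradient tolerance 1e−8, 50 iterations, steps damped
to ±2; monotone likelihoods are flagged and capped at |log HR| = 15
instead of diverging). For binary covariates the reported logrank p is
the classical ties-corrected logrank statistic — identical to
`survival::survdiff` in the tests — rather than the partial-likelihood
score test, which differs slightly under ties. Ten-year capping (time >
120 months → 120, event → 0) is applied at read time so every downstream
computation sees capped data.

**The prognostic score.** The published description of the score is
ambiguous: a per-site 1/0 "averaged for each sample" would be constant per
site if read literally. The implemented reading — the only one that
yields sample-level variation usable for stratification — is: each site
is dichotomized at its median β (the cut is unstated in the source;
median is the least-informative choice); a univariate Cox fit labels the
lower-hazard state favorable (HR exactly 1 ties to "low", flagged); a
sample's score is the fraction of sites (significant ones by default,
logrank p < 0.01) where it occupies the favorable state. Stratification
splits at the median score, ties to the low group, and reports KM curves,
logrank p and the Cox HR of low vs high score; with degenerate inputs
(e.g. two samples) stratification still returns groups but the Cox HR is
NA.

## The synthetic cohort: what it emulates and what it does not

The generator is the package's testing ground and a first-class module.
Betas are logistic-transformed Gaussians on the M scale; the Gaussian
mean is solved by Gauss–Hermite quadrature + Newton so that the *expected
beta* equals the requested group mean exactly — group effects are
specified on the beta scale (`effect_delta`, default 0.2–0.25 in tests, a
realistic strong subtype effect) while composing additively on M, and the
within-group beta-scale dispersion `noise_sd` (default 0.05, typical
within-subtype spread for a differential 450k probe) maps to the M scale
by the delta method. Background probes draw baselines from a bimodal
mixture (45% low, 45% high, 10% intermediate) mimicking the
characteristic 450k beta distribution. Planted TN sites shift the TN
group by ±`effect_delta`; luminal-only sites shift only luminal.
Expression for planted genes is built to a target methylation–expression
correlation (`meth_expr_rho`, default −0.7, a strong promoter-repression
signal). Survival is exponential with log hazard
`hazard_log_hr` × Σ(unfavorable-state indicator − ½) over prognostic
sites; centering the indicator is algebraically identical (the constant
is absorbed into the baseline hazard, median 72 months) but keeps the
baseline interpretable. Administrative censoring is an independent
uniform C ~ U(0, τ) with τ calibrated by root-finding so the expected
censoring fraction matches `censor_rate` (default 0.3); the 10-year cap
then adds further administrative censoring, as it does for real cohorts.

Two choices deserve emphasis:

* **Structure vs sample seeds.** The RNG is split into a structure phase
  (baselines, planted directions, gene map, QC flags) keyed by
  `structure_seed` and a sample phase keyed by `seed`. A
  discovery/validation pair shares `structure_seed` and differs in
  `seed` — without this, a "validation" cohort would have different
  planted biology and cross-cohort validation would be meaningless.
* **Prognostic-site placement.** Prognostic sites preferentially overlap
  the planted TN set, and those overlapping sites share one orientation
  (TN-hypermethylated), so their unfavorable states accumulate in the
  hazard instead of cancelling; this also means TN samples carry the
  excess hazard, as TN tumors do clinically, and lets the pipeline's
  survival stage operate on the derived signature. Parameter-recovery
  tests use configs with `n_planted_tn = 0`, making prognostic sites
  independent background probes — the clean setting in which univariate
  Cox recovery (within 3 SE at n = 400) is a well-posed check; note that
  with many simultaneous planted sites the *marginal* per-site HR is
  attenuated by Cox non-collapsibility, which is expected behavior, not a
  bug.

What the generator does **not** emulate: Infinium type I/II probe
chemistry, batch effects, cell-type composition, spatial correlation
along the genome, and non-exponential hazards. A green test therefore
establishes that the statistics recover what was planted under the
stated noise model — not that the pipeline is robust to array artifacts
it never sees.

## Numerical choices

* Beta values are clamped to [1e−6, 1 − 1e−6] before the M transform.
* BH step-up is order-preserving with monotonicity enforcement
  (cummin over the reverse-sorted sequence).
* Trigamma inversion: Newton on y ← y + Δ with the standard asymptotic
  starting point; prior df is ∞ when the moment estimate of the log-F
  variance is non-positive.
* The tree RNG is splitmix64, independent of R's RNG; a forest is a pure
  function of (matrix, labels, seed, hyperparameters).
* KDE peaks use `stats::density` with 512 grid points; peak positions are
  grid-resolution accurate, which the normalization tolerances reflect.
* Enrichment p-values use the hypergeometric upper tail
  P(X ≥ k) with BH across sets; the universe is the set of genes that
  survived preprocessing (the measurable pool), not the genome.

## Known limitations

* Peak normalization assumes a bimodal M density; cohorts dominated by
  intermediate methylation (e.g. heavily tumor-purity-confounded data)
  will trigger pass-through warnings.
* The moderated-t prior assumes exchangeable per-probe variances; no
  mean-variance trend or robustification is offered.
* The classifier is binary TN vs non-TN throughout; three-class metrics
  are out of scope.
* Survival analysis is univariate; no adjusted or multivariate Cox
  models, competing risks, or time-varying covariates.
* Real-cohort results depend on the input data: nothing in this package
  downloads or bundles cohort data, and the tests verify the machinery on
  planted synthetic cohorts and on published 2×2 confusion-matrix worked
  examples, not on any real beta matrix.
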