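# methcap

Subtype-specific CpG methylation signatures with prognostic scoring.

## What this package is for

Breast cancers stratify into luminal, HER2-positive (HER2p) and triple
negative (TN) subtypes by ER/PR/HER2 immunohistochemistry. TN tumors lack
targeted therapy and are the hardest to classify and prognose. DNA
methylation — the beta value β ∈ [0, 1] measured per CpG on Illumina
450k-style arrays — is a stable epigenetic mark that can separate these
subtypes. `methcap` implements, as a tested and reusable pipeline, the
analysis that derives a TN-specific CpG signature from subtype-labeled beta
matrices and evaluates it three ways: unsupervised (cluster purity),
supervised (tree-ensemble classification with F1/MCC/AUC), and clinically
(a per-sample averaged prognostic score stratifying 10-year overall
survival).

It is written for computational biologists who want to run the same
analysis on their own beta matrices, or to study its statistical behavior
on synthetic cohorts with known ground truth — the package ships a
generator that plants subtype-differential CpGs, methylation–expression
anti-correlation, and site-level survival effects, so every stage is
testable offline.

## The statistics at the core

* **Moderated t per CpG.** For a contrast of groups A and B, the pooled
  residual variance s² (d = n_A + n_B − 2 df) is shrunk toward a prior
  (d₀, s₀²) estimated across probes by matching the moments of log s² to a
  scaled log-F distribution:
  s̃² = (d₀ s₀² + d s²) / (d₀ + d), t = Δβ / (s̃ √(1/n_A + 1/n_B)),
  on d₀ + d degrees of freedom, with Benjamini–Hochberg control across
  probes.
* **Signature derivation.** A CpG enters the TN signature when it is
  BH-significant (adj. p < 0.01) with a concordant direction in *both*
  luminal-vs-TN and HER2p-vs-TN contrasts; "hyper" means higher methylation
  in the non-TN group.
* **Cluster purity.** Ward-linkage dendrograms (Euclidean or 1 − r
  distance) cut at k = 1…10; each cluster takes its majority label, purity
  is the majority fraction (size-weighted mean and per-cutoff maximum are
  both reported).
* **Classification metrics.** Bagged decision trees with the per-tree node
  budget tuned by out-of-bag error over 1…n−1; F1 = 2·Prec·Rec/(Prec+Rec)
  with Prec = TP/(TP+FP), Rec = TP/(TP+FN), per class; MCC; AUC as the
  Mann–Whitney concordance probability.
* **Prognostic score.** Each signature site is dichotomized at its median
  β; a univariate Cox fit (Breslow ties, Newton–Raphson) labels the
  lower-hazard state "favorable"; a sample's score is the fraction of
  significant sites (logrank p < 0.01) where it occupies the favorable
  state. The median-split score groups are compared by Kaplan–Meier,
  logrank and Cox HR on 10-year-capped overall survival.

## Worked example

```r
library(methcap)

cfg <- cohort_config(
  n_samples_per_subtype = c(TN = 40, HER2p = 40, luminal = 40),
  n_probes = 1000, n_planted_tn = 50, n_planted_luminal_only = 50,
  effect_delta = 0.25, noise_sd = 0.05, n_prognostic = 20,
  hazard_log_hr = 1.0, censor_rate = 0.3, seed = 1)
cohort <- generate_cohort(cfg)

lab <- cohort$labels
lum <- moderated_t_test(cohort$betas, names(lab)[lab == "luminal"],
                        names(lab)[lab == "TN"])
her <- moderated_t_test(cohort$betas, names(lab)[lab == "HER2p"],
                        names(lab)[lab == "TN"])
sig <- derive_signature(lum, her, alpha = 0.01, annot = cohort$annotation)
print(sig)
#> signature_set: 18 hyper + 32 hypo CpGs; 50 genes

sb  <- cohort$betas[sig$probes$probe_id, ]
tnb <- setNames(factor(ifelse(lab == "TN", "TN", "nonTN"),
                       levels = c("TN", "nonTN")), names(lab))
pc  <- purity_curve(hierarchical_cluster(sb), tnb, max_k = 5)
print(pc$summary, row.names = FALSE)
#>  cutoff overall_weighted_purity max_cluster_purity
#>       1               0.6666667          0.6666667
#>       2               1.0000000          1.0000000
#>       3               1.0000000          1.0000000
#>       4               1.0000000          1.0000000
#>       5               1.0000000          1.0000000

dirs  <- site_directions(sb, cohort$clinical, alpha = 0.01)
strat <- stratify_and_test(prognostic_scores(sb, dirs), cohort$clinical)
cat(sprintf("prognostic sites: %d | stratification logrank p = %.3g, HR = %.2f\n",
            sum(dirs$significant), strat$logrank_p, strat$hr))
#> prognostic sites: 50 | stratification logrank p = 1.78e-13, HR = 59.33
```

Reading the output: all 50 planted TN-differential CpGs are recovered (18
of them hypermethylated in non-TN tumors), a single cut at k = 2 already
isolates the TN samples perfectly (purity 1.0 from k ≥ 2), and the
averaged 0/1 prognostic score splits the cohort into groups with sharply
different survival (the planted per-site log-HR of 1.0 over 20 sites makes
the low-score group's hazard ~59-fold higher — synthetic effects compound
across sites, so the HR is much larger than one site's).

Confusion-matrix metrics work directly from printed 2×2 counts:

```r
m <- confusion_metrics(tp = 7, fn = 2, fp = 5, tn = 32)
cat(sprintf("F1_TN = %.2f, F1_nonTN = %.2f, MCC = %.2f\n",
            m$f1_tn_2dp, m$f1_nontn_2dp, m$mcc_2dp))
#> F1_TN = 0.67, F1_nonTN = 0.90, MCC = 0.58
```

## Command line

```sh
Rscript -e 'methcap::methcap_cli()' simulate --out cohort/ --seed 3
Rscript -e 'methcap::methcap_cli()' run --config pipeline.cfg
```

Subcommands: `simulate`, `preprocess`, `diffmeth`, `cluster`, `classify`,
`survival`, `enrich`, `run`. The pipeline config is a flat `key=value`
file; see `?run_pipeline` for the keys.

## Documentation

The methods vignette (`vignettes/methcap-methods.Rmd`) describes the model,
the synthetic-data generator and what a green test does and does not
establish, numerical choices, and known limitations.
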