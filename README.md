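# anchorsig

Anchor-gene DEG construction, enrichment scoring, and survival
stratification for bulk expression cohorts.

## The problem

Pathway genes such as the Notch ligands and receptors (JAG1/2, DLL1/3/4,
NOTCH1-4) act through downstream transcriptional programs whose activity
can be a sharper phenotype and prognosis readout than the genes' own
expression. `anchorsig` turns that idea into a tested pipeline for any
set of *anchor genes* in a genes × samples expression matrix with
matched clinical data:

1. **DEG sets.** For each anchor, samples are split by the anchor's
   expression with the **mean ± SEM rule** (high ≥ mean + SEM, low ≤
   mean − SEM, middle band excluded); genes with Pearson |r| > 0.2
   against the anchor enter a from-scratch **SAM** (significance
   analysis of microarrays): moderated statistic
   `d = (x̄_hi − x̄_lo)/(s + s0)`, label-permutation null (exhaustive on
   small groups), per-gene FDR `q` with π₀ = 1, selecting genes
   significantly up in the anchor-high group as the set `"<anchor>-DEG"`.
2. **Enrichment.** Gene-set collections (GMT) and the DEG sets are
   scored per sample by from-scratch **ssGSEA** (rank-weighted ECDF gap,
   α = 0.75) and z-normalized per set; two-class **GSEA**
   (signal-to-noise ranking, permutation NES and FDR; significant when
   q < 0.25 and NES > 1.25) handles group contrasts.
3. **Classification.** Signatures are classified positive/negative by
   the **sign of the summed correlation** between their z-scores and the
   predictors (anchor expression, DEG z-scores) across cohorts.
4. **Survival.** Kaplan-Meier estimation and k-group log-rank tests
   compare high vs low groups, and the crossed **four-group**
   (HH/HL/LH/LL) assignment over an anchor and a signature.

A synthetic-cohort generator plants co-expression modules at a target
correlation, signed latent signature activities, and exponential
survival with a log-linear hazard — with full ground truth — so every
stage has a recovery test.

## Worked example

```r
library(anchorsig)

cfg <- simulation_config(
  n_samples = 300, n_background_genes = 500, anchors = "JAG1",
  module_size = 60, target_rho = 0.5,
  signatures = data.frame(
    name = c("HYPOXIA", "ANGIOGENESIS", "MYC_TARGETS", "DNA_REPAIR"),
    size = 40, sign = c(1, 1, -1, -1), gamma = 0.5),
  coef_anchor = log(2.5), coef_signature = log(2.5),
  censoring_fraction = 0.2, seed = 42)
cohort <- simulate_cohort(cfg)

deg <- build_deg_sets(cohort$expression, "JAG1",
                      sam_params(n_permutations = 500, seed = 1))
length(deg$sets[["JAG1-DEG"]])
#> [1] 79        # all 60 planted module genes plus genuinely
#>               # anchor-correlated signature genes

sets <- cohort$true_signatures
enr  <- ssgsea_matrix(cohort$expression, sets, 0.75)
cl   <- classify_signatures(
  correlation_profile(list(JAG1 = cohort$expression["JAG1", ]), enr))
round(cl$sum_r, 3)
#>      HYPOXIA ANGIOGENESIS  MYC_TARGETS   DNA_REPAIR  JAG1-module
#>        0.088        0.304       -0.423       -0.279        0.674
```

Both planted-positive signatures (and the anchor's own co-expression
module) land in `cl$positive`, both planted-negative in `cl$negative`.
Stratifying survival by the anchor:

```r
strat <- mean_sem_split(cohort$expression["JAG1", ])
strat
#> mean+/-SEM split: 138 high, 145 low, 17 excluded
two <- survival_by_stratification(strat, cohort$clinical)
two$logrank
#> log-rank: chi2 = 32.56 on 1 df, p = 1.156e-08
```

and crossing it with the hypoxia signature's z-score split:

```r
four <- combined_survival(strat, mean_sem_split(enr$z["HYPOXIA", ]),
                          cohort$clinical)
four$overall
#> log-rank: chi2 = 92.82 on 3 df, p = 5.438e-20
```

Survival at median follow-up per group is 0.277 (HH), 0.518 (HL), 0.471
(LH), 0.894 (LL): the double-high group fares worst, as planted
(θ₁ = θ₂ = log 2.5 > 0), and the double-low group best.

The whole flow — simulate → deg → enrich → associate → survive, with
provenance-stamped TSV outputs — runs as one call:

```r
run_all(pipeline_config(out_dir = "out", simulate = cfg, seed = 7))
```

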