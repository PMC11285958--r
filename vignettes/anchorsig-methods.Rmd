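---
title: "Methods: anchor-gene DEG construction, enrichment scoring, and survival stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anchor-gene DEG construction, enrichment scoring, and survival stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorsig)
```

## The analysis this package implements

In many cancers the Notch pathway's ligands (JAG1/2, DLL1/3/4) and
receptors (NOTCH1-4) act as context-dependent oncogenes or tumor
suppressors, and their downstream transcriptional programs are better
prognostic readouts than the genes' own expression. `anchorsig`
implements the corresponding cohort analysis as a reusable, tested
pipeline around a set of user-chosen *anchor genes*:

1. **Per-anchor DEG sets.** Samples are dichotomized by the anchor's
   expression (mean ± SEM rule); genes whose Pearson correlation with
   the anchor exceeds |r| > 0.2 enter a two-class unpaired SAM
   (significance analysis of microarrays) that calls genes significantly
   up-regulated in the anchor-high group. The selected genes form the
   gene set `"<anchor>-DEG"`.
2. **Enrichment scoring.** Hallmark-style gene-set collections (GMT)
   and the DEG sets themselves are scored per sample by ssGSEA; the
   per-set score vectors are z-normalized across samples. A two-class
   GSEA (signal-to-noise ranking, permutation NES/FDR) is available for
   group contrasts, flagging sets with FDR q < 0.25 and NES > 1.25.
3. **Signature classification.** Each signature's z-score row is
   correlated with every predictor (anchor expression, DEG-set z-scores)
   in every cohort; signatures are classified *positive* or *negative*
   by the sign of the summed correlation. Hierarchical clustering
   (average linkage on 1 − r distance) supplies only a display ordering;
   the operative rule is the sign of the sum.
4. **Survival stratification.** High/low groups (and the crossed
   four-group HH/HL/LH/LL assignment over an anchor and a signature) are
   compared with Kaplan-Meier curves and k-group log-rank tests.

Every stage is validated against a synthetic-cohort generator that
plants the exact structure the analysis assumes, so each step has a
ground-truth recovery test.

## Stratification: the mean ± SEM rule

For a per-sample score vector the high group is
\{v ≥ mean + SEM\} and the low group \{v ≤ mean − SEM\}, with
SEM = sd/√n (sample sd, n − 1 denominator). Two cutoffs can only yield
two groups if the intermediate band is excluded, so samples between the
thresholds take part in neither group; boundaries are inclusive so that
duplicated extreme values are never lost. The same rule serves raw
expression and ssGSEA z-scores, and it is invariant under shifting and
positive rescaling of the scores. A constant score vector, or a split
that would empty either group, is an error rather than a silent
degenerate result. Exclusion of the middle band is a design choice
(the two-threshold phrasing does not dictate the band's fate) and is
worth a sensitivity check on real data.

## SAM: statistic, permutation null, and q-values

For gene *i* with high/low group values, the moderated statistic is

$$d_i = \frac{\bar x_{hi} - \bar x_{lo}}{s_i + s_0},\qquad
s_i = \sqrt{\tfrac{1/n_1 + 1/n_2}{n_1+n_2-2}\,(SS_{hi} + SS_{lo})},$$

the pooled-variance two-sample t statistic with an exchangeability
offset $s_0$ that prevents low-variance genes from dominating. By
default $s_0$ is the median of the per-gene $s_i$ (robust and simple); a
Tusher-style coefficient-of-variation minimization over percentile
windows of $s$, and a fixed value, are also available.

The null is generated by permuting the high/low labels: exhaustively
when the number of distinct arrangements is at most `n_permutations`
(always the case for the small instances used in the oracle tests),
otherwise by a seeded random draw. Each permutation's sorted statistics
are averaged position-wise into the expected order statistics
$\bar d_{(i)}$. For a grid of thresholds Δ (the distinct observed
positive-side offsets $d_{(i)} - \bar d_{(i)}$), the called set is
\{genes with offset ≥ Δ and d > 0\}; the estimated number of false calls
is the median across permutations of the count of permuted statistics at
or above the smallest called d; and a gene's q is the smallest
false/called ratio over the Δ that admit it, with $\pi_0$ fixed at 1
(conservative; estimating $\pi_0$ is deliberately omitted). Finally q is
made monotone along the ranking by a cumulative minimum carried from the
least significant gene toward the most significant — the same direction
as the Benjamini-Hochberg step-up, so a stronger gene never carries a
larger q than a weaker one, and a single extreme gene's q never leaks to
the rest of the list. Getting this direction right matters: the reversed
pass looks identical on signal-bearing data but inflates the pure-noise
selected fraction by two orders of magnitude, which is why the test
suite checks the null calibration (pure-noise matrices, 500 genes,
30 + 30 samples, 20 seeds) and not only oracle equivalence.

Only the up-regulated side is called by default, matching the DEG-set
definition; the symmetric down side is available through the label-swap
antisymmetry of d (`direction = "down"`).

## ssGSEA and two-class GSEA

ssGSEA ranks one sample's genes by expression, descending, breaking ties
by gene identifier so results are reproducible. The gene at position *i*
receives rank weight $G - i + 1$ and the score for a set of size *m* is

$$ES = \sum_{i=1}^{G}\left[\frac{\sum_{j \in S,\ pos(j)\le i} r_j^\alpha}
{\sum_{j\in S} r_j^\alpha} - \frac{|\{j \notin S : pos(j)\le i\}|}{G-m}\right],$$

the integrated gap between the weighted in-set ECDF and the uniform
out-of-set ECDF. It depends on the expression column only through its
ranks (tested as invariance under strictly monotone transforms). The
weighting exponent defaults to α = 0.75, the common single-sample
default; raw ES are z-normalized per set across samples and the
z-scores are what stratification and correlation consume, so no
additional cross-sample range normalization is applied. A constant
score row z-maps to zeros rather than NaN.

Two-class GSEA ranks genes by signal-to-noise with each class sd floored
at 0.2 × |class mean| (0.2 when the mean is also zero), accumulates the
weighted running sum (member increments ∝ |metric|, uniform decrements),
and takes the maximum deviation as ES. The permutation null shuffles
phenotype labels, or draws random gene sets of matched size when a class
has fewer than 7 samples. NES divides ES by the mean same-sign permuted
ES; the FDR q comes from the standard pooled-NES two-tail procedure.
Significance uses the conventional q < 0.25 with the stricter
NES > 1.25.

## Survival

`km_estimate` is the product-limit estimator over the distinct observed
times, processing events before censorings at ties. `logrank`
accumulates, at each distinct event time, observed minus expected events
per group with the hypergeometric covariance, and forms the chi-square
quadratic form on k − 1 df (a pseudo-inverse handles risk sets that make
the covariance singular). For two groups this reduces to the squared
standardized O − E statistic and agrees with `survival::survdiff`, which
the tests use as an independent cross-check. The four-group analysis
reports the overall 3-df test and all six pairwise tests with raw
p-values; no multiplicity correction is applied, so the pairwise table
is descriptive, not confirmatory.

## The synthetic cohort generator

The generator plants exactly the structure the analysis assumes — and
nothing else:

* per sample, each anchor has latent activity $a \sim N(0,1)$; the
  anchor gene is $a$ plus $N(0, \sigma^2)$ noise ($\sigma$ = 1 by
  default, a typical log-scale dispersion);
* module genes are $\beta a + \varepsilon$ with
  $\beta = \rho\sigma/\sqrt{1-\rho^2}$, so their population correlation
  with $a$ is exactly the target ρ (default 0.5, a strong but realistic
  co-expression level; the |r| > 0.2 prefilter then has high recall at
  n ≥ 300);
* signature activities are $h_k = s_k\gamma a + N(0,1)$ with planted
  sign $s_k = \pm 1$ and strength γ (default 0.5); member genes load on
  $h_k$ with the same ρ-construction;
* background genes are pure noise, giving SAM and GSEA an honest null;
* survival is exponential with hazard
  $\lambda_0 \exp(\theta_1 a + \theta_2 h)$ for the designated
  survival-driving signature; censoring is an independent exponential
  whose rate is solved numerically (the expected censored fraction of a
  sample with event rate r under censoring rate c is c/(c+r)) to hit
  the target fraction in expectation;
* optional tumor/normal, stage, and paired pre/post labels add
  configured shifts to the anchor and module genes only, so contrasts on
  background genes remain null.

Where an effect size was not dictated externally it was fixed once at a
value a cohort analyst would call typical and not revisited: hazard
coefficients $\theta_1 = \theta_2 = \log 2.5$ (a hazard ratio of 2.5 per
unit latent activity, the magnitude used in the power checks), module
and signature loadings ρ = 0.5, noise sd 1, censoring 20-30%.

What the generator does **not** emulate: count-level sampling noise,
library-size and batch effects, correlated background structure,
heavy-tailed expression, non-proportional hazards, informative
censoring, or single-cell cluster structure. Passing recovery tests
therefore demonstrate the machinery's correctness under its own model,
not robustness to real-data pathologies.

## Numerical and reproducibility choices

* Every random draw descends from one integer seed, salted with the
  stage name by a fixed integer hash, so stages are independently
  reproducible and two runs of the same configuration are
  byte-identical (checked file-by-file in the tests).
* Ranking ties break by gene identifier, stably.
* Duplicate gene ids on input collapse to the highest-mean row, logged.
* Expression is assumed pre-normalized and log-scale; the package never
  normalizes, and clinical time units are caller-declared and never
  converted.
* Degenerate inputs (constant vectors, empty groups, empty four-group
  cells, zero-overlap gene sets, sets covering the whole universe) are
  classed errors, not warnings, so a pipeline cannot silently continue
  on meaningless strata.
* Problem sizes in the validation suite (e.g. SAM null at 500 genes ×
  60 samples × 20 seeds with 100 permutations; GSEA null at 200 genes ×
  40 samples × 500 permutations × 10 seeds; DEG recovery at 1,100 genes
  × 300 samples with 500 permutations) were chosen as the smallest
  cohorts at which the targeted sampling distributions are stable.

## Known limitations

* SAM's q-values use $\pi_0 = 1$; with many truly differential genes the
  reported q overstates the FDR (conservative).
* The prefilter computes r over all samples, not only the stratified
  ones; correlation and the subsequent two-group test are therefore not
  independent, which is inherent to the DEG-set definition.
* ssGSEA scores depend on the gene universe; comparing scores across
  matrices with different gene sets is not meaningful.
* The four-group pairwise log-rank p-values are raw; with six pairs per
  anchor-signature combination, family-wise error is not controlled.
* The generator's exponential survival model makes the planted effect a
  true proportional hazard; the log-rank test is optimal there, so its
  power on synthetic data is an upper bound for real cohorts.
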