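---
title: "Methods: survival GWAS and risk modelling for treatment-induced hearing loss"
author: "otoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survival GWAS and risk modelling for treatment-induced hearing loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otoscan)
```

## The problem

Hearing loss is a frequent, irreversible side effect of platinum-based
concurrent chemoradiotherapy, particularly in nasopharyngeal carcinoma where
the radiation field abuts the auditory apparatus. Clinical factors (age,
tumor stage, cumulative cisplatin dose) explain only part of the
between-patient variability, which motivates a genome-wide search for
germline modifiers of ototoxicity risk, treated as a **time-to-event**
outcome: months from the start of treatment to the first documented hearing
loss, right-censored at last follow-up.

`otoscan` implements the full analysis as a reusable, tested pipeline:

1. variant-level quality control and genotype principal components,
2. a per-SNP additive Cox proportional-hazards scan with clinical and
   ancestry covariates,
3. permutation-based enrichment of scan signal in hereditary-deafness gene
   regions,
4. clinical Cox modelling with ROC-derived cutoffs, and
5. a combined genetic + clinical risk score with train/test validation.

Because individual-level cohort data of this kind is access-controlled, the
package ships a synthetic-data generator that reproduces the *statistical
structure* of such a cohort, so every stage is exercised end to end by the
test suite.

## Models

### Per-SNP Cox scan

For subject $i$ with covariate row $z_i$ and effect-allele dosage
$g_i \in [0, 2]$ for the variant under test, the hazard is

$$\lambda_i(t) = \lambda_0(t)\, \exp(\gamma g_i + \beta^\top z_i),$$

the additive genetic model. Each variant is fit by Newton–Raphson
maximization of the Efron-adjusted partial likelihood (`coxFit()`, compiled
code), with tolerance $10^{-9}$ on the largest coefficient change, at most
50 iterations and step-halving; standard errors come from the inverse
observed information, and the reported P is the two-sided Wald test of
$\gamma = 0$. Efron is the default tie correction because event times in
months are frequently tied; Breslow is available behind a flag. The score
statistic at $\gamma = 0$ is also exposed — for a lone binary covariate
without ties it equals the log-rank chi-square, which the test suite uses as
an exact cross-check, alongside agreement with `survival::coxph()` to
$10^{-7}$ and a brute-force grid search of the explicit partial likelihood
on small datasets.

Default scan covariates are the three independent clinical risk factors
(age ≥ 50 years, T3–T4 stage, concurrent cisplatin dose ≥ 155 mg/m²) plus
the first two genotype principal components; the reporting thresholds are
the conventional genome-wide $5\times10^{-8}$ and suggestive
$1\times10^{-5}$. Subjects missing a variant's genotype are dropped for
that variant only (`n_used` records the analysed count); monomorphic or
collinear variants are emitted flagged `converged = FALSE`, never with
fabricated numbers.

Calibration is summarized by the genomic inflation factor
$\lambda_{GC} = \mathrm{median}(\chi^2_{obs}) / 0.4549$. Note that a
$\lambda_{GC}$ estimated from $m$ SNPs is itself noisy — at $m = 5000$ its
Monte Carlo SD is about 0.033 — so the package's calibration tests average
it over replicate null datasets rather than trusting a single draw.

### Variant QC

Variants are removed if call rate < 95%, MAF < 0.01, Hardy–Weinberg exact
$P < 10^{-12}$, or imputation INFO < 0.8 (INFO applies only where an INFO
score is present; any filter can be disabled). MAF is computed on
non-missing dosages as $\min(p, 1-p)$ with $p$ = mean dosage / 2; folding is
used **only** for filtering — the effect allele is always ALT. The HWE test
is the exact conditional test on heterozygote counts (two-sided:
total probability of heterozygote counts no more probable than observed),
computed on hard calls (dosages rounded) because the exact test is defined
on genotype counts; the choice of an exact rather than asymptotic test is
recorded in the QC report. Sample-level QC (sample call rate,
heterozygosity, IBD, iterative PC-outlier removal) is deliberately out of
scope — `sampleQCHook()` documents this and passes data through.

### Genotype PCA

Missing entries are mean-imputed per variant, dosages centred at $2p$ and
scaled by $\sqrt{2p(1-p)}$, and the top-$k$ eigenvectors of the subject
covariance matrix returned, with the sign convention that each component's
largest-magnitude entry is positive (making results deterministic). PCs are
ancestry covariates in the scan.

### Permutation enrichment

A gene region set is the union of gene bodies extended symmetrically by a
flank (50 kb for the enrichment analysis, following the observation that
most Asian-population LD blocks fall within 50 kb of a gene; 20 kb is the
convention for candidate-gene selection). A variant at 1-based position $q$
belongs to a gene iff $\mathrm{start} - \mathrm{flank} \le q \le
\mathrm{end} + \mathrm{flank}$, counted once even when it hits several
genes. The enrichment statistic is the number of member variants with scan
$P$ below a threshold; the null distribution is built by $B$ shuffles in
which the **phenotype block** (outcome time/event plus the clinical
covariates) is permuted jointly across subjects while genotypes stay fixed,
and the empirical P is the fraction of shuffles with a count ≥ the observed
one (ties count; an add-one $(N+1)/(B+1)$ variant is available but the plain
$N/B$ estimator is the default).

Two design decisions deserve note:

* **Member-only rescanning.** Inside permutations only member variants are
  refit — the counts are identical to a genome-wide rescan at a fraction of
  the cost, since non-member variants never enter the statistic.
* **PCs travel with the genotypes.** Genotype-derived PCs are a property of
  the genotype side of the permutation and are not permuted.

Because the count statistic is integer-valued, the empirical P is lumpy at
stringent thresholds (with 40 member SNPs at threshold 0.05 the count's
largest atom is ~0.27). This does not affect validity — exchangeability of
observed and permuted counts makes the empirical P conservative — but it
does starve uniformity diagnostics of resolution, so the package's null
calibration test counts at a loose threshold (0.25) where the statistic has
real support, and tests detection power at $10^{-3}$ in a planted-signal
scenario.

### Clinical modelling

`cohortSummary()` follows clinical Table-1 conventions (percentages to one
decimal, median/IQR by linear interpolation). Optimal cutoffs for
continuous covariates maximize Youden's $J = \mathrm{sens} + \mathrm{spec}
- 1$ over observed values with the rule "≥ cutoff", ties broken toward the
smaller cutoff; the outcome for cutoff selection is the end-of-follow-up
event indicator (a plain ROC, not a time-dependent one). Univariate and
multivariate Cox tables use `survival::coxph`; the univariate-significance
screening rule (carry forward $P < 0.05$) is provided as an explicit,
optional step (`selectUnivariate()`) rather than hard-wired, and the scan's
covariate list is configuration, with the three established risk factors as
the default.

### Risk score

The combined model is one joint Cox fit over SNP dosages (additive) and the
binary clinical indicators, on a simple random training half (`ceiling(n/2)`
subjects; 777 subjects split 389/388). The per-subject risk score is the
uncentered linear predictor $\sum_j \hat\beta_j x_{ij}$; the training-set
median score is the high/low cutoff, with "score > cutoff" defining the
high-risk group (the median subject falls low). Clinical-only, genetic-only
and combined models are the same code path with different term lists.

Discrimination at a 60-month horizon (5-year risk) uses the
cumulative/dynamic time-dependent AUC with inverse-probability-of-censoring
weights from the Kaplan–Meier estimate of the censoring distribution: cases
are events by the horizon weighted by $1/\hat G(T_i^-)$, controls are
subjects observed beyond it weighted by $1/\hat G(\tau)$. When no censoring
occurs before the horizon this reduces *exactly* to the Mann–Whitney AUC of
the binary "event by horizon" outcome — the identity is asserted to
$10^{-10}$ in the tests, which is the main verification hook for the
hand-written estimator (no installed package provides an IPCW AUC). The
high- vs low-risk hazard ratio comes from a single-covariate Cox fit with
Wald CI and P.

## The synthetic cohort generator

`simConfig()` defaults encode the cohort structure the analysis assumes:

* **Cohort size and outcome**: 777 subjects; Weibull baseline hazard
  (shape 1.1, scale 560 months) with administrative censoring at 88 months
  plus exponential dropout at 0.007/month, calibrated once to give ~17%
  events and a median observed time near 70 months at the default clinical
  effect sizes.
* **Genotypes**: biallelic SNPs, MAF uniform on [0.01, 0.5], drawn from
  Hardy–Weinberg proportions via a latent Gaussian thresholded at the HW
  quantiles; an AR(1) latent correlation (ρ = 0.6) within blocks of 10
  consecutive variants induces LD that decays with distance. An optional
  clipped Gaussian dosage noise (quantized to 4 decimals so VCF round trips
  are exact) emulates imputed dosages, with an INFO-like score
  $1 - \sigma^2_{noise} / 2p(1-p)$.
* **Clinical covariates**: marginals patterned on an advanced NPC cohort
  (median age ~43, ~29% female, ~63% T3–T4, EBV DNA with a point mass at
  zero, IMRT dose ~70 Gy, cisplatin dose distributions with realistic zero
  fractions). Default log-hazard effects are the three established risk
  factors at their adjusted hazard ratios (1.72, 1.66, 1.46).
* **Annotation**: non-overlapping genes (lengths U(5–30 kb)) on one
  synthetic chromosome (enrichment logic is position-based, so one
  chromosome suffices); a configurable fraction of genes forms the
  "deafness" set, and variant positions can be planted so a target fraction
  falls within a flank of those genes.
* **Planted effects**: named per-variant log hazard ratios enter the
  outcome model additively. In experiments that plant strong effects, the
  baseline scale is raised to offset the added marginal hazard so the event
  rate stays near 17%.

What the generator does **not** emulate: realistic human LD maps and
recombination structure, chip-specific genotyping error, population
admixture and relatedness, informative censoring, or measurement error in
the clinical covariates. Passing tests therefore demonstrate correctness of
the statistical machinery under a well-specified proportional-hazards world,
not robustness to every failure mode of real cohort data.

## Numerical choices and degenerate inputs

* Cox fits: tolerance $10^{-9}$ on coefficient change, ≤ 50 iterations,
  step-halving (≤ 30 halvings); singular information, constant columns and
  separation drift (|β| > 20) are flagged `converged = FALSE` with `NA`
  outputs.
* HWE exact P uses log-factorial arithmetic with a $1+10^{-9}$ relative
  guard when comparing probabilities "no more probable than observed".
* PCA eigenvalues are clipped at zero; `k` beyond the numerical rank is an
  error; component signs are anchored to the largest-magnitude entry.
* Empty QC output is a warning (not an error); an empty enrichment
  membership or an empty risk-SNP list makes the pipeline mark the section
  absent rather than fail.
* All generator stages derive their RNG streams from `seed` plus a fixed
  per-stage offset, so stages are individually reproducible and a fixed
  config is byte-deterministic (manifest hashes are asserted equal in the
  tests).

## Problem sizes used by the test suite

Test problem sizes were chosen so Monte Carlo error sits comfortably below
the tested tolerances: null-scan calibration uses three replicate
800 × 5000 datasets (λ averaged across replicates, see above); planted-SNP
recovery uses 200 replicates of n = 800; enrichment calibration uses 50
null datasets with B = 100 and power uses 20 replicates with B = 200;
risk-score checks use 50 replicates each. The whole suite runs in about ten
minutes on one CPU.

## Known limitations

* No kinship/mixed-model association, X-chromosome models, multiallelic
  decomposition or haplotype phasing/imputation — inputs are assumed
  imputed and sample-QCed upstream.
* Competing risks are not modelled; death before hearing loss is treated as
  censoring.
* ROC cutoffs are derived on the full cohort (as the clinical-table
  convention suggests), which is optimistic if reused for prediction; the
  risk model avoids this by fixing its clinical codings before the split.
* The IPCW AUC assumes censoring independent of covariates (marginal KM
  weights).
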