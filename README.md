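# otoscan

Survival GWAS, gene-set enrichment and risk modelling for
treatment-induced hearing loss.

## What this package is for

Hearing loss after platinum-based chemoradiotherapy (common in
nasopharyngeal carcinoma, where the radiation field borders the auditory
organs) is progressive and untreatable, and clinical factors only partly
explain who is affected. `otoscan` is an R implementation of the full
statistical pipeline for studying germline modifiers of this ototoxicity as
a right-censored time-to-event outcome:

* **Variant QC** — call rate ≥ 95%, MAF ≥ 0.01, Hardy–Weinberg exact
  *P* ≥ 10⁻¹², imputation INFO ≥ 0.8 — plus genotype PCA for ancestry
  covariates.
* **Per-SNP Cox scan** — for each variant with dosage *g*, the additive
  proportional-hazards model
  λ(t) = λ₀(t)·exp(γg + βᵀz), fit by Newton–Raphson on the
  Efron-adjusted partial likelihood (compiled core), with Wald HR, 95% CI
  and *P*; genomic inflation λ_GC and QQ/Manhattan tables for diagnostics;
  stratified and subgroup analyses; Kaplan–Meier / log-rank utilities.
* **Permutation gene-set enrichment** — counts of deafness-gene-region SNPs
  (gene bodies ± 50 kb flank) below a scan *P* threshold, compared with a
  null built by jointly permuting the phenotype block (outcome + clinical
  covariates) against fixed genotypes; empirical
  *P* = #{N_b ≥ N_obs}/B.
* **Clinical Cox modelling** — Table-1 style summaries, Youden-*J* ROC
  cutoffs, univariate and multivariate Cox with optional significance
  screening.
* **Combined risk score** — one joint Cox fit over SNP dosages and clinical
  indicators on a random training half; score = coefficient-weighted sum;
  training-median cutoff; censoring-aware (IPCW) time-dependent AUC at a
  60-month horizon and the high- vs low-risk hazard ratio, on train, test
  and pooled sets.
* **Synthetic cohort generator** — LD-blocked Hardy–Weinberg genotypes,
  Table-1-like clinical marginals, Weibull proportional-hazards outcomes
  with administrative + dropout censoring, planted SNP effects and gene
  annotations. Because real cohorts of this kind are access-controlled, the
  generator is what makes the whole pipeline testable at desk scale.

Standard formats are used throughout: VCF v4.2 (GT or DS) in/out, phenotype
TSV, BED (0-based half-open) gene intervals, newline-delimited gene sets.

## Worked example

Simulate a 777-subject cohort, plant one HR-2 variant inside a
deafness-gene region, and run the pipeline:

```r
library(otoscan)

cfg <- simConfig(n_subjects = 777L, n_variants = 2000L, seed = 42L,
                 deafness_variant_fraction = 0.25)
ann <- simulateGeneAnnotation(cfg)
pos <- sampleVariantPositions(cfg, ann)
g   <- simulateGenotypes(cfg, positions = pos)
mem <- mapSnpsToRegions(g, ann$genes, gene_subset = ann$deafness)

causal <- mem$membership[100]                      # "snp00428"
cfg2 <- simConfig(n_subjects = 777L, n_variants = 2000L, seed = 42L,
                  causal_effects = setNames(log(2), causal))
cohort <- simulateOutcomes(g, simulateClinical(cfg2), cfg2)

qc   <- variantQC(g)
pcs  <- genotypePCA(qc$genotypes, 2)$scores
scan <- gwasScan(qc$genotypes, cohort, pcs)
st   <- as.data.frame(scanTable(scan))
st[order(st$p)[1:3], c("variant", "eaf", "hr", "ci_low", "ci_high", "p")]
#>       variant    eaf   hr ci_low ci_high        p
#> 428  snp00428 0.0460 2.60  1.726   3.930 5.11e-06
#> 1610 snp01614 0.0767 1.79  1.265   2.536 1.02e-03
#> 1309 snp01312 0.2813 0.63  0.476   0.835 1.29e-03
genomicInflation(st$p)
#> 0.966
```

The planted variant is the top hit (HR 2.60, CI 1.73–3.93 — the true HR 2
is inside the interval) and the scan shows no global inflation. Enrichment
of the deafness gene set and the combined risk score:

```r
er <- permutationEnrichment(qc$genotypes, cohort, pcs,
                            intersect(mem$membership, rownames(qc$genotypes)),
                            thresholds = c(5e-2, 1e-3, 1e-4),
                            B = 200L, seed = 7L)
er
#> EnrichmentResult: 200 permutations
#>  threshold observed empirical_p
#>      5e-02       22       0.725
#>      1e-03        1       0.395
#>      1e-04        1       0.055

sp <- splitTrainTest(cohort, 0.5, seed = 1L)          # 389 / 388
model <- fitRiskModel(sp$train, qc$genotypes, snp_ids = causal)
model <- evaluateRiskModel(model, list(
  train = list(cohort = sp$train, genotypes = qc$genotypes),
  test  = list(cohort = sp$test,  genotypes = qc$genotypes)))
model
#> RiskModel: 1 SNP + 3 clinical terms; horizon 60 months
#>   training-median cutoff: 0.7919
#>   train: AUC 0.681, high-vs-low HR 2.32 (P 0.000625)
#>   test: AUC 0.556, high-vs-low HR 1.27 (P 0.275)
```

With a single planted variant, the gene-set signal is concentrated at the
stringent threshold (empirical *P* = 0.055 at 10⁻⁴, i.e. 11 of 200 null
shuffles matched the observed count) and the one-SNP risk model adds only
modest discrimination over the clinical terms — both exactly what this
amount of planted signal should produce. `runPipeline()` chains all stages
from a single config (or YAML file) and writes every artifact with an
MD5 manifest and a JSON run report.

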