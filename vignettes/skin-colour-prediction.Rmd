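---
title: "Predicting categorical skin colour from pigmentation SNPs"
author: "skintyper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting categorical skin colour from pigmentation SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skintyper)
```

## The problem

Skin colour is one of the externally visible characteristics that can be
predicted from DNA for investigative and anthropological use. Unlike eye
and hair colour, its genetic architecture is strongly structured by
continental ancestry *and* shows substantial variation within continental
groups, so a usable predictor has to combine markers that separate light
from dark skin across continents with markers that resolve very pale
versus pale versus intermediate tones within Europeans. `skintyper`
implements such a predictor — a multinomial logistic regression (MLR) over
five lightness-ordered categories on a ranked 36-SNP panel — together with
the selection pipeline that produces it and the validation protocol that
measures it.

## Phenotype scales

Two phenotyping routes are supported, with deterministic maps between
them:

* **Fitzpatrick skin types 1–6**, the dermatological scale combining
  perceived colour and tanning response. Types 3 and 4 are
  dermatologically close and condense into one prediction category,
  giving the five-category scale: 1 → Very Pale, 2 → Pale, 3/4 →
  Intermediate, 5 → Dark, 6 → Dark-Black (`fitzpatrickTo5cat()`). The
  three-category scale groups types 1–4 into Light, with 5 → Dark and
  6 → Dark-Black (`fitzpatrickTo3cat()`); equivalently,
  `collapse5to3()` merges Very Pale/Pale/Intermediate into Light.
* **CIE L\*** readings from a spectrophotometer, binned into White
  (L\* 60.36–74.14), Intermediate (59.32–40.04) and Black (39.75–29.99)
  by `labTo3cat()`. Range membership is inclusive at both endpoints. The
  published ranges leave small gaps (60.36→59.32 and 40.04→39.75)
  unassigned: in `strict` mode a reading in a gap is an error; in
  `nearest` mode it takes the category of the nearest range boundary,
  with exact ties resolved to the lighter category. This keeps the map
  total and monotone in L\*.

Category order is always lightness-descending; it fixes the ordinal
coding used by the association filter and the tie-breaking order of the
classifier.

## The marker panel

`skinPanel()` ships a 77-SNP candidate panel of previously
pigmentation-associated variants with three nested tiers:

* **candidate** (77 SNPs): everything genotyped;
* **associated** (53 SNPs): squared partial correlation with the ordinal
  skin colour scale significant at p < 0.05 (uncorrected), adjusting for
  sex and population;
* **final** (36 SNPs from 16 genes): the AIC-selected prediction set,
  ranked 1–36 by predictive contribution (rank 1 is `SLC24A5`
  rs1426654).

The panel file (`inst/extdata/skin_colour_panel.tsv`) is tab-separated
with one row per SNP and `.` for absent values; `loadPanel()` /
`writePanel()` round-trip it byte-identically. Transcription notes:

* The association statistics (r², p) and the auxiliary fitted-glm
  coefficients are stored as metadata only; predictions never use them.
  Shipped models are fitted fresh from data.
* rs2228479 is also known under the spelling rs228479; the MC1R
  N29insA indel (rs312262906, alleles `-`/`insA`) and Y152OCH stop
  variant (rs201326893) are recorded verbatim; none of the three reaches
  the final model. Synonyms are kept in a dedicated column.
* rs12896399 is annotated to `SLC24A4` (its positional label is the
  upstream transcript `LOC105370627`); with that labelling the final
  tier spans exactly 16 distinct genes.
* The source table does not machine-readably flag which allele of each
  printed pair is counted; the package adopts the convention that the
  **effect allele is the second listed allele** (for the indel, `insA`).
  This is an internal orientation convention: dosage orientation only
  needs to be consistent between training and prediction, and the VCF
  reader reconciles external files onto it.

## Genotype handling

Genotypes are effect-allele dosages in {0, 1, 2, missing}, held as a
`SkinGenotypes` object (a `SummarizedExperiment` with SNPs as rows,
samples as columns, and sample metadata in `colData`). Two readers are
provided:

* `readDosageCsv()` for the tabular interchange format
  (`sample_id` + one column per rsid, `NA` or empty for missing);
* `readGenotypeVcf()` for VCF 4.x, matching records by rsid and falling
  back to (chromosome, position). Allele reconciliation accepts an exact
  REF/ALT match, a swapped match (the effect allele may be REF, which
  complements the dosage), or a strand-flipped match for non-ambiguous
  SNVs. Strand-ambiguous pairs (A/T, C/G — e.g. rs16891982 C/G) must
  match exactly or the SNP is set missing with a warning, since a flip
  cannot be distinguished from a swap. Half-calls (`0/.`) and genotypes
  containing a non-panel allele are conservatively missing.

Model fitting and marker selection require complete genotypes
(`completeCaseFilter()`), mirroring how such models are trained in
practice; prediction additionally offers a `drop_terms` policy that
omits missing SNPs from every linear predictor and flags the output as
degraded — intended for casework-style inputs, at the cost of
probabilities no longer being calibrated against the training model.

## The prediction model

With dosages `x` at `k` SNPs and `K` ordered categories, non-reference
category `m` has linear predictor `alpha_m + beta_m' x` and

$$\pi_m = \frac{\exp(\alpha_m + \beta_m'x)}{1 + \sum_{m'}\exp(\alpha_{m'} + \beta_{m'}'x)},$$

with the reference category taking the remaining mass. Conventions and
numerical choices:

* **Reference category** is the first (lightest) category — Very Pale on
  the 5-category scale, Light on the 3-category scale. Model files record
  it explicitly.
* **Fitting** (`fitMlr()`) is Newton–Raphson on the full observed
  information matrix with step-halving; convergence when the largest
  parameter update falls below `tol` (default 1e-8, within 100
  iterations). Standard errors come from the inverse information at the
  optimum. Non-convergence is an error carrying the last iterate.
* **Ridge**: a default penalty of 1e-6 on betas (never intercepts)
  stabilises quasi-separated fits, which occur routinely when a rare
  category is nearly determined by a strong marker in a small training
  split. The penalty is switchable to 0 for a pure ML fit; at 1e-6 its
  bias is orders of magnitude below one standard error.
* **Classification** takes the argmax; exact ties go to the earliest
  (lightest) category and are flagged.
* **Model files** are TSV with two header lines (category order,
  reference) and a term table; numbers are written as `%.17g`, so
  write/read round-trips are bit-exact.
* `logLikelihood()` reports an explicit `-Inf` when a zero probability
  meets an observed label; `modelAIC()` uses `2p − 2lnL` with
  `p = (K−1)(k+1)` free parameters.

## Marker selection and validation

The pipeline reproduces the three-stage selection design:

1. **Association filter** (`associationFilter()`): per SNP, dosage and
   the ordinal-coded phenotype (Very Pale = 1 … Dark-Black = 5) are
   residualized on an intercept, a sex indicator and population
   indicators; the partial correlation `r` of the residuals gives
   `r²` and a p value via `t = r·sqrt((n−2−c)/(1−r²))` with `c`
   covariate columns. SNPs are kept at p < 0.05, uncorrected — the
   filter is a screening step, not an inference, so no multiplicity
   correction is applied. Constant or covariate-determined dosage
   columns report r² = 0, p = 1. The ordinal coding reflects the
   lightness ordering of the categories; with covariates held fixed it
   is the natural single-degree-of-freedom screen for a monotone
   dosage–darkness trend.
2. **AIC subset selection** (`aicSelect()`): greedy stepwise search
   minimising the MLR's AIC, backward from the full associated set by
   default (the bidirectional strategy additionally reconsiders dropped
   markers). The search stops when no single move lowers the AIC and can
   reach the intercept-only model; the visited-AIC trace is returned for
   audit. On well-separated instances the greedy search recovers the
   exhaustive best subset, which the tests verify against a brute-force
   oracle up to 10 candidates.
3. **Replicated cross-validation** (`crossValidate()`): the complete-case
   cohort is split 80/20 uniformly at random (`split8020()`; for
   n = 1423 that is exactly 1138 train / 285 test), the model is refitted
   on the training split and scored on the test split by per-category
   one-vs-rest AUC; the mean ± sd over replicates is reported. The full
   protocol uses 1000 replicates; the packaged tests and acceptance
   script use 100, which already pins the mean AUC to ±0.01 or better.
   Splits are unstratified; a split whose training part lacks a category
   is redrawn (and counted). Replicate `r` uses seed `base + r`, so any
   single replicate can be reproduced in isolation.
   `incrementalAucCurve()` refits on the full data adding SNPs in rank
   order, tracing each marker's accumulated contribution.

## Evaluation

`aucOneVsRest()` uses the Mann–Whitney pair-counting form (midranks, ties
count one half). This is deterministic and free of interpolation
choices; the test suite verifies to 1e-12 that it equals the trapezoidal
area under the empirical threshold-sweep ROC. Confusion-matrix metrics
(sensitivity, specificity, PPV, NPV) are one-vs-rest with zero
denominators reported as `NA`, never as 0, and serialized as `NA` in CSV.

The comparison baseline (`fitNaiveBayes()`) is a naive Bayes genotype
classifier of the kind used by earlier web-based skin colour predictors:
class priors are category frequencies and each SNP contributes an
independent categorical likelihood over its genotype state (0/1/2) with
an additive pseudo-count (default 0.5). It conditions on genotype state
rather than allele count, mirroring that classifier family.
`compareModels()` lays both models' per-category AUC /
sensitivity / specificity / PPV / NPV side by side; AUC can be computed
from class probabilities (default) or from hard calls.

## Synthetic cohorts

No training cohort is distributable, so the generator
(`simulateCohort()`) creates cohorts with the statistical structure the
model assumes: within each population, dosages are Binomial(2, f) under
Hardy–Weinberg with population-specific effect-allele frequencies; each
sample's category is drawn from a true MLR model's probabilities at its
genotype; sex is Bernoulli; missingness (if requested) is applied
completely at random *after* phenotype generation. Everything derives
from one integer seed.

`makeTrueModel()` builds plausible generating models: per-SNP weights
decline with rank, per-category coefficients grow with darkness, and
intercepts are centred so that at the mean genotype the category
proportions match a target — by default 6/44/42/3/5 percent from
Very Pale to Dark-Black, the composition of a predominantly European
multi-population study cohort.

Canned fixtures (`makeFixture()`):

* `small` — 3 populations × 50, the 6 top-ranked panel SNPs; fast
  end-to-end runs.
* `medium` — 5 populations × 300 with the full 36-SNP final panel and
  moderately differentiated frequencies; emulates the scale (n = 1500 vs
  1423) and structure of a global training cohort.
* `confounded` — 2 populations × 250 where the last SNP (`null_snp`) has
  no phenotype effect but strongly stratified frequencies (0.9 vs 0.1).
  Because the populations also differ in phenotype, the null SNP shows a
  strong marginal association that the population covariate must remove
  — the canonical stress test for the association filter.

What the generator does **not** emulate: linkage disequilibrium between
panel SNPs (dosages are independent given the population), admixed
individuals, genotyping error, informative missingness, and
environmental contributions to phenotype (tanning). Consequently,
passing tests demonstrate that the pipeline's statistics behave
correctly under the model's own assumptions — calibration, recovery,
selection, ranking — not that any particular accuracy level will be
attained on real cohorts, where inter-marker correlation and phenotype
noise reduce effective information.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` choose problem sizes that make
the statistical assertions sharp while keeping runs quick: n = 5000 for
parameter recovery (36 SNPs, 5 categories), n = 50,000 single-population
draws for law-of-large-numbers checks (allele frequency to ±0.005,
category proportions to ±0.01), 100 cross-validation replicates
(standard error of a mean AUC well under 0.01), exhaustive best-subset
oracles up to 2^10 subsets, and 1000 random score/label fixtures for the
AUC equivalence. Every stochastic step takes an explicit integer seed,
and the acceptance script derives all of its seeds from its `--seed`
argument.

## Known limitations

* The packaged panel carries the published association metadata, but the
  shipped software never reuses published regression coefficients: models
  must be trained on data (real or simulated) before prediction.
* The `drop_terms` prediction policy degrades gracefully but is not a
  principled missing-data treatment (no imputation is attempted).
* One-vs-rest AUC for middle categories of an ordered scale is
  intrinsically pessimistic: neighbouring categories share most of the
  genotype signal, so Pale/Intermediate/Dark AUCs sit well below the
  extremes even when the model is exactly correct — the same pattern
  reported for real cohorts.
* The association filter's partial-correlation screen assumes an
  approximately linear dosage–ordinal trend; markers with purely
  heterotic effects would be under-ranked.
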