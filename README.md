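# skintyper

DNA-based prediction of categorical human skin colour from a curated panel
of pigmentation SNPs, for forensic and anthropological genetics.

Externally visible characteristics such as eye, hair and skin colour can be
predicted from a small number of genotyped DNA markers. Skin colour is the
hardest of the three because its variation is strongly structured both
*between* continental groups and *within* them (very pale to olive tones
among Europeans, for example). `skintyper` implements a global skin colour
prediction system built around a 36-SNP multinomial logistic regression
(MLR) model over five lightness-ordered categories — Very Pale, Pale,
Intermediate, Dark, Dark-Black — and a collapsed three-category scale
(Light, Dark, Dark-Black), together with the full marker-selection and
validation pipeline that produces and evaluates such a model.

## The model

Let `x = (x_1, ..., x_k)` be the effect-allele dosages (0, 1 or 2 counted
alleles) of an individual at the `k` panel SNPs, and let the skin colour
category `y` take one of `K` ordered values with category 1 (the lightest)
as reference. The model assigns probabilities by multinomial logistic
regression:

    pi_m = exp(alpha_m + beta_m' x) / (1 + sum_m' exp(alpha_m' + beta_m' x))   (m = 2..K)
    pi_1 = 1 / (1 + sum_m' exp(alpha_m' + beta_m' x))

The predicted category is the argmax of `(pi_1, ..., pi_K)`. Models are
fitted by Newton–Raphson maximum likelihood (optionally with a tiny ridge
on the betas for quasi-separated data) on complete-genotype samples only.

Around the model core the package provides:

* **Panel** (`skinPanel()`): the transcribed 77-SNP candidate panel with
  its nested tiers — 53 SNPs passing the sex- and population-adjusted
  association filter, and the final ranked 36-SNP predictor set spanning
  16 genes (`SLC24A5`, `IRF4`, `MC1R`, `OCA2`, `SLC45A2`, `HERC2`, `TYR`,
  `RALY`, `DEF8`, `PIGU`, `ASIP`, `SLC24A4`, `TYRP1`, `KITLG`, `ANKRD11`,
  `BNC2`).
* **Genotype I/O**: effect-allele dosage matrices from VCF
  (`readGenotypeVcf()`, with REF/ALT swap and strand-flip reconciliation)
  or CSV (`readDosageCsv()`), backed by `SummarizedExperiment`;
  `completeCaseFilter()` enforces the complete-genotype rule.
* **Phenotypes**: Fitzpatrick skin types 1–6 condensed to the 5- and
  3-category scales (`fitzpatrickTo5cat()`, `fitzpatrickTo3cat()`,
  `collapse5to3()`), and CIE L\* spectrophotometer readings binned to
  White/Intermediate/Black (`labTo3cat()`).
* **Selection**: partial-correlation association filtering
  (`associationFilter()`), stepwise AIC subset selection (`aicSelect()`),
  replicated 80/20 cross-validation with per-category one-vs-rest AUC
  (`crossValidate()`, `split8020()`), and rank-incremental AUC curves
  (`incrementalAucCurve()`).
* **Evaluation**: pair-counting AUC (`aucOneVsRest()`), confusion-matrix
  metrics (`confusionTable()`, `metricsFromConfusion()`), a naive Bayes
  genotype-classifier baseline (`fitNaiveBayes()`), and side-by-side model
  comparison tables (`compareModels()`).
* **Synthetic cohorts** (`simulateCohort()`, `makeFixture()`):
  multi-population Hardy–Weinberg genotypes with categorical phenotypes
  drawn from a known true model, so every pipeline stage is testable
  without access to any real cohort.
* **CLI** (`skintyperCli()`, `inst/cli/skintyper.R`): `predict`, `train`,
  `select`, `cv`, `compare` and `simulate` subcommands over the CSV/TSV
  interchange formats.

## Worked example

```r
library(skintyper)

panel <- skinPanel()
panel
#> SnpPanel with 77 SNPs
#>   candidate  77
#>   associated 53
#>   final      36

head(panelSnps(subsetTier(panel, "final"))[, c("rsid", "locus", "rank", "assoc_r2")], 5)
#>         rsid   locus rank assoc_r2
#> 1  rs1426654 SLC24A5    1   0.1500
#> 2 rs12203592    IRF4    2   0.0201
#> 3  rs1805007    MC1R    3   0.0268
#> 4  rs1800414    OCA2    4   0.0470
#> 5 rs16891982 SLC45A2    5   0.1420

# a deterministic synthetic training cohort: 5 populations x 300 samples,
# the 36 final-panel SNPs
cohort <- makeFixture("medium")
model  <- fitMlr(sampleDosages(cohort$genotypes), cohort$categories)
model
#> SkinColourModel: 5 categories ( VeryPale > Pale > Intermediate > Dark > DarkBlack ), reference VeryPale
#> 36 SNP predictors
#> fitted: logLik -1409.819, converged TRUE (8 iterations), n = 1500

# replicated 80/20 cross-validation, per-category one-vs-rest AUC
crossValidate(sampleDosages(cohort$genotypes), cohort$categories,
              replicates = 20, seed = 42)
#>       category mean_auc sd_auc n_defined
#> 1     VeryPale    0.886 0.0229        20
#> 2         Pale    0.712 0.0224        20
#> 3 Intermediate    0.703 0.0303        20
#> 4         Dark    0.697 0.0498        20
#> 5    DarkBlack    0.931 0.0138        20

# predict one individual
p <- predictProbabilities(model, sampleDosages(cohort$genotypes)[1, ])
round(p, 4)
#>     VeryPale         Pale Intermediate         Dark    DarkBlack
#>       0.0038       0.0949       0.4458       0.1745       0.2811
classifyProbabilities(p)
#>       category   tie
#> 1 Intermediate FALSE
```

The AUC column reads as usual: 0.5 is random, 1 is perfect. Mid-scale
categories (Pale/Intermediate/Dark) are intrinsically harder one-vs-rest
than the extremes, because neighbouring categories share most of their
genotype signal — the same pattern expected on real cohorts.

The same workflows are scriptable:

```sh
Rscript inst/cli/skintyper.R simulate --fixture medium --out-dir cohort/
Rscript inst/cli/skintyper.R train   --genotypes cohort/dosages.csv \
    --metadata cohort/metadata.csv --out model.tsv
Rscript inst/cli/skintyper.R predict --genotypes cohort/dosages.csv \
    --model model.tsv --out predictions.csv
```

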