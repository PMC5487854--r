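Package: skintyper
Title: Global Skin Colour Prediction from Pigmentation SNP Genotypes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for DNA-based prediction of categorical human skin
    colour from a curated panel of pigmentation-associated SNPs. Implements
    a multinomial logistic regression prediction model over five
    (Very Pale to Dark-Black) and three (Light/Dark/Dark-Black) skin colour
    categories on effect-allele dosages, together with the accompanying
    marker-selection pipeline (sex- and population-adjusted partial
    correlation filter followed by stepwise AIC subset selection),
    replicated 80/20 cross-validation with one-vs-rest AUC reporting, a
    naive Bayes genotype-classifier baseline for model comparison, and a
    multi-population synthetic cohort simulator for end-to-end testing.
    Genotypes are handled as effect-allele dosage matrices backed by
    SummarizedExperiment and can be imported from VCF or tabular files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    nnet,
    jsonlite
biocViews: SNP, Genetics, Classification, Regression
Config/testthat/edition: 3
RoxygenNote: 7.3.3
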