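Package: staygreenGT
Title: Stay-Green Senescence Traits and Genotype-by-Treatment GWAS for
    Heat-Stressed Wheat Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models flag-leaf senescence from chlorophyll kinetics with a
    four-parameter logistic curve (pseudo-point augmentation, two-pass
    outlier handling, closed-form stay-green traits), fits split-plot
    mixed models with kinship-structured genotype and genotype-by-treatment
    random effects by average-information REML, runs a SNP main-effect and
    SNP-by-treatment interaction genome-wide association scan with
    leave-one-chromosome-out kinship and an effective-test-count
    significance threshold, and delimits QTL confidence intervals by
    linkage-disequilibrium clustering and local LD decay.  A synthetic-data
    generator emulating the split-plot heat-stress study design (biallelic
    SNP panels with block LD, polygenic and QTL phenotype effects,
    per-plant senescence curves) makes the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
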