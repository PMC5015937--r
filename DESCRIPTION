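Package: htpblup
Title: Multi-Trait Pedigree and Genomic Prediction with High-Throughput
    Phenotyping Secondary Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for improving pedigree and genomic prediction of
    grain yield in wheat field trials using aerially measured secondary
    traits (canopy temperature and vegetation indices). Provides quality
    control of plot-level longitudinal phenotypes via repeatability models
    and Studentized-residual outlier screening, marker filtering and
    construction of genomic (VanRaden) and pedigree (tabular method)
    relationship matrices, restricted maximum likelihood estimation of
    univariate and multi-trait mixed models with Kronecker-structured
    genetic covariance, best linear unbiased estimation and prediction of
    line genetic values, heritability and genetic-correlation estimation,
    cross-validated prediction accuracy with secondary traits observed on
    selection candidates, and a field-trial simulator with configurable
    heritabilities and genetic correlations for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
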