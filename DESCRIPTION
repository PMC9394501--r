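Package: ykincohort
Title: Kin-Cohort Association Analysis of Y-Chromosome Haplogroups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for testing male-specific Y-chromosome (MSY) haplogroups
    against cardiovascular phenotypes in large cohorts, with a kin-cohort
    validation design in which father phenotypes act as replication and
    mother phenotypes as a negative control. Provides haplogroup assignment
    from haploid Y-SNP genotypes on a user-supplied phylogeny, composite and
    paragroup indicator construction, iterative Tukey outlier filtering,
    medication-adjusted blood pressure and lipid phenotypes, coronary artery
    disease classification from ICD/OPCS code lists, population-structure
    robust linear/logistic/Cox association models, a PCA-based effective
    number of independent tests, genetic inference of father-son pairs, a
    bootstrap estimate of heart-disease-as-CAD-proxy accuracy, and a seeded
    synthetic cohort generator with geographically structured lineage
    frequencies for end-to-end validation without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    flexsurv,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
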