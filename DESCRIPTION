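Package: casespec
Title: Case-Specificity Scoring and Power Simulation for Small
    Case-Control Exome Studies
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Prioritizes candidate disease-marker variants in small
    case-control exome cohorts using additive case-specificity scores,
    Monte-Carlo power characterization over true minor allele frequency
    and odds ratio, MAF-adjusted empirical p-values from resampling
    nulls, biologically motivated protein-altering variant filters, and
    a conventional single-variant and gene-burden association layer.
    Includes a synthetic-cohort generator (Hardy-Weinberg genotypes
    under configurable allelic odds ratios, annotations, and
    covariate-linked quantitative traits) so that the whole pipeline is
    testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
biocViews: GeneticVariability, SNP, VariantAnnotation, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'casespec-package.R'
    'AllClasses.R'
    'scores.R'
    'association.R'
    'filters.R'
    'io.R'
    'null-models.R'
    'simulate.R'
    'pipeline.R'
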