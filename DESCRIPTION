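Package: TempLinkNe
Title: Contemporary Effective Population Size from Temporally Spaced
    Samples of Linked Loci
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Moment-based temporal estimation of contemporary effective
    population size (Ne) from two samples of biallelic loci taken t
    generations apart, designed for dense, genetically linked marker
    panels. Implements the temporal F statistics (arithmetic and
    ratio-of-sums forms), the Waples plan-II point estimator of Ne, and
    linkage-adjusted confidence intervals obtained by eigen-decomposing
    the between-locus correlation matrix of standardized allele-frequency
    changes and Monte-Carlo sampling the resulting chi-square mixture.
    Includes pairwise LD estimation from phased haplotypes or unphased
    genotypes (EM under Hardy-Weinberg with a composite-LD fallback),
    Haldane map conversion of physical distances, VCF input/output, and a
    forward Wright-Fisher simulator with recombination used to validate
    the moment formulas and confidence-interval coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: PopulationGenetics, SNP, Coverage, Software
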