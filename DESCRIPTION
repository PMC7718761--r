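Package: rohscan
Title: Runs of Homozygosity, Genomic Inbreeding and ROH Islands from SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
                  role = c("aut", "cre"))
Description: Detection and characterisation of runs of homozygosity (ROH) in
    diploid biallelic SNP genotypes from multi-population cohorts. Implements
    variant quality control (minor-allele, call-rate and exact Hardy-Weinberg
    filters), per-population diversity statistics (observed and expected
    heterozygosity, polymorphic marker ratio, Wright's Fis), a sliding-window
    ROH caller with the standard seven-criterion parameterisation, ROH
    length-class, chromosome-coverage and genomic-inbreeding (FROH) summaries,
    and ROH-island detection with interval intersection against annotation
    tracks such as QTL regions. Ships a cohort simulator that plants
    autozygous tracts with known coordinates, providing ground truth for
    end-to-end validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
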