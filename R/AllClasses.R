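# S4 containers shared across the pipeline. Genotype calls are coded as
# integers: 0 = homozygous reference, 1 = heterozygous, 2 = homozygous
# alternate, NA = missing.

#' GenotypeCohort: diploid SNP genotypes for a multi-population cohort
#'
#' Extends [SummarizedExperiment::RangedSummarizedExperiment]. Rows are
#' biallelic SNPs (width-1 `GRanges`, positions strictly increasing within a
#' chromosome), columns are individuals. The single assay `"GT"` holds integer
#' genotype codes (0 hom-ref, 1 het, 2 hom-alt, NA missing). `colData` carries
#' a `population` factor assigning every individual to exactly one population.
#'
#' @aliases GenotypeCohort-class
#' @exportClass GenotypeCohort
setClass("GenotypeCohort", contains = "RangedSummarizedExperiment")

setValidity("GenotypeCohort", function(object) {
    msg <- character()
    if (!"GT" %in% assayNames(object)) {
        msg <- c(msg, "assay 'GT' is required")
    } else {
        gt <- assay(object, "GT")
        if (!is.integer(gt)) {
            msg <- c(msg, "'GT' must be an integer matrix")
        } else {
            v <- gt[!is.na(gt)]
            if (length(v) && (min(v) < 0L || max(v) > 2L))
                msg <- c(msg, "'GT' codes must be 0, 1, 2 or NA")
        }
    }
    if (!"population" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'population' column")
    rr <- rowRanges(object)
    if (length(rr) && any(width(rr) != 1L))
        msg <- c(msg, "variant ranges must have width 1")
    if (length(rr) > 1L) {
        chr <- as.character(seqnames(rr))
        pos <- start(rr)
        same <- chr[-1L] == chr[-length(chr)]
        if (any(same & diff(pos) <= 0L))
            msg <- c(msg,
                "positions must be strictly increasing within each chromosome")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GenotypeCohort
#'
#' @param calls Integer matrix, variants x individuals, values 0/1/2/NA.
#' @param variants `GRanges` of width-1 SNP positions, one per row of `calls`.
#'   Optional `ref`/`alt` metadata columns are kept for VCF output.
#' @param populations Character or factor of length `ncol(calls)` assigning
#'   each individual to a population (order of first appearance defines the
#'   population level order).
#' @return A [GenotypeCohort-class] object, rows sorted by chromosome (in
#'   `seqlevels` order) and position.
#' @examples
#' calls <- matrix(c(0L, 1L, 2L, NA, 0L, 0L), nrow = 3,
#'                 dimnames = list(NULL, c("s1", "s2")))
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 200, 300), width = 1))
#' gc <- GenotypeCohort(calls, gr, c("A", "A"))
#' @export
GenotypeCohort <- function(calls, variants, populations) {
    if (!is.matrix(calls))
        stop("'calls' must be a matrix")
    storage.mode(calls) <- "integer"
    if (length(variants) != nrow(calls))
        stop("'variants' length must match nrow(calls)")
    if (length(populations) != ncol(calls))
        stop("'populations' must assign every individual to one population")
    if (is.null(colnames(calls)))
        colnames(calls) <- paste0("ind", seq_len(ncol(calls)))
    populations <- factor(as.character(populations),
                          levels = unique(as.character(populations)))
    chr <- as.character(seqnames(variants))
    o <- order(match(chr, unique(chr)), start(variants))
    variants <- variants[o]
    calls <- calls[o, , drop = FALSE]
    rownames(calls) <- paste(as.character(seqnames(variants)),
                             start(variants), sep = ":")
    names(variants) <- rownames(calls)
    se <- SummarizedExperiment(
        assays = list(GT = calls),
        rowRanges = variants,
        colData = DataFrame(population = populations,
                            row.names = colnames(calls)))
    new("GenotypeCohort", se)
}

#' GenomeLayout: chromosome sizes and marker density for simulation
#'
#' @slot chromosomes `data.frame` with columns `chrom` (unique labels) and
#'   `length` (bp, > 0), ordered as the chromosomes should appear.
#' @slot snpDensity Mean SNPs per bp (e.g. `1/5000` for one SNP every 5 kb).
#' @aliases GenomeLayout-class
#' @exportClass GenomeLayout
setClass("GenomeLayout",
         representation(chromosomes = "data.frame", snpDensity = "numeric"))

setValidity("GenomeLayout", function(object) {
    ch <- object@chromosomes
    msg <- character()
    if (!all(c("chrom", "length") %in% colnames(ch)))
        msg <- c(msg, "'chromosomes' needs columns 'chrom' and 'length'")
    else {
        if (anyDuplicated(ch$chrom)) msg <- c(msg, "chromosome names must be unique")
        if (any(ch$length <= 0)) msg <- c(msg, "chromosome lengths must be > 0")
    }
    if (length(object@snpDensity) != 1L || object@snpDensity <= 0)
        msg <- c(msg, "'snpDensity' must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' Define a genome layout
#'
#' The default is a desk-scale genome of three chromosomes (50, 20 and 5 Mb)
#' mirroring the macro-, intermediate- and micro-chromosome size tiers of an
#' avian karyotype, at one SNP per 5 kb (about 15,000 SNPs).
#'
#' @param chromosomes `data.frame` with columns `chrom`, `length` (bp).
#' @param snpDensity Mean SNPs per bp.
#' @return A [GenomeLayout-class] object.
#' @export
genomeLayout <- function(chromosomes = data.frame(
                             chrom = c("chr1", "chr2", "chr3"),
                             length = c(50e6, 20e6, 5e6)),
                         snpDensity = 1 / 5000) {
    new("GenomeLayout",
        chromosomes = data.frame(chrom = as.character(chromosomes$chrom),
                                 length = as.numeric(chromosomes$length),
                                 stringsAsFactors = FALSE),
        snpDensity = snpDensity)
}

#' PopulationProfile: parameters of one simulated population
#'
#' @slot name Population label.
#' @slot nIndividuals Number of diploid individuals (>= 1).
#' @slot targetHet Target mean per-SNP heterozygosity in [0, 0.5).
#' @slot missingRate Per-call missing rate in [0, 1].
#' @slot withinTractHetRate Rate of erroneous heterozygous calls inside planted
#'   autozygous tracts, in [0, 1].
#' @slot tracts `data.frame` with columns `minMb`, `maxMb`, `count`: for each
#'   tract length class, the expected number of planted tracts per individual.
#' @aliases PopulationProfile-class
#' @exportClass PopulationProfile
setClass("PopulationProfile",
         representation(name = "character", nIndividuals = "integer",
                        targetHet = "numeric", missingRate = "numeric",
                        withinTractHetRate = "numeric", tracts = "data.frame"))

setValidity("PopulationProfile", function(object) {
    msg <- character()
    if (object@nIndividuals < 1L) msg <- c(msg, "'nIndividuals' must be >= 1")
    if (object@targetHet < 0 || object@targetHet >= 0.5)
        msg <- c(msg, "'targetHet' must lie in [0, 0.5)")
    for (s in c("missingRate", "withinTractHetRate")) {
        v <- slot(object, s)
        if (v < 0 || v > 1) msg <- c(msg, sprintf("'%s' must lie in [0, 1]", s))
    }
    tr <- object@tracts
    if (!all(c("minMb", "maxMb", "count") %in% colnames(tr)))
        msg <- c(msg, "'tracts' needs columns minMb, maxMb, count")
    else if (nrow(tr) && (any(tr$maxMb <= tr$minMb) || any(tr$count < 0)))
        msg <- c(msg, "'tracts' classes must have maxMb > minMb and count >= 0")
    if (length(msg)) msg else TRUE
})

#' Define a simulated population profile
#'
#' @param name Population label.
#' @param nIndividuals Number of individuals.
#' @param targetHet Target mean heterozygosity (per-SNP allele frequencies are
#'   drawn from a symmetric Beta calibrated so that E\[2p(1-p)\] equals this).
#' @param missingRate Per-call missing rate.
#' @param withinTractHetRate Erroneous-heterozygote rate inside planted tracts.
#' @param tracts Tract mix as produced by [tractMix()]; defaults to none.
#' @return A [PopulationProfile-class] object.
#' @export
populationProfile <- function(name, nIndividuals, targetHet,
                              missingRate = 0, withinTractHetRate = 0,
                              tracts = tractMix()) {
    new("PopulationProfile", name = as.character(name),
        nIndividuals = as.integer(nIndividuals), targetHet = targetHet,
        missingRate = missingRate, withinTractHetRate = withinTractHetRate,
        tracts = tracts)
}

#' ROH length classes
#'
#' The seven conventional length classes used throughout: 0.3-1, 1-2, 2-4,
#' 4-8, 8-10, 10-16 and >16 Mb. Bins are left-closed, right-open.
#'
#' @return `data.frame` with columns `label`, `minMb`, `maxMb` (last is `Inf`).
#' @export
rohLengthClasses <- function() {
    data.frame(
        label = c("0.3-1Mb", "1-2Mb", "2-4Mb", "4-8Mb", "8-10Mb", "10-16Mb",
                  ">16Mb"),
        minMb = c(0.3, 1, 2, 4, 8, 10, 16),
        maxMb = c(1, 2, 4, 8, 10, 16, Inf),
        stringsAsFactors = FALSE)
}

#' Expected planted-tract counts per length class
#'
#' @param counts Numeric vector of length 7: expected tracts per individual in
#'   each of the classes of [rohLengthClasses()]. Fractional values are
#'   realised stochastically (floor plus a Bernoulli on the remainder).
#' @param maxLongMb Upper sampling bound (Mb) for the open-ended `>16Mb`
#'   class; defaults to 20 Mb.
#' @return `data.frame` with columns `minMb`, `maxMb`, `count`.
#' @export
tractMix <- function(counts = rep(0, 7), maxLongMb = 20) {
    cls <- rohLengthClasses()
    stopifnot(length(counts) == nrow(cls))
    data.frame(minMb = cls$minMb,
               maxMb = ifelse(is.finite(cls$maxMb), cls$maxMb, maxLongMb),
               count = as.numeric(counts))
}

#' ROHSet: runs of homozygosity for a cohort
#'
#' @slot segments `GRanges` of ROH segments (1-based, inclusive; width is the
#'   segment length in bp) with metadata columns `individual`, `population`
#'   and `nSNPs`. Segments of one individual on one chromosome are disjoint
#'   and position-sorted.
#' @slot params The [scanParams()] list used for the scan.
#' @slot samples `DataFrame` with columns `individual` and `population`
#'   covering every scanned individual (including those without any ROH).
#' @aliases ROHSet-class
#' @exportClass ROHSet
setClass("ROHSet",
         representation(segments = "GRanges", params = "list",
                        samples = "DataFrame"))

setValidity("ROHSet", function(object) {
    msg <- character()
    mc <- mcols(object@segments)
    need <- c("individual", "population", "nSNPs")
    if (!all(need %in% colnames(mc)))
        msg <- c(msg, paste("segments need metadata columns:",
                            paste(need, collapse = ", ")))
    if (!all(c("individual", "population") %in% colnames(object@samples)))
        msg <- c(msg, "'samples' needs columns individual, population")
    else if (length(object@segments) &&
             !all(mc$individual %in% object@samples$individual))
        msg <- c(msg, "every segment's individual must appear in 'samples'")
    if (length(msg)) msg else TRUE
})

#' Construct an ROHSet
#'
#' @param segments `GRanges` with metadata columns `individual`, `population`,
#'   `nSNPs`.
#' @param params Scan parameter list ([scanParams()]).
#' @param samples `DataFrame`/`data.frame` with columns `individual`,
#'   `population` listing all scanned individuals.
#' @return An [ROHSet-class] object.
#' @export
ROHSet <- function(segments, params = scanParams(), samples) {
    samples <- as(samples, "DataFrame")
    samples$population <- factor(as.character(samples$population),
                                 levels = unique(as.character(samples$population)))
    new("ROHSet", segments = segments, params = params, samples = samples)
}

#' QCReport: per-filter variant counts
#'
#' @slot nInput Variants read in.
#' @slot nRemovedMonomorphic Removed for lacking a minor allele.
#' @slot nRemovedCallrate Removed for call rate below the floor.
#' @slot nRemovedHWE Removed for exact-test Hardy-Weinberg deviation.
#' @slot nRetained Variants surviving all filters.
#' @slot genotypingRate Overall non-missing call fraction of the retained
#'   matrix (NA when nothing is retained).
#' @aliases QCReport-class
#' @exportClass QCReport
setClass("QCReport",
         representation(nInput = "integer", nRemovedMonomorphic = "integer",
                        nRemovedCallrate = "integer", nRemovedHWE = "integer",
                        nRetained = "integer", genotypingRate = "numeric"))

setValidity("QCReport", function(object) {
    msg <- character()
    if (object@nInput != object@nRemovedMonomorphic + object@nRemovedCallrate +
            object@nRemovedHWE + object@nRetained)
        msg <- c(msg, "removal classes plus retained must sum to the input")
    gr <- object@genotypingRate
    if (!is.na(gr) && (gr < 0 || gr > 1))
        msg <- c(msg, "'genotypingRate' must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})
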