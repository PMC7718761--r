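# Accessor generics and show methods.

#' Genotype call matrix of a cohort
#'
#' @param x A [GenotypeCohort-class].
#' @return Integer matrix (variants x individuals) of 0/1/2/NA codes.
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname genotypeCalls
setMethod("genotypeCalls", "GenotypeCohort", function(x) assay(x, "GT"))

#' Variant positions of a cohort
#'
#' @param x A [GenotypeCohort-class].
#' @return Width-1 `GRanges`, one per variant.
#' @export
setGeneric("variantRanges", function(x) standardGeneric("variantRanges"))

#' @rdname variantRanges
setMethod("variantRanges", "GenotypeCohort", function(x) rowRanges(x))

#' Population assignment of a cohort's individuals
#'
#' @param x A [GenotypeCohort-class] or [ROHSet-class].
#' @return Factor of population labels, one per individual, named by
#'   individual id.
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname populations
setMethod("populations", "GenotypeCohort", function(x)
    setNames(colData(x)$population, colnames(x)))

#' @rdname populations
setMethod("populations", "ROHSet", function(x)
    setNames(x@samples$population, x@samples$individual))

#' ROH segments of an ROHSet
#'
#' @param x An [ROHSet-class].
#' @return `GRanges` of segments with `individual`, `population`, `nSNPs`.
#' @export
setGeneric("rohSegments", function(x) standardGeneric("rohSegments"))

#' @rdname rohSegments
setMethod("rohSegments", "ROHSet", function(x) x@segments)

#' Scan parameters recorded in an ROHSet
#'
#' @param x An [ROHSet-class].
#' @return The [scanParams()] list used to produce the segments.
#' @export
setGeneric("rohParams", function(x) standardGeneric("rohParams"))

#' @rdname rohParams
setMethod("rohParams", "ROHSet", function(x) x@params)

#' Sample table of an ROHSet
#'
#' @param x An [ROHSet-class].
#' @return `DataFrame` with columns `individual`, `population`.
#' @export
setGeneric("rohSamples", function(x) standardGeneric("rohSamples"))

#' @rdname rohSamples
setMethod("rohSamples", "ROHSet", function(x) x@samples)

setMethod("show", "GenotypeCohort", function(object) {
    pops <- table(colData(object)$population)
    cat(sprintf("GenotypeCohort: %d variants x %d individuals\n",
                nrow(object), ncol(object)))
    cat("populations:",
        paste(sprintf("%s (n=%d)", names(pops), as.integer(pops)),
              collapse = ", "), "\n")
    cat("chromosomes:",
        paste(seqlevels(rowRanges(object)), collapse = ", "), "\n")
    gt <- assay(object, "GT")
    cat(sprintf("genotyping rate: %.4f\n", mean(!is.na(gt))))
})

setMethod("show", "ROHSet", function(object) {
    segs <- object@segments
    cat(sprintf("ROHSet: %d segments across %d individuals\n",
                length(segs), nrow(object@samples)))
    if (length(segs)) {
        bypop <- tapply(width(segs), mcols(segs)$population, length)
        bypop[is.na(bypop)] <- 0
        cat("segments per population:",
            paste(sprintf("%s=%d", names(bypop), as.integer(bypop)),
                  collapse = ", "), "\n")
        cat(sprintf("length range: %.2f-%.2f Mb\n",
                    min(width(segs)) / 1e6, max(width(segs)) / 1e6))
    }
})

setMethod("show", "QCReport", function(object) {
    cat("Variant QC report\n")
    cat(sprintf("  input:              %d\n", object@nInput))
    cat(sprintf("  removed monomorphic:%d\n", object@nRemovedMonomorphic))
    cat(sprintf("  removed call rate:  %d\n", object@nRemovedCallrate))
    cat(sprintf("  removed HWE:        %d\n", object@nRemovedHWE))
    cat(sprintf("  retained:           %d\n", object@nRetained))
    cat(sprintf("  genotyping rate:    %s\n",
                ifelse(is.na(object@genotypingRate), "NA",
                       sprintf("%.4f", object@genotypingRate))))
})

setMethod("show", "GenomeLayout", function(object) {
    cat(sprintf("GenomeLayout: %d chromosomes, %.0f Mb total, 1 SNP per %.0f bp\n",
                nrow(object@chromosomes), sum(object@chromosomes$length) / 1e6,
                1 / object@snpDensity))
})

setMethod("show", "PopulationProfile", function(object) {
    cat(sprintf(
        "PopulationProfile '%s': n=%d, target Ho=%.3f, missing=%.3f, tract het=%.3f, %.1f tracts/individual\n",
        object@name, object@nIndividuals, object@targetHet,
        object@missingRate, object@withinTractHetRate,
        sum(object@tracts$count)))
})
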