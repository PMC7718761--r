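# Genotype input: VCF plus a sample-to-population map.

.GT_LUT <- c("0/0" = 0L, "0|0" = 0L,
             "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
             "1/1" = 2L, "1|1" = 2L)

#' Read diploid biallelic SNP genotypes from a VCF
#'
#' Parses a VCF v4.2 file (via `VariantAnnotation`) into a
#' [GenotypeCohort-class]. Only biallelic SNP records are kept; multiallelic,
#' indel and symbolic-allele records are skipped and counted. Genotypes other
#' than `0/0`, `0/1`, `1/1` (phased or unphased) -- including half-missing
#' calls such as `./1` -- are treated as missing.
#'
#' @param vcfPath Path to a VCF file.
#' @param populationMap Either a two-column `data.frame` (columns `sample`,
#'   `population`) or the path to a headerless two-column TSV. Every sample in
#'   the VCF must be present.
#' @return A [GenotypeCohort-class]. `metadata()$nSkippedRecords` counts the
#'   non-SNP/multiallelic records that were dropped.
#' @export
readGenotypes <- function(vcfPath, populationMap) {
    pm <- if (is.character(populationMap)) {
        read.table(populationMap, header = FALSE, sep = "\t",
                   col.names = c("sample", "population"),
                   stringsAsFactors = FALSE)
    } else {
        as.data.frame(populationMap, stringsAsFactors = FALSE)
    }
    if (!all(c("sample", "population") %in% colnames(pm)))
        stop("population map needs columns 'sample' and 'population'")

    vcf <- readVcf(vcfPath, genome = "cohort")
    gtc <- geno(vcf)$GT
    if (is.null(gtc)) stop("VCF has no GT field")

    missing <- setdiff(colnames(gtc), pm$sample)
    if (length(missing))
        stop("sample(s) absent from population map: ",
             paste(missing, collapse = ", "))

    refs <- ref(vcf)
    alts <- alt(vcf)
    biallelic <- elementNROWS(alts) == 1L
    altChar <- rep(NA_character_, length(alts))
    altChar[biallelic] <- vapply(which(biallelic),
                                 function(i) as.character(alts[[i]][1L]),
                                 character(1))
    isSnp <- biallelic & width(refs) == 1L &
        !is.na(altChar) & altChar %in% c("A", "C", "G", "T")
    nSkipped <- sum(!isSnp)
    if (nSkipped)
        message(nSkipped, " multiallelic or non-SNP record(s) skipped")

    gtc <- gtc[isSnp, , drop = FALSE]
    calls <- .GT_LUT[gtc]
    dim(calls) <- dim(gtc)
    dimnames(calls) <- dimnames(gtc)

    rr <- rowRanges(vcf)[isSnp]
    variants <- GRanges(seqnames(rr), IRanges(start(rr), width = 1L),
                        ref = as.character(refs)[isSnp],
                        alt = altChar[isSnp],
                        seqinfo = seqinfo(rr))
    pops <- pm$population[match(colnames(calls), pm$sample)]
    cohort <- GenotypeCohort(calls, variants, pops)
    metadata(cohort)$nSkippedRecords <- nSkipped
    cohort
}

#' Read a two-column chromosome-length table
#'
#' @param path Headerless TSV: chromosome label, length in bp.
#' @return Named numeric vector of chromosome lengths.
#' @export
readChromosomeTable <- function(path) {
    tab <- read.table(path, header = FALSE, sep = "\t",
                      col.names = c("chrom", "length"),
                      stringsAsFactors = FALSE)
    setNames(as.numeric(tab$length), tab$chrom)
}
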