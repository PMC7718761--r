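# Cohort simulator: multi-population diploid genotypes with known allele
# frequencies and planted autozygous tracts. The planted tracts are the ground
# truth against which the ROH caller is validated.

#' Desk-scale five-population cohort profiles
#'
#' Five populations patterned on a layer/broiler/wild contrast: two layer-type
#' lines of 25 birds with heavy short-tract autozygosity, two broiler-type
#' lines of 20, and one wild-type population of 25 with few tracts. Target
#' heterozygosities span 0.24-0.31 and per-class tract burdens are scaled to
#' the default 75 Mb desk genome so that realised FROH spans roughly 0.1-0.5
#' across populations.
#'
#' @param missingRate Per-call missing rate (default 0.02, i.e. a ~0.98
#'   genotyping rate).
#' @param withinTractHetRate Erroneous heterozygote rate inside planted tracts
#'   (default 0.01); sporadic within-tract heterozygotes are what breaks long
#'   autozygous stretches into several called segments at sequence resolution.
#' @return List of five [PopulationProfile-class] objects.
#' @export
deskCohortProfiles <- function(missingRate = 0.02, withinTractHetRate = 0.01) {
    list(
        populationProfile("WL", 25, 0.278, missingRate, withinTractHetRate,
            tractMix(c(30.5, 8.4, 2.2, 0.14, 0, 0, 0))),
        populationProfile("BL", 25, 0.282, missingRate, withinTractHetRate,
            tractMix(c(14.9, 6.0, 3.2, 1.1, 0.07, 0.05, 0.003))),
        populationProfile("BRA", 20, 0.296, missingRate, withinTractHetRate,
            tractMix(c(9.5, 2.4, 1.3, 0.32, 0.02, 0.02, 0))),
        populationProfile("BRB", 20, 0.309, missingRate, withinTractHetRate,
            tractMix(c(11.4, 2.9, 1.4, 0.31, 0.02, 0, 0))),
        populationProfile("RJF", 25, 0.240, missingRate, withinTractHetRate,
            tractMix(c(3.5, 1.6, 1.1, 0.49, 0.06, 0.04, 0.003))))
}

# Symmetric Beta(a, a) has E[2p(1-p)] = a/(2a+1); invert for a target mean
# heterozygosity h < 0.5.
.betaShapeForHet <- function(h) h / (1 - 2 * h)

#' Simulate a multi-population cohort with planted autozygous tracts
#'
#' Variant positions are drawn once per chromosome (shared by all
#' populations). Each population receives its own per-SNP alternate-allele
#' frequency p from a symmetric Beta distribution calibrated so that the mean
#' heterozygosity 2p(1-p) equals the profile's `targetHet`; genotypes are then
#' drawn under Hardy-Weinberg proportions. Planted tracts overwrite the calls
#' of one individual with a homozygous founder haplotype (allele drawn from p
#' per SNP), after which erroneous heterozygotes are injected at
#' `withinTractHetRate` and missing calls at `missingRate` (the missing mask
#' applies genome wide).
#'
#' @param layout A [genomeLayout()].
#' @param profiles List of [populationProfile()] objects.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param extraTracts Optional `data.frame` with columns `individual`,
#'   `chrom`, `start`, `end` (1-based, inclusive) of additional tracts to
#'   plant in named individuals (ids are `<population>_<i>`), e.g. a shared
#'   region for island-recovery experiments.
#' @return List with elements `cohort` (a [GenotypeCohort-class]; its
#'   `metadata()` records the seed and the per-population allele-frequency
#'   matrix) and `truth` (`GRanges` of planted tracts with metadata columns
#'   `individual`, `population`; overlapping tracts of one individual are
#'   merged with a warning).
#' @examples
#' sim <- simulateCohort(
#'     genomeLayout(data.frame(chrom = "chr1", length = 5e6)),
#'     list(populationProfile("A", 5, 0.25)), seed = 1)
#' sim$cohort
#' @export
simulateCohort <- function(layout, profiles, seed, extraTracts = NULL) {
    stopifnot(is(layout, "GenomeLayout"), length(profiles) >= 1L)
    for (pr in profiles) stopifnot(is(pr, "PopulationProfile"))
    if (exists(".Random.seed", envir = globalenv())) {
        oldseed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", oldseed, envir = globalenv()))
    }
    set.seed(as.integer(seed))

    chroms <- layout@chromosomes
    posList <- lapply(seq_len(nrow(chroms)), function(i) {
        n <- max(1L, round(chroms$length[i] * layout@snpDensity))
        sort(sample.int(chroms$length[i], n))
    })
    chromVec <- rep(chroms$chrom, lengths(posList))
    pos <- unlist(posList)
    nVar <- length(pos)
    refIdx <- sample.int(4L, nVar, replace = TRUE)
    altIdx <- (refIdx - 1L + sample.int(3L, nVar, replace = TRUE)) %% 4L + 1L
    bases <- c("A", "C", "G", "T")
    variants <- GRanges(chromVec, IRanges(pos, width = 1L),
                        ref = bases[refIdx], alt = bases[altIdx],
                        seqinfo = Seqinfo(chroms$chrom, chroms$length))

    popNames <- vapply(profiles, function(p) p@name, character(1))
    freqs <- matrix(NA_real_, nVar, length(profiles),
                    dimnames = list(NULL, popNames))
    callCols <- list()
    popVec <- character(0)
    truth <- list()
    mergedAny <- FALSE

    for (k in seq_along(profiles)) {
        pr <- profiles[[k]]
        nInd <- pr@nIndividuals
        ids <- paste0(pr@name, "_", seq_len(nInd))
        p <- if (pr@targetHet == 0) {
            sample(c(0, 1), nVar, replace = TRUE)
        } else {
            a <- .betaShapeForHet(pr@targetHet)
            rbeta(nVar, a, a)
        }
        freqs[, k] <- p
        g <- matrix(rbinom(nVar * nInd, 2L, rep(p, nInd)), nVar, nInd,
                    dimnames = list(NULL, ids))

        for (j in seq_len(nInd)) {
            tr <- .drawTracts(pr@tracts, chroms)
            if (!is.null(extraTracts)) {
                ex <- extraTracts[extraTracts$individual == ids[j], ,
                                  drop = FALSE]
                if (nrow(ex)) {
                    bad <- !(ex$chrom %in% chroms$chrom) |
                        ex$end > chroms$length[match(ex$chrom, chroms$chrom)] |
                        ex$start < 1
                    if (any(bad))
                        stop("extra tract outside its chromosome for ", ids[j])
                    tr <- rbind(tr, ex[, c("chrom", "start", "end")])
                }
            }
            if (!nrow(tr)) next
            gr <- GRanges(tr$chrom, IRanges(tr$start, tr$end))
            red <- GenomicRanges::reduce(BiocGenerics::sort(gr))
            if (length(red) < length(gr)) mergedAny <- TRUE
            for (t in seq_along(red)) {
                idx <- which(chromVec == as.character(seqnames(red)[t]) &
                             pos >= start(red)[t] & pos <= end(red)[t])
                if (length(idx)) {
                    founder <- rbinom(length(idx), 1L, p[idx])
                    calls <- 2L * founder
                    if (pr@withinTractHetRate > 0) {
                        err <- runif(length(idx)) < pr@withinTractHetRate
                        calls[err] <- 1L
                    }
                    g[idx, j] <- calls
                }
            }
            truth[[length(truth) + 1L]] <- GRanges(
                seqnames(red), IRanges(start(red), end(red)),
                individual = ids[j], population = pr@name,
                seqinfo = Seqinfo(chroms$chrom, chroms$length))
        }
        if (pr@missingRate > 0)
            g[matrix(runif(nVar * nInd) < pr@missingRate, nVar, nInd)] <- NA
        callCols[[k]] <- g
        popVec <- c(popVec, rep(pr@name, nInd))
    }
    if (mergedAny)
        warning("overlapping planted tracts were merged within individuals")

    calls <- do.call(cbind, callCols)
    cohort <- GenotypeCohort(calls, variants, popVec)
    metadata(cohort)$seed <- as.integer(seed)
    metadata(cohort)$alleleFreqs <- freqs
    truth <- if (length(truth)) {
        do.call(c, truth)
    } else {
        GRanges(seqinfo = Seqinfo(chroms$chrom, chroms$length),
                individual = character(0), population = character(0))
    }
    list(cohort = cohort, truth = truth)
}

# Draw planted tracts for one individual: realised count per class is
# floor(expected) plus a Bernoulli on the fraction; length uniform within the
# class; placement uniform over chromosomes that can hold the tract, weighted
# by the number of admissible start positions.
.drawTracts <- function(tracts, chroms) {
    out <- list()
    for (r in seq_len(nrow(tracts))) {
        mu <- tracts$count[r]
        k <- floor(mu) + (runif(1) < mu - floor(mu))
        if (k < 1) next
        lens <- round(runif(k, tracts$minMb[r], tracts$maxMb[r]) * 1e6)
        for (len in lens) {
            room <- chroms$length - len + 1
            if (all(room <= 0))
                stop(sprintf("tract of %.2f Mb is longer than every chromosome",
                             len / 1e6))
            w <- pmax(room, 0)
            ci <- sample.int(nrow(chroms), 1L, prob = w)
            s <- floor(runif(1, 1, room[ci] + 1))
            out[[length(out) + 1L]] <- data.frame(
                chrom = chroms$chrom[ci], start = s, end = s + len - 1)
        }
    }
    if (length(out)) do.call(rbind, out)
    else data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
}

#' Write a cohort as VCF v4.2
#'
#' Emits one biallelic SNP record per variant with a GT-only FORMAT column and
#' `##contig` header lines carrying chromosome lengths. Missing calls are
#' written as `./.`. The output is plain text and byte-stable for a given
#' cohort, so identical simulation seeds give identical files.
#'
#' @param cohort A [GenotypeCohort-class].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
writeCohortVCF <- function(cohort, path) {
    rr <- rowRanges(cohort)
    gt <- assay(cohort, "GT")
    mc <- mcols(rr)
    refA <- if ("ref" %in% colnames(mc)) as.character(mc$ref) else rep("A", length(rr))
    altA <- if ("alt" %in% colnames(mc)) as.character(mc$alt) else rep("G", length(rr))
    sl <- seqlengths(rr)
    contigs <- if (all(is.na(sl))) character(0) else
        sprintf("##contig=<ID=%s,length=%d>", names(sl), as.integer(sl))
    header <- c("##fileformat=VCFv4.2",
                "##source=rohscan",
                contigs,
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", colnames(gt)), collapse = "\t"))
    codes <- c("0/0", "0/1", "1/1")
    gtx <- matrix("./.", nrow(gt), ncol(gt))
    ok <- !is.na(gt)
    gtx[ok] <- codes[gt[ok] + 1L]
    body <- do.call(paste, c(list(as.character(seqnames(rr)), start(rr), ".",
                                  refA, altA, ".", ".", ".", "GT"),
                             as.data.frame(gtx, stringsAsFactors = FALSE),
                             sep = "\t"))
    writeLines(c(header, body), path)
    invisible(path)
}

#' Write a two-column chromosome-length table
#'
#' @param x A [GenomeLayout-class] or a `GenotypeCohort` whose variant ranges
#'   carry seqlengths.
#' @param path Output TSV path (no header: chromosome, length in bp).
#' @return Invisibly, the path.
#' @export
writeChromosomeTable <- function(x, path) {
    tab <- if (is(x, "GenomeLayout")) {
        x@chromosomes
    } else {
        sl <- seqlengths(rowRanges(x))
        data.frame(chrom = names(sl), length = as.numeric(sl))
    }
    write.table(tab, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write planted truth tracts as BED
#'
#' Coordinates convert from the internal 1-based inclusive convention to BED's
#' 0-based half-open intervals; the name column is the individual id.
#'
#' @param truth `GRanges` with an `individual` metadata column, as returned by
#'   [simulateCohort()].
#' @param path Output BED path.
#' @return Invisibly, the path.
#' @export
writeTractsBED <- function(truth, path) {
    df <- data.frame(chrom = as.character(seqnames(truth)),
                     start = start(truth) - 1L, end = end(truth),
                     name = mcols(truth)$individual)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}
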