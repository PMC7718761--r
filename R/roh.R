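# Sliding-window ROH caller. A window of `windowSnps` consecutive SNPs is
# "homozygous" when it contains at most `windowMaxHet` heterozygous and
# `windowMaxMissing` missing calls. Each SNP's hit rate is the fraction of
# windows containing it that are homozygous; SNPs with a hit rate at or above
# `hitProportion` whose own call is not heterozygous are flagged, and maximal
# runs of flagged SNPs (split at physical gaps larger than `maxGapKb`) become
# segments if they satisfy the SNP-count, length and density floors.

#' Parameters of the sliding-window ROH scan
#'
#' Defaults are the conventional seven-criterion sequence-data
#' parameterisation: 50-SNP windows tolerating up to 3 heterozygous and 5
#' missing calls, a 0.05 hit-rate floor, at least 50 SNPs and 300 kb per
#' segment, a 1000 kb maximum gap between consecutive segment SNPs, and an
#' average density of at least 1 SNP per 50 kb.
#'
#' @param windowSnps Window size in SNPs.
#' @param windowMaxHet Maximum heterozygous calls per homozygous window.
#' @param windowMaxMissing Maximum missing calls per homozygous window.
#' @param hitProportion Minimum fraction of homozygous windows covering a SNP
#'   for it to be flagged (inclusive threshold).
#' @param minSnps Minimum SNPs per reported segment.
#' @param minLengthKb Minimum segment length (kb).
#' @param maxGapKb Maximum physical gap (kb) between consecutive segment SNPs.
#' @param minDensityKbPerSnp Maximum average spacing (kb per SNP) of a
#'   segment, i.e. 50 means at least 1 SNP per 50 kb.
#' @param segmentMaxHet,segmentMaxMissing Optional caps on the total
#'   heterozygous/missing calls within a final segment. `NULL` (default)
#'   applies the het/missing allowances per window only.
#' @return Named parameter list.
#' @export
scanParams <- function(windowSnps = 50L, windowMaxHet = 3L,
                       windowMaxMissing = 5L, hitProportion = 0.05,
                       minSnps = 50L, minLengthKb = 300, maxGapKb = 1000,
                       minDensityKbPerSnp = 50,
                       segmentMaxHet = NULL, segmentMaxMissing = NULL) {
    p <- list(windowSnps = as.integer(windowSnps),
              windowMaxHet = as.integer(windowMaxHet),
              windowMaxMissing = as.integer(windowMaxMissing),
              hitProportion = hitProportion,
              minSnps = as.integer(minSnps),
              minLengthKb = minLengthKb,
              maxGapKb = maxGapKb,
              minDensityKbPerSnp = minDensityKbPerSnp,
              segmentMaxHet = segmentMaxHet,
              segmentMaxMissing = segmentMaxMissing)
    stopifnot(p$windowSnps >= 1L, p$windowMaxHet >= 0L,
              p$windowMaxMissing >= 0L,
              p$hitProportion > 0, p$hitProportion <= 1,
              p$minSnps >= 1L, p$minLengthKb > 0, p$maxGapKb > 0,
              p$minDensityKbPerSnp > 0)
    p
}

#' Per-SNP homozygous-window hit rates
#'
#' For SNP i of a chromosome-ordered call vector, the fraction of the
#' sliding windows containing it that are homozygous. Edge SNPs are covered
#' by fewer windows and use only those that exist; a chromosome shorter than
#' one window is evaluated as a single whole-chromosome window.
#'
#' @param calls Integer vector of genotype codes (0/1/2/NA) for one
#'   individual on one chromosome, in position order.
#' @param params A [scanParams()] list.
#' @return Numeric vector of hit rates in \[0, 1\], one per SNP.
#' @export
windowHitRates <- function(calls, params = scanParams()) {
    n <- length(calls)
    if (n == 0L) stop("empty call vector")
    het <- !is.na(calls) & calls == 1L
    mis <- is.na(calls)
    w <- params$windowSnps
    if (n < w) {
        hom <- sum(het) <= params$windowMaxHet &&
            sum(mis) <= params$windowMaxMissing
        return(rep(as.numeric(hom), n))
    }
    nw <- n - w + 1L
    ch <- c(0L, cumsum(het))
    cm <- c(0L, cumsum(mis))
    hetW <- ch[(w + 1L):(n + 1L)] - ch[1:nw]
    misW <- cm[(w + 1L):(n + 1L)] - cm[1:nw]
    homWin <- hetW <= params$windowMaxHet & misW <= params$windowMaxMissing
    cw <- c(0L, cumsum(homWin))
    i <- seq_len(n)
    lo <- pmax(1L, i - w + 1L)
    hi <- pmin(nw, i)
    (cw[hi + 1L] - cw[lo]) / (hi - lo + 1L)
}

#' Call runs of homozygosity on one chromosome of one individual
#'
#' A SNP is flagged when its window hit rate reaches `hitProportion` and its
#' own call is not heterozygous (missing calls can be flagged: absence of a
#' call is not evidence against homozygosity). Maximal runs of flagged SNPs
#' are split wherever consecutive flagged SNPs lie more than `maxGapKb` apart
#' and each resulting run is reported if it has at least `minSnps` SNPs,
#' spans at least `minLengthKb`, and averages at least one SNP per
#' `minDensityKbPerSnp`. Segment coordinates are the positions of the first
#' and last flagged SNP; length is `end - start + 1` bp.
#'
#' @param calls Integer genotype codes (0/1/2/NA), position-ordered.
#' @param positions Strictly increasing bp positions, same length as `calls`.
#' @param params A [scanParams()] list.
#' @return `data.frame` with columns `start`, `end`, `nSNPs`, `length`.
#' @export
callROH <- function(calls, positions, params = scanParams()) {
    if (length(calls) != length(positions))
        stop("'calls' and 'positions' must have the same length")
    if (length(positions) > 1L && any(diff(positions) <= 0))
        stop("'positions' must be strictly increasing")
    rates <- windowHitRates(calls, params)
    het <- !is.na(calls) & calls == 1L
    flag <- rates >= params$hitProportion & !het

    empty <- data.frame(start = numeric(0), end = numeric(0),
                        nSNPs = integer(0), length = numeric(0))
    if (!any(flag)) return(empty)

    r <- rle(flag)
    runEnd <- cumsum(r$lengths)
    runStart <- runEnd - r$lengths + 1L
    out <- vector("list", sum(r$values))
    oi <- 0L
    for (k in which(r$values)) {
        i0 <- runStart[k]; i1 <- runEnd[k]
        idx <- i0:i1
        gaps <- which(diff(positions[idx]) > params$maxGapKb * 1000)
        pieceStart <- c(i0, i0 + gaps)
        pieceEnd <- c(i0 + gaps - 1L, i1)
        for (q in seq_along(pieceStart)) {
            a <- pieceStart[q]; b <- pieceEnd[q]
            ns <- b - a + 1L
            len <- positions[b] - positions[a] + 1
            if (ns < params$minSnps || len < params$minLengthKb * 1000 ||
                len / ns > params$minDensityKbPerSnp * 1000)
                next
            if (!is.null(params$segmentMaxHet) &&
                sum(het[a:b]) > params$segmentMaxHet)
                next
            if (!is.null(params$segmentMaxMissing) &&
                sum(is.na(calls[a:b])) > params$segmentMaxMissing)
                next
            oi <- oi + 1L
            out[[oi]] <- c(positions[a], positions[b], ns, len)
        }
    }
    if (oi == 0L) return(empty)
    m <- do.call(rbind, out[seq_len(oi)])
    data.frame(start = m[, 1], end = m[, 2], nSNPs = as.integer(m[, 3]),
               length = m[, 4])
}

#' Scan a whole cohort for runs of homozygosity
#'
#' Applies [callROH()] to every individual on every chromosome and collects
#' the segments into an [ROHSet-class]. Deterministic; per-population segment
#' totals are reported as messages.
#'
#' @param cohort A (QC-filtered) [GenotypeCohort-class].
#' @param params A [scanParams()] list.
#' @return An [ROHSet-class].
#' @export
scanCohort <- function(cohort, params = scanParams()) {
    stopifnot(is(cohort, "GenotypeCohort"))
    gt <- assay(cohort, "GT")
    rr <- rowRanges(cohort)
    chr <- as.character(seqnames(rr))
    pos <- start(rr)
    pops <- colData(cohort)$population
    byChrom <- split(seq_along(chr), factor(chr, levels = unique(chr)))

    segs <- list()
    for (j in seq_len(ncol(gt))) {
        for (cname in names(byChrom)) {
            idx <- byChrom[[cname]]
            d <- callROH(gt[idx, j], pos[idx], params)
            if (nrow(d)) {
                d$chrom <- cname
                d$individual <- colnames(gt)[j]
                d$population <- as.character(pops[j])
                segs[[length(segs) + 1L]] <- d
            }
        }
    }
    si <- seqinfo(rr)
    gr <- if (length(segs)) {
        d <- do.call(rbind, segs)
        GRanges(d$chrom, IRanges(d$start, d$end), nSNPs = d$nSNPs,
                individual = d$individual, population = d$population,
                seqinfo = si)
    } else {
        GRanges(nSNPs = integer(0), individual = character(0),
                population = character(0), seqinfo = si)
    }
    samples <- DataFrame(individual = colnames(gt), population = pops)
    res <- ROHSet(gr, params, samples)
    tot <- tapply(rep(1L, length(gr)), mcols(gr)$population, sum)
    for (pop in levels(pops))
        message(sprintf("population %s: %d ROH segments", pop,
                        ifelse(pop %in% names(tot) && !is.na(tot[pop]),
                               as.integer(tot[pop]), 0L)))
    res
}

#' Export ROH segments as a per-individual table
#'
#' @param rohset An [ROHSet-class].
#' @return `data.frame` with columns `individual`, `population`, `chrom`,
#'   `start`, `end`, `n_snps`, `length_kb`.
#' @export
rohSegmentTable <- function(rohset) {
    segs <- rohSegments(rohset)
    data.frame(individual = mcols(segs)$individual,
               population = mcols(segs)$population,
               chrom = as.character(seqnames(segs)),
               start = start(segs), end = end(segs),
               n_snps = mcols(segs)$nSNPs,
               length_kb = width(segs) / 1000,
               stringsAsFactors = FALSE)
}

#' Export ROH segments as BED
#'
#' 0-based half-open coordinates; the name column is the individual id.
#'
#' @param rohset An [ROHSet-class].
#' @param path Output BED path.
#' @return Invisibly, the path.
#' @export
writeROHBed <- function(rohset, path) {
    segs <- rohSegments(rohset)
    df <- data.frame(chrom = as.character(seqnames(segs)),
                     start = start(segs) - 1L, end = end(segs),
                     name = mcols(segs)$individual)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}
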