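# ROH islands: per-SNP ROH incidence, population-specific top-quantile
# thresholds, island calling, and interval intersection against annotations
# or other populations' islands.

#' Per-SNP ROH incidence within a population
#'
#' For each SNP, the fraction of the population's individuals that have at
#' least one ROH segment covering its position.
#'
#' @param rohset An [ROHSet-class].
#' @param variants Width-1 `GRanges` of SNP positions, or a
#'   [GenotypeCohort-class] (its variant ranges are used).
#' @param population Population label.
#' @return `GRanges` copy of the variant positions with an `incidence`
#'   metadata column; `metadata()$population` records the population.
#' @export
snpIncidence <- function(rohset, variants, population) {
    if (is(variants, "GenotypeCohort")) variants <- rowRanges(variants)
    samples <- rohSamples(rohset)
    nInd <- sum(samples$population == population)
    if (nInd < 1L) stop("population has no individuals: ", population)
    segs <- rohSegments(rohset)
    segs <- segs[mcols(segs)$population == population]
    hits <- findOverlaps(variants, segs, ignore.strand = TRUE)
    qh <- queryHits(hits)
    ind <- match(mcols(segs)$individual[subjectHits(hits)],
                 samples$individual)
    # count distinct covering individuals per SNP (scan output segments are
    # disjoint per individual, but tolerate overlapping input)
    keep <- !duplicated(qh * (nrow(samples) + 1) + ind)
    counts <- tabulate(qh[keep], nbins = length(variants))
    out <- GRanges(seqnames(variants), IRanges(start(variants), width = 1L),
                   incidence = counts / nInd, seqinfo = seqinfo(variants))
    metadata(out)$population <- population
    metadata(out)$nIndividuals <- nInd
    out
}

#' Population-specific island-calling threshold
#'
#' The incidence of the k-th most-ROH-covered SNP, where
#' k = `ceiling(topFraction * n)`: the nearest-rank upper quantile of the
#' incidence distribution, so SNPs at or above the threshold are the top
#' `topFraction` of the track. Incidence takes at most N+1 discrete values
#' for N individuals, so no interpolation is used. Because the threshold is a
#' quantile of each population's own track, it is population-specific by
#' construction.
#'
#' @param track Incidence `GRanges` from [snpIncidence()], or a numeric
#'   vector of incidences.
#' @param topFraction Upper tail fraction in (0, 1); default 0.01 (top 1%).
#' @return The incidence threshold (with a warning when the track is
#'   degenerate, i.e. all values equal).
#' @export
islandThreshold <- function(track, topFraction = 0.01) {
    inc <- if (is(track, "GRanges")) mcols(track)$incidence else track
    n <- length(inc)
    if (n == 0L) stop("empty incidence track")
    stopifnot(topFraction > 0, topFraction < 1)
    if (length(unique(inc)) == 1L)
        warning("degenerate incidence track: all values equal ", inc[1])
    k <- ceiling(topFraction * n)
    sort(inc, decreasing = TRUE)[k]
}

#' Call ROH islands from an incidence track
#'
#' Islands are maximal runs of consecutive SNPs whose incidence is at or
#' above `threshold`, broken where adjacent qualifying SNPs lie more than
#' `maxGapKb` apart; runs of fewer than `minSnps` SNPs (default 2) are
#' discarded. Island coordinates are the first and last member SNP.
#'
#' @param track Incidence `GRanges` from [snpIncidence()].
#' @param threshold Incidence threshold in \[0, 1\] (see [islandThreshold()]).
#' @param maxGapKb Maximum gap between consecutive island SNPs (kb).
#' @param minSnps Minimum SNPs per island.
#' @return `GRanges` of islands with metadata columns `nSNPs` and
#'   `meanIncidence` (plus `population` when the track records one).
#' @export
callIslands <- function(track, threshold, maxGapKb = 1000, minSnps = 2L) {
    stopifnot(is(track, "GRanges"), threshold >= 0)
    inc <- mcols(track)$incidence
    chr <- as.character(seqnames(track))
    pos <- start(track)
    pop <- metadata(track)$population
    out <- list()
    for (cname in unique(chr)) {
        sel <- which(chr == cname)
        q <- inc[sel] >= threshold
        if (!any(q)) next
        r <- rle(q)
        rEnd <- cumsum(r$lengths)
        rStart <- rEnd - r$lengths + 1L
        for (k in which(r$values)) {
            idx <- sel[rStart[k]:rEnd[k]]
            gaps <- which(diff(pos[idx]) > maxGapKb * 1000)
            pieceStart <- c(1L, gaps + 1L)
            pieceEnd <- c(gaps, length(idx))
            for (qq in seq_along(pieceStart)) {
                member <- idx[pieceStart[qq]:pieceEnd[qq]]
                if (length(member) < minSnps) next
                out[[length(out) + 1L]] <- data.frame(
                    chrom = cname, start = pos[member[1L]],
                    end = pos[member[length(member)]],
                    nSNPs = length(member),
                    meanIncidence = mean(inc[member]))
            }
        }
    }
    if (!length(out))
        return(GRanges(nSNPs = integer(0), meanIncidence = numeric(0),
                       seqinfo = seqinfo(track)))
    d <- do.call(rbind, out)
    gr <- GRanges(d$chrom, IRanges(d$start, d$end), nSNPs = d$nSNPs,
                  meanIncidence = d$meanIncidence, seqinfo = seqinfo(track))
    if (!is.null(pop)) mcols(gr)$population <- pop
    gr
}

# Normalise interval input (GRanges or BED-like data.frame with 0-based
# half-open coordinates) to a GRanges plus display labels.
.asIntervalGR <- function(x, what = "intervals") {
    if (is(x, "GRanges")) {
        lab <- if (!is.null(mcols(x)$label)) as.character(mcols(x)$label)
               else if (!is.null(mcols(x)$name)) as.character(mcols(x)$name)
               else if (!is.null(names(x))) names(x)
               else sprintf("%s:%d-%d", as.character(seqnames(x)),
                            start(x) - 1L, end(x))
        return(list(gr = x, label = lab))
    }
    x <- as.data.frame(x)
    need <- c("chrom", "start", "end")
    if (!all(need %in% colnames(x)))
        stop(what, " need columns chrom, start, end (0-based half-open)")
    if (any(x$end <= x$start))
        stop("malformed interval: 'end' must exceed 'start' (half-open)")
    lab <- if ("label" %in% colnames(x)) as.character(x$label)
           else if ("name" %in% colnames(x)) as.character(x$name)
           else sprintf("%s:%d-%d", x$chrom, x$start, x$end)
    list(gr = GRanges(x$chrom, IRanges(x$start + 1L, x$end)), label = lab)
}

#' Intersect two interval sets
#'
#' Reports every pair of intervals from `a` and `b` that overlap by at least
#' 1 bp, with the overlap size. Inputs may be `GRanges` (1-based inclusive,
#' used as-is) or BED-like `data.frame`s with columns `chrom`, `start`, `end`
#' in 0-based half-open convention (so `[10,20)` and `[20,30)` do not
#' overlap). Typical uses: islands vs QTL annotations, or islands of one
#' population group vs another.
#'
#' @param a,b Interval sets.
#' @return `data.frame` with columns `aIndex`, `bIndex`, `aLabel`, `bLabel`,
#'   `chrom`, `overlapBp`.
#' @export
intersectIntervals <- function(a, b) {
    A <- .asIntervalGR(a, "intervals 'a'")
    B <- .asIntervalGR(b, "intervals 'b'")
    hits <- findOverlaps(A$gr, B$gr, ignore.strand = TRUE)
    qi <- queryHits(hits)
    si <- subjectHits(hits)
    ov <- width(pintersect(A$gr[qi], B$gr[si], ignore.strand = TRUE))
    data.frame(aIndex = qi, bIndex = si,
               aLabel = A$label[qi], bLabel = B$label[si],
               chrom = as.character(seqnames(A$gr))[qi],
               overlapBp = ov, stringsAsFactors = FALSE)
}

#' Read annotation intervals (BED or TSV)
#'
#' `.bed` files are parsed with `rtracklayer`; anything else is read as a
#' headerless TSV whose first four columns are chrom, start, end (0-based
#' half-open) and label.
#'
#' @param path File path.
#' @return `GRanges` with a `label` metadata column.
#' @export
readIntervals <- function(path) {
    if (grepl("\\.bed$", path, ignore.case = TRUE)) {
        gr <- rtracklayer::import(path, format = "BED")
        lab <- if (!is.null(mcols(gr)$name)) as.character(mcols(gr)$name)
               else sprintf("%s:%d-%d", as.character(seqnames(gr)),
                            start(gr) - 1L, end(gr))
        mcols(gr) <- DataFrame(label = lab)
        return(gr)
    }
    tab <- read.table(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 3L) stop("interval TSV needs at least 3 columns")
    lab <- if (ncol(tab) >= 4L) as.character(tab[[4L]])
           else sprintf("%s:%d-%d", tab[[1L]], tab[[2L]], tab[[3L]])
    GRanges(tab[[1L]], IRanges(tab[[2L]] + 1L, tab[[3L]]),
            label = lab)
}

#' Islands as a flat table
#'
#' @param islands `GRanges` from [callIslands()].
#' @param population Optional population label override.
#' @return `data.frame` with columns `population`, `chrom`, `start`, `end`,
#'   `n_snps`, `length_bp`, `mean_incidence`.
#' @export
islandTable <- function(islands, population = NULL) {
    pop <- if (!is.null(population)) population
           else if (!is.null(mcols(islands)$population))
               mcols(islands)$population
           else NA_character_
    data.frame(population = pop,
               chrom = as.character(seqnames(islands)),
               start = start(islands), end = end(islands),
               n_snps = mcols(islands)$nSNPs,
               length_bp = width(islands),
               mean_incidence = mcols(islands)$meanIncidence,
               stringsAsFactors = FALSE)
}
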