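# Programmatic fixtures.

# Cohort from an explicit call matrix on one chromosome at given positions.
makeCohort <- function(calls, positions, chrom = "chr1",
                       populations = rep("P", ncol(calls)),
                       chromLength = max(positions) + 1000) {
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(positions, width = 1),
    ref = rep("A", length(positions)), alt = rep("G", length(positions)),
    seqinfo = GenomeInfoDb::Seqinfo(chrom, chromLength))
  GenotypeCohort(calls, gr, populations)
}

# ROHSet built directly from a segment table (columns: individual,
# population, chrom, start, end, nSNPs optional).
makeROHSet <- function(segTable, samples = NULL) {
  if (is.null(samples)) {
    u <- !duplicated(segTable$individual)
    samples <- data.frame(individual = segTable$individual[u],
                          population = segTable$population[u])
  }
  gr <- if (nrow(segTable)) {
    GenomicRanges::GRanges(
      segTable$chrom, IRanges::IRanges(segTable$start, segTable$end),
      individual = segTable$individual, population = segTable$population,
      nSNPs = if ("nSNPs" %in% names(segTable)) segTable$nSNPs
              else as.integer(pmax(50, (segTable$end - segTable$start) %/% 5000)))
  } else {
    GenomicRanges::GRanges(individual = character(0),
                           population = character(0), nSNPs = integer(0))
  }
  ROHSet(gr, scanParams(), samples)
}

# Segment table with per-class counts, lengths at class midpoints (20 Mb for
# the open class), distributed round-robin over a population's individuals.
# Each individual's segments are packed end to end so coordinates stay within
# integer range even for many thousands of segments.
classCountsROHSet <- function(counts, nInd, pop = "P") {
  cls <- rohLengthClasses()
  mids <- ifelse(is.finite(cls$maxMb), (cls$minMb + cls$maxMb) / 2, 20)
  lens <- rep(mids, counts) * 1e6
  ind <- paste0(pop, "_", rep_len(seq_len(nInd), length(lens)))
  ord <- order(ind)
  ind <- ind[ord]; lens <- lens[ord]
  start <- unlist(lapply(split(lens, ind), function(l)
    cumsum(c(1, head(l + 10, -1)))), use.names = FALSE)
  segTable <- data.frame(individual = ind, population = pop, chrom = "chr1",
                         start = start, end = start + lens - 1)
  samples <- data.frame(individual = paste0(pop, "_", seq_len(nInd)),
                        population = pop)
  makeROHSet(segTable, samples)
}

# Best-overlap recovery of truth tracts by called segments: reciprocal
# overlap and boundary error of the best-matching segment per tract.
tractRecovery <- function(truth, segs) {
  recip <- numeric(length(truth))
  bnd <- rep(NA_real_, length(truth))
  for (i in seq_along(truth)) {
    s <- segs[S4Vectors::mcols(segs)$individual ==
                S4Vectors::mcols(truth)$individual[i]]
    h <- GenomicRanges::findOverlaps(truth[i], s)
    if (!length(h)) next
    sh <- s[S4Vectors::subjectHits(h)]
    ov <- BiocGenerics::width(GenomicRanges::pintersect(
      rep(truth[i], length(sh)), sh))
    b <- which.max(ov)
    recip[i] <- min(ov[b] / BiocGenerics::width(truth[i]),
                    ov[b] / BiocGenerics::width(sh[b]))
    bnd[i] <- max(abs(BiocGenerics::start(sh[b]) -
                        BiocGenerics::start(truth[i])),
                  abs(BiocGenerics::end(sh[b]) -
                        BiocGenerics::end(truth[i])))
  }
  data.frame(recip = recip, boundaryError = bnd)
}

# Write a VCF from raw lines (header built here) for parser tests.
writeVcfLines <- function(records, samples, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}
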