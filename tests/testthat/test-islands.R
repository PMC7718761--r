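# ROH incidence, island thresholds/calling, interval intersection.

incidenceFixture <- function(seed = 70, nSnp = 300, nInd = 10) {
  set.seed(seed)
  positions <- sort(sample.int(3e6, nSnp))
  segs <- list()
  for (j in seq_len(nInd)) {
    for (k in seq_len(sample(0:3, 1))) {
      s <- sample.int(2.5e6, 1)
      segs[[length(segs) + 1]] <- data.frame(
        individual = paste0("i", j), population = "P", chrom = "chr1",
        start = s, end = s + sample(1e5:5e5, 1))
    }
  }
  segTable <- do.call(rbind, segs)
  samples <- data.frame(individual = paste0("i", seq_len(nInd)),
                        population = "P")
  list(rohset = makeROHSet(segTable, samples), positions = positions,
       segTable = segTable, samples = samples)
}

test_that("SNP incidence counts covering individuals", {
  positions <- c(100, 5000, 9000)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(positions, width = 1))
  samples <- data.frame(individual = c("a", "b", "c"), population = "P")
  # no segments at all -> incidence 0 everywhere
  rsEmpty <- makeROHSet(data.frame(individual = character(0),
                                   population = character(0),
                                   chrom = character(0), start = numeric(0),
                                   end = numeric(0)), samples)
  expect_equal(S4Vectors::mcols(snpIncidence(rsEmpty, gr, "P"))$incidence,
               c(0, 0, 0))
  # a SNP inside one segment of every individual -> 1.0
  segTable <- data.frame(individual = c("a", "b", "c"), population = "P",
                         chrom = "chr1", start = 4000, end = 6000)
  inc <- S4Vectors::mcols(
    snpIncidence(makeROHSet(segTable, samples), gr, "P"))$incidence
  expect_equal(inc, c(0, 1, 0))
})

test_that("SNP incidence matches the containment-loop oracle", {
  fx <- incidenceFixture()
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(fx$positions, width = 1))
  got <- S4Vectors::mcols(snpIncidence(fx$rohset, gr, "P"))$incidence
  want <- incidenceOracle(fx$positions, rep("chr1", length(fx$positions)),
                          fx$segTable, fx$samples$individual)
  expect_equal(got, want)
})

test_that("island threshold is the nearest-rank top quantile", {
  expect_equal(islandThreshold(seq(0.01, 1, by = 0.01), 0.01), 1)
  expect_warning(thr <- islandThreshold(rep(0, 50), 0.01), "degenerate")
  expect_equal(thr, 0)
  set.seed(71)
  inc <- sample(seq(0, 1, by = 0.05), 10000, replace = TRUE)
  k <- ceiling(0.01 * length(inc))
  expect_equal(islandThreshold(inc, 0.01),
               sort(inc, decreasing = TRUE)[k])
  expect_equal(islandThreshold(inc, 0.25),
               sort(inc, decreasing = TRUE)[2500])
  expect_error(islandThreshold(numeric(0)), "empty")
})

test_that("islands are maximal qualifying runs of at least two SNPs", {
  pos <- seq(1e5, by = 5000, length.out = 200)
  inc <- rep(0.4, 200); inc[101:150] <- 1
  track <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 1),
                                  incidence = inc)
  isl <- callIslands(track, 0.96)
  expect_equal(length(isl), 1L)
  expect_equal(BiocGenerics::start(isl), pos[101])
  expect_equal(BiocGenerics::end(isl), pos[150])
  expect_equal(S4Vectors::mcols(isl)$nSNPs, 50L)
  # impossible threshold
  expect_equal(length(callIslands(track, 1.01)), 0L)
  # single qualifying SNP is discarded
  inc1 <- rep(0.1, 200); inc1[7] <- 1
  track1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 1),
                                   incidence = inc1)
  expect_equal(length(callIslands(track1, 0.96)), 0L)
  # a physical gap splits an island
  posGap <- c(seq(1e5, by = 5000, length.out = 50),
              seq(3e6, by = 5000, length.out = 50))
  trackGap <- GenomicRanges::GRanges("chr1",
                                     IRanges::IRanges(posGap, width = 1),
                                     incidence = rep(1, 100))
  expect_equal(length(callIslands(trackGap, 0.5)), 2L)
})

test_that("island calling matches a run-enumeration oracle", {
  set.seed(72)
  for (rep in 1:20) {
    n <- sample(100:500, 1)
    pos <- sort(sample.int(5e6, n))
    inc <- round(sample(seq(0, 1, by = 0.1), n, replace = TRUE), 10)
    thr <- sample(seq(0.2, 0.9, by = 0.1), 1)
    track <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(pos, width = 1),
                                    incidence = inc)
    isl <- callIslands(track, thr, maxGapKb = 500, minSnps = 2)
    # oracle: walk the SNPs
    want <- list()
    i <- 1
    while (i <= n) {
      if (inc[i] < thr) { i <- i + 1; next }
      j <- i
      while (j < n && inc[j + 1] >= thr && pos[j + 1] - pos[j] <= 5e5)
        j <- j + 1
      if (j > i)
        want[[length(want) + 1]] <- c(pos[i], pos[j], j - i + 1)
      i <- j + 1
    }
    expect_equal(length(isl), length(want))
    for (k in seq_along(want)) {
      expect_equal(BiocGenerics::start(isl)[k], want[[k]][1])
      expect_equal(BiocGenerics::end(isl)[k], want[[k]][2])
      expect_equal(S4Vectors::mcols(isl)$nSNPs[k], want[[k]][3])
    }
    # completeness: every member SNP qualifies
    if (length(isl)) {
      for (k in seq_along(isl)) {
        member <- pos >= BiocGenerics::start(isl)[k] &
          pos <= BiocGenerics::end(isl)[k]
        expect_true(all(inc[member] >= thr))
      }
    }
  }
})

test_that("interval intersection uses half-open semantics", {
  a <- data.frame(chrom = "chr1", start = 10, end = 20, label = "A1")
  b <- data.frame(chrom = c("chr1", "chr1"), start = c(15, 20),
                  end = c(25, 30), label = c("B1", "B2"))
  ov <- intersectIntervals(a, b)
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$overlapBp, 5)
  expect_equal(ov$bLabel, "B1")
  expect_error(
    intersectIntervals(data.frame(chrom = "c", start = 5, end = 5), b),
    "malformed")
})

test_that("interval intersection matches the quadratic oracle and is symmetric", {
  set.seed(73)
  rand <- function(n) {
    s <- sample.int(1e6, n)
    data.frame(chrom = sample(c("c1", "c2"), n, replace = TRUE),
               start = s, end = s + sample.int(5e4, n))
  }
  a <- rand(40); b <- rand(40)
  got <- intersectIntervals(a, b)
  want <- intersectOracle(a, b)
  o1 <- order(got$aIndex, got$bIndex); o2 <- order(want$aIndex, want$bIndex)
  expect_equal(got$aIndex[o1], want$aIndex[o2])
  expect_equal(got$bIndex[o1], want$bIndex[o2])
  expect_equal(got$overlapBp[o1], want$overlapBp[o2])
  # symmetry up to column swap
  rev <- intersectIntervals(b, a)
  o3 <- order(rev$bIndex, rev$aIndex)
  expect_equal(rev$bIndex[o3], got$aIndex[o1])
  expect_equal(rev$aIndex[o3], got$bIndex[o1])
  expect_equal(rev$overlapBp[o3], got$overlapBp[o1])
})

test_that("annotation readers accept BED and TSV", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tqtl1", "chr2\t500\t900\tqtl2"), bed)
  gr <- readIntervals(bed)
  expect_equal(length(gr), 2L)
  expect_equal(BiocGenerics::start(gr), c(101L, 501L))  # 1-based internal
  expect_equal(S4Vectors::mcols(gr)$label, c("qtl1", "qtl2"))
  tsv <- tempfile(fileext = ".txt")
  writeLines("chr1\t100\t200\tq1\ttrait", tsv)
  gr2 <- readIntervals(tsv)
  expect_equal(S4Vectors::mcols(gr2)$label, "q1")
})
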