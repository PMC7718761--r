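# Sliding-window ROH caller.

test_that("window hit rates are 1 for all-homozygous and 0 for all-het", {
  p <- scanParams()
  expect_equal(windowHitRates(rep(0L, 100), p), rep(1, 100))
  expect_equal(windowHitRates(rep(1L, 100), p), rep(0, 100))
  # a single het within the allowance leaves every window homozygous
  calls <- rep(2L, 150); calls[75] <- 1L
  expect_equal(windowHitRates(calls, p), rep(1, 150))
  # four hets in a cluster exceed the 3-het allowance for covering windows
  calls4 <- rep(0L, 150); calls4[70:73] <- 1L
  expect_lt(min(windowHitRates(calls4, p)), 1)
  expect_error(windowHitRates(integer(0), p), "empty")
})

test_that("chromosomes shorter than one window use a single window", {
  p <- scanParams()
  expect_equal(windowHitRates(rep(0L, 10), p), rep(1, 10))
  expect_equal(windowHitRates(c(rep(0L, 6), rep(1L, 4)), p), rep(0, 10))
})

test_that("callROH enforces each of the seven criteria", {
  p <- scanParams()
  pos60 <- seq(1e5, 5e5, length.out = 60)            # 60 SNPs over 400 kb
  seg <- callROH(rep(0L, 60), pos60, p)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start, pos60[1])
  expect_equal(seg$end, pos60[60])
  expect_equal(seg$nSNPs, 60L)
  # too short: 60 SNPs over 200 kb
  expect_equal(nrow(callROH(rep(0L, 60), seq(1e5, 3e5, length.out = 60), p)),
               0L)
  # too few SNPs: 40 over 400 kb
  expect_equal(nrow(callROH(rep(0L, 40), seq(1e5, 5e5, length.out = 40), p)),
               0L)
  # physical gap splits the run into two reportable halves
  posGap <- c(seq(1e5, 4.5e5, length.out = 60),
              seq(2e6, 2.35e6, length.out = 60))
  segs <- callROH(rep(0L, 120), posGap, p)
  expect_equal(nrow(segs), 2L)
  # density floor: 60 SNPs spread over 4 Mb is sparser than 1 SNP / 50 kb
  expect_equal(nrow(callROH(rep(0L, 60), seq(1e5, 4.1e6, length.out = 60), p)),
               0L)
  expect_error(callROH(rep(0L, 5), 1:4, p), "same length")
  expect_error(callROH(rep(0L, 3), c(10, 10, 20), p), "strictly increasing")
})

test_that("heterozygous SNPs are never segment members", {
  p <- scanParams()
  calls <- rep(0L, 120); calls[60] <- 1L
  pos <- seq(1e5, 1.4e6, length.out = 120)
  segs <- callROH(calls, pos, p)
  # the run is interrupted at the het SNP; both flanks (59 and 60 SNPs,
  # each > 300 kb) survive the floors
  expect_equal(nrow(segs), 2L)
  expect_true(all(segs$end < pos[60] | segs$start > pos[60]))
})

test_that("missing calls may sit inside segments", {
  p <- scanParams()
  calls <- rep(0L, 60); calls[30] <- NA
  pos <- seq(1e5, 5e5, length.out = 60)
  segs <- callROH(calls, pos, p)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$nSNPs, 60L)
})

test_that("optional segment-level caps prune segments after the scan", {
  calls <- rep(0L, 80); calls[c(20, 40, 60)] <- NA
  pos <- seq(1e5, 6e5, length.out = 80)
  expect_equal(nrow(callROH(calls, pos, scanParams())), 1L)
  capped <- scanParams(segmentMaxMissing = 2L)
  expect_equal(nrow(callROH(calls, pos, capped)), 0L)
})

test_that("callROH equals the brute-force oracle on random chromosomes", {
  set.seed(4242)
  p <- scanParams()
  for (rep in 1:30) {
    n <- sample(60:1500, 1)
    chrom <- randomChromosome(n, pHet = sample(c(0.01, 0.03, 0.1, 0.3), 1),
                              pMiss = sample(c(0, 0.02, 0.08), 1))
    got <- callROH(chrom$calls, chrom$positions, p)
    want <- rohOracle(chrom$calls, chrom$positions, p)
    expect_equal(got, want)
  }
})

test_that("raising the post-filters never adds segments or length", {
  set.seed(555)
  base <- scanParams()
  for (rep in 1:10) {
    chrom <- randomChromosome(1000, pHet = 0.05, pMiss = 0.02)
    s0 <- callROH(chrom$calls, chrom$positions, base)
    s1 <- callROH(chrom$calls, chrom$positions, scanParams(minLengthKb = 600))
    s2 <- callROH(chrom$calls, chrom$positions, scanParams(minSnps = 80))
    expect_lte(nrow(s1), nrow(s0)); expect_lte(sum(s1$length), sum(s0$length))
    expect_lte(nrow(s2), nrow(s0)); expect_lte(sum(s2$length), sum(s0$length))
  }
})

test_that("no reported segment spans a flagged gap beyond the maximum", {
  set.seed(556)
  p <- scanParams()
  for (rep in 1:10) {
    chrom <- randomChromosome(800, pHet = 0.04, pMiss = 0.02,
                              maxSpacing = 100000)
    segs <- callROH(chrom$calls, chrom$positions, p)
    for (k in seq_len(nrow(segs))) {
      inside <- chrom$positions >= segs$start[k] &
        chrom$positions <= segs$end[k]
      expect_lte(max(diff(chrom$positions[inside])), p$maxGapKb * 1000)
    }
  }
})

test_that("an error-free planted 2-Mb tract is recovered almost exactly", {
  layout <- genomeLayout(data.frame(chrom = "chr1", length = 10e6))
  extra <- data.frame(individual = "A_1", chrom = "chr1",
                      start = 4e6, end = 6e6 - 1)
  sim <- simulateCohort(layout, list(populationProfile("A", 5, 0.28)),
                        seed = 77, extraTracts = extra)
  rohset <- suppressMessages(scanCohort(sim$cohort))
  segs <- rohSegments(rohset)
  segs <- segs[S4Vectors::mcols(segs)$individual == "A_1"]
  hits <- GenomicRanges::findOverlaps(segs, sim$truth)
  expect_gte(length(hits), 1L)
  ovw <- BiocGenerics::width(GenomicRanges::pintersect(
    segs[S4Vectors::queryHits(hits)], sim$truth[S4Vectors::subjectHits(hits)]))
  best <- which.max(ovw)
  segW <- BiocGenerics::width(segs)[S4Vectors::queryHits(hits)[best]]
  recip <- min(ovw[best] / segW, ovw[best] / BiocGenerics::width(sim$truth))
  expect_gte(recip, 0.95)
})

test_that("scanCohort composes callROH over individuals and chromosomes", {
  # all-heterozygous cohort yields an empty ROHSet
  callsHet <- matrix(1L, 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  cohortHet <- makeCohort(callsHet, positions = (1:200) * 4000)
  rsHet <- suppressMessages(scanCohort(cohortHet))
  expect_equal(length(rohSegments(rsHet)), 0L)
  expect_equal(nrow(rohSamples(rsHet)), 3L)
  # one individual, one chromosome: identical to callROH on the slice
  set.seed(31)
  chrom <- randomChromosome(600, pHet = 0.05)
  cohort1 <- makeCohort(matrix(chrom$calls, ncol = 1,
                               dimnames = list(NULL, "solo")),
                        positions = chrom$positions)
  rs1 <- suppressMessages(scanCohort(cohort1))
  direct <- callROH(chrom$calls, chrom$positions, scanParams())
  segs1 <- rohSegments(rs1)
  expect_equal(BiocGenerics::start(segs1), direct$start)
  expect_equal(BiocGenerics::end(segs1), direct$end)
  expect_equal(S4Vectors::mcols(segs1)$nSNPs, direct$nSNPs)
})
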