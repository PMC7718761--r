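# Length-class tables, FROH, chromosome coverage, correlation.

test_that("length classes use left-closed right-open Mb bins", {
  rs <- makeROHSet(data.frame(
    individual = "i1", population = "P", chrom = "chr1",
    start = c(1e6, 10e6, 20e6),
    end = c(1e6 + 0.95e6 - 1, 10e6 + 1e6 - 1, 20e6 + 16e6 - 1)))
  lc <- classifyLengths(rs)
  got <- lc$byClass[lc$byClass$count > 0, ]
  expect_equal(got$class, c("0.3-1Mb", "1-2Mb", ">16Mb"))
  expect_equal(got$count, c(1L, 1L, 1L))
  # a segment below the smallest class violates the caller contract
  tooShort <- makeROHSet(data.frame(individual = "i1", population = "P",
                                    chrom = "chr1", start = 1e6,
                                    end = 1e6 + 2e5 - 1))
  expect_error(classifyLengths(tooShort), "smallest class")
})

test_that("class shares and per-bird means reproduce printed-table arithmetic", {
  # one population of 25 individuals with class counts as printed for the
  # most ROH-rich line, another with the wild-type counts
  rsWL <- classCountsROHSet(c(9458, 2619, 688, 42, 0, 0, 0), 25, "WL")
  lc <- classifyLengths(rsWL)
  expect_equal(lc$totals$total_n, 12807L)
  expect_equal(lc$totals$mean_n, 512.28)
  smallest <- lc$byClass[lc$byClass$class == "0.3-1Mb", ]
  expect_equal(round(smallest$percent, 1), 73.9)
  rsRJF <- classCountsROHSet(c(1083, 504, 330, 153, 17, 12, 1), 25, "RJF")
  lcR <- classifyLengths(rsRJF)
  expect_equal(lcR$totals$total_n, 2100L)
  expect_equal(lcR$totals$mean_n, 84)
  expect_equal(round(lcR$byClass$percent[lcR$byClass$class == "0.3-1Mb"], 1),
               51.6)
})

test_that("per-individual summary covers zero-segment individuals", {
  segTable <- data.frame(individual = c("a", "a", "b"), population = "P",
                         chrom = "chr1", start = c(1e6, 3e6, 5e6),
                         end = c(1.5e6, 3.4e6, 5.9e6))
  samples <- data.frame(individual = c("a", "b", "c"), population = "P")
  psum <- perIndividualSummary(makeROHSet(segTable, samples))
  expect_equal(psum$n_segments, c(2L, 1L, 0L))
  expect_equal(psum$total_length_bp,
               c(1.5e6 - 1e6 + 1 + 3.4e6 - 3e6 + 1, 5.9e6 - 5e6 + 1, 0))
  empty <- makeROHSet(segTable[0, ], samples)
  expect_equal(perIndividualSummary(empty)$n_segments, c(0L, 0L, 0L))
  expect_equal(classifyLengths(empty)$totals$mean_n, 0)
})

test_that("FROH is total ROH length over the genome size, additive by class", {
  # a bird carrying 432.1 Mb of ROH against a 931 Mb genome
  lens <- c(rep(4e6, 100), 32.1e6)  # 432.1 Mb total
  start <- cumsum(c(1, head(lens + 10, -1)))
  rs <- makeROHSet(data.frame(individual = "bird1", population = "WL",
                              chrom = "chr1", start = start,
                              end = start + lens - 1))
  fr <- fROH(rs, genomeSizeBp = 931e6)
  expect_equal(round(fr$froh_total, 2), 0.46)
  clsCols <- grep("^froh_", names(fr), value = TRUE)
  clsCols <- setdiff(clsCols, "froh_total")
  expect_equal(sum(fr[, clsCols]), fr$froh_total, tolerance = 1e-9)
  # wild-bird-scale burden
  rs2 <- makeROHSet(data.frame(individual = "w1", population = "RJF",
                               chrom = "chr1", start = 1e6,
                               end = 1e6 + 134.6e6 - 1))
  expect_equal(round(fROH(rs2, 931e6)$froh_total, 2), 0.14)
  # no segments -> 0
  rsEmpty <- makeROHSet(data.frame(individual = character(0),
                                   population = character(0),
                                   chrom = character(0), start = numeric(0),
                                   end = numeric(0)),
                        data.frame(individual = "x", population = "P"))
  expect_equal(fROH(rsEmpty, 931e6)$froh_total, 0)
  # mis-configured genome size warns rather than errors
  expect_warning(fROH(rs, genomeSizeBp = 1e8), "exceeds")
})

test_that("chromosome coverage averages union length over all individuals", {
  lens <- c(chr1 = 2e6, chr2 = 1e6)
  segTable <- data.frame(individual = c("a", "b"), population = "P",
                         chrom = "chr1", start = c(1, 1), end = c(1e6, 5e5))
  samples <- data.frame(individual = c("a", "b"), population = "P")
  cov <- chromosomeCoverage(makeROHSet(segTable, samples), lens)
  chr1 <- cov[cov$chrom == "chr1", ]
  expect_equal(chr1$percent_covered, mean(c(50, 25)))
  expect_equal(cov[cov$chrom == "chr2", ]$percent_covered, 0)
  expect_equal(chr1$n_roh, 2L)
  expect_error(
    chromosomeCoverage(makeROHSet(segTable, samples), c(chrX = 1e6)),
    "absent")
})

test_that("chromosome coverage matches a base-pair bitmap oracle", {
  set.seed(60)
  chromLen <- 2e5
  segs <- list()
  for (ind in c("a", "b", "c")) {
    # random disjoint segments per individual
    starts <- sort(sample(seq(1, chromLen - 2e4, by = 2e4),
                          sample(3, 1)))
    for (s in starts)
      segs[[length(segs) + 1]] <- data.frame(
        individual = ind, population = "P", chrom = "c1",
        start = s, end = s + sample(5e3:1.5e4, 1))
  }
  segTable <- do.call(rbind, segs)
  samples <- data.frame(individual = c("a", "b", "c"), population = "P")
  cov <- chromosomeCoverage(makeROHSet(segTable, samples),
                            c(c1 = chromLen))
  perInd <- vapply(samples$individual, function(ind) {
    mask <- logical(chromLen)
    sub <- segTable[segTable$individual == ind, ]
    for (k in seq_len(nrow(sub))) mask[sub$start[k]:sub$end[k]] <- TRUE
    sum(mask) / chromLen * 100
  }, numeric(1))
  expect_equal(cov$percent_covered, mean(perInd))
})

test_that("Pearson correlation matches the closed-form computation", {
  expect_equal(pearsonCorrelation(1:10, 1:10)$r, 1)
  expect_equal(pearsonCorrelation(1:10, -(1:10))$r, -1)
  set.seed(61)
  x <- rnorm(20); y <- 0.6 * x + rnorm(20)
  got <- pearsonCorrelation(x, y)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt(18 / (1 - r^2))
  expect_equal(got$r, r, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(tstat), 18), tolerance = 1e-12)
  expect_error(pearsonCorrelation(rep(1, 5), 1:5), "variance")
  expect_error(pearsonCorrelation(1:2, 1:2), "3 complete pairs")
})

test_that("Fis and FROH correlate strongly when tracts drive inbreeding", {
  layout <- genomeLayout(data.frame(chrom = "chr1", length = 25e6))
  nInd <- 50
  # tract burden ramping from 0 to ~40% of the genome across individuals
  extras <- list()
  for (j in seq_len(nInd)) {
    nT <- round((j - 1) / (nInd - 1) * 10)
    if (nT > 0)
      extras[[length(extras) + 1]] <- data.frame(
        individual = paste0("A_", j), chrom = "chr1",
        start = seq(5e5, by = 2.4e6, length.out = nT),
        end = seq(5e5, by = 2.4e6, length.out = nT) + 1e6 - 1)
  }
  sim <- simulateCohort(layout, list(populationProfile("A", nInd, 0.3)),
                        seed = 62, extraTracts = do.call(rbind, extras))
  rohset <- suppressMessages(scanCohort(sim$cohort))
  fr <- fROH(rohset, genomeSizeBp = 25e6)
  fis <- wrightFis(sim$cohort, "A")
  stopifnot(identical(fr$individual, fis$individual))
  ct <- pearsonCorrelation(fis$fis, fr$froh_total)
  expect_gt(ct$r, 0.5)
})

test_that("population FROH summary aggregates the per-individual table", {
  rs <- classCountsROHSet(c(4, 2, 0, 0, 0, 0, 0), 3, "P")
  fr <- fROH(rs, genomeSizeBp = 931e6)
  fs <- frohSummary(fr)
  expect_equal(fs$froh_total, mean(fr$froh_total))
  expect_equal(fs$froh_total_sd, sd(fr$froh_total))
  expect_equal(fs$n, 3L)
})
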