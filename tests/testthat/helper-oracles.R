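# Independent brute-force oracles. These deliberately use direct enumeration
# and explicit loops, not the vectorised routines they validate.

# Exact HWE p-value by full enumeration: conditional probabilities computed
# from binomial coefficients (not the log-factorial route of the package).
hweOracle <- function(nHom1, nHet, nHom2) {
  n <- nHom1 + nHet + nHom2
  nA <- 2 * nHom1 + nHet
  rare <- min(nA, 2 * n - nA)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  w <- numeric(length(hets))
  for (i in seq_along(hets)) {
    h <- hets[i]
    nAA <- (rare - h) / 2
    w[i] <- choose(n, nAA) * choose(n - nAA, h) * 2^h
  }
  pr <- w / sum(w)
  pObs <- pr[hets == nHet]
  min(1, sum(pr[pr <= pObs * (1 + 1e-9)]))
}

# ROH calling by direct window enumeration and run scanning.
rohOracle <- function(calls, positions, p = scanParams()) {
  n <- length(calls)
  het <- !is.na(calls) & calls == 1L
  mis <- is.na(calls)
  w <- p$windowSnps
  if (n < w) {
    rate <- rep(as.numeric(sum(het) <= p$windowMaxHet &&
                             sum(mis) <= p$windowMaxMissing), n)
  } else {
    nw <- n - w + 1
    homWin <- logical(nw)
    for (s in seq_len(nw)) {
      idx <- s:(s + w - 1)
      homWin[s] <- sum(het[idx]) <= p$windowMaxHet &&
        sum(mis[idx]) <= p$windowMaxMissing
    }
    rate <- numeric(n)
    for (i in seq_len(n)) {
      ws <- max(1, i - w + 1):min(nw, i)
      rate[i] <- mean(homWin[ws])
    }
  }
  flag <- rate >= p$hitProportion & !het
  segs <- list()
  i <- 1
  while (i <= n) {
    if (!flag[i]) { i <- i + 1; next }
    j <- i
    while (j < n && flag[j + 1] &&
             positions[j + 1] - positions[j] <= p$maxGapKb * 1000) j <- j + 1
    ns <- j - i + 1
    len <- positions[j] - positions[i] + 1
    keep <- ns >= p$minSnps && len >= p$minLengthKb * 1000 &&
      len / ns <= p$minDensityKbPerSnp * 1000
    if (keep && !is.null(p$segmentMaxHet))
      keep <- sum(het[i:j]) <= p$segmentMaxHet
    if (keep && !is.null(p$segmentMaxMissing))
      keep <- sum(mis[i:j]) <= p$segmentMaxMissing
    if (keep)
      segs[[length(segs) + 1]] <- data.frame(
        start = positions[i], end = positions[j], nSNPs = ns, length = len)
    i <- j + 1
  }
  if (length(segs)) do.call(rbind, segs)
  else data.frame(start = numeric(0), end = numeric(0), nSNPs = integer(0),
                  length = numeric(0))
}

# Per-SNP ROH incidence by an O(SNPs x segments) containment loop.
incidenceOracle <- function(positions, chroms, segTable, individuals) {
  out <- numeric(length(positions))
  for (i in seq_along(positions)) {
    covered <- character(0)
    for (s in seq_len(nrow(segTable))) {
      if (segTable$chrom[s] == chroms[i] &&
            segTable$start[s] <= positions[i] &&
            segTable$end[s] >= positions[i])
        covered <- union(covered, segTable$individual[s])
    }
    out[i] <- length(covered) / length(individuals)
  }
  out
}

# All-pairs interval overlap on half-open BED-style intervals.
intersectOracle <- function(a, b) {
  res <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= 1)
        res[[length(res) + 1]] <- data.frame(aIndex = i, bIndex = j,
                                             overlapBp = ov)
    }
  }
  if (length(res)) do.call(rbind, res)
  else data.frame(aIndex = integer(0), bIndex = integer(0),
                  overlapBp = integer(0))
}

# Random single-chromosome genotype vector with hom stretches.
randomChromosome <- function(n, pHet, pMiss = 0, maxSpacing = 20000) {
  positions <- cumsum(sample.int(maxSpacing, n, replace = TRUE))
  g <- ifelse(runif(n) < pHet, 1L, ifelse(runif(n) < 0.5, 0L, 2L))
  g[runif(n) < pMiss] <- NA
  list(calls = as.integer(g), positions = positions)
}
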