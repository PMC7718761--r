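# Exact test of Hardy-Weinberg equilibrium for a biallelic SNP.

# Two-sided exact p for one genotype-count triple. Conditional on the
# observed allele counts, the number of heterozygotes nAB follows
#   P(nAB | n, nA)  proportional to  n! 2^nAB / (nAA! nAB! nBB!),
# over all nAB with the parity of the minor-allele count. The p-value sums
# the probabilities of all configurations no more likely than the observed
# one (with a small relative tolerance guarding ties against rounding).
.hweExactP <- function(nHom1, nHet, nHom2) {
    n <- nHom1 + nHet + nHom2
    if (n < 1L) stop("at least one genotyped individual is required")
    nA <- 2L * nHom1 + nHet
    rare <- min(nA, 2L * n - nA)
    if (rare == 0L) return(1)           # monomorphic: single configuration
    hets <- seq.int(rare %% 2L, rare, by = 2L)
    nAA <- (rare - hets) / 2
    nBB <- n - nAA - hets
    logw <- lfactorial(n) - lfactorial(nAA) - lfactorial(hets) -
        lfactorial(nBB) + hets * log(2)
    pr <- exp(logw - max(logw))
    pr <- pr / sum(pr)
    pObs <- pr[match(nHet, hets)]
    min(1, sum(pr[pr <= pObs * (1 + 1e-9)]))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on the genotype counts of a biallelic SNP,
#' conditioning on the observed allele counts. The p-value is the total
#' probability of all heterozygote counts (with matching allele-count parity)
#' whose conditional probability does not exceed that of the observed count.
#' For a monomorphic SNP the only attainable configuration is the observed
#' one and the p-value is 1.
#'
#' @param nHom1,nHet,nHom2 Non-negative genotype counts (vectorised; recycled
#'   to a common length). Each triple must sum to at least 1.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' hweExactTest(5, 0, 0)        # monomorphic -> 1
#' hweExactTest(20, 50, 30)
#' @export
hweExactTest <- function(nHom1, nHet, nHom2) {
    k <- max(length(nHom1), length(nHet), length(nHom2))
    nHom1 <- rep_len(as.integer(nHom1), k)
    nHet <- rep_len(as.integer(nHet), k)
    nHom2 <- rep_len(as.integer(nHom2), k)
    if (any(nHom1 < 0L | nHet < 0L | nHom2 < 0L, na.rm = TRUE))
        stop("genotype counts must be non-negative")
    vapply(seq_len(k), function(i) .hweExactP(nHom1[i], nHet[i], nHom2[i]),
           numeric(1))
}

# Vectorised p-values with caching over duplicate triples; triples with no
# genotyped individuals give NA.
.hweVec <- function(n0, n1, n2) {
    key <- paste(n0, n1, n2)
    first <- which(!duplicated(key))
    pv <- vapply(first, function(i) {
        if (n0[i] + n1[i] + n2[i] == 0L) NA_real_
        else .hweExactP(n0[i], n1[i], n2[i])
    }, numeric(1))
    pv[match(key, key[first])]
}
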