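# Length-class, per-individual, genomic-inbreeding and chromosome-coverage
# summaries of an ROHSet.

.popCounts <- function(rohset) {
    tab <- table(rohSamples(rohset)$population)
    setNames(as.integer(tab), names(tab))
}

#' Classify ROH segments into length classes
#'
#' Bins are left-closed, right-open in Mb (a segment of exactly 1.0 Mb falls
#' in the 1-2 Mb class). Percentages are per population, over that
#' population's total segment count.
#'
#' @param rohset An [ROHSet-class].
#' @param classes Class table as from [rohLengthClasses()].
#' @return List with `byClass` (`data.frame`: population, class, count,
#'   percent) and `totals` (`data.frame`: population, total_n, mean_n,
#'   total_length_mb, max_mb, min_mb). Populations without segments appear
#'   with zero counts.
#' @export
classifyLengths <- function(rohset, classes = rohLengthClasses()) {
    stopifnot(is(rohset, "ROHSet"), nrow(classes) >= 1L)
    segs <- rohSegments(rohset)
    lenMb <- width(segs) / 1e6
    if (length(lenMb) && any(lenMb < min(classes$minMb)))
        stop(sprintf("segment shorter than the smallest class (%.2f Mb)",
                     min(classes$minMb)))
    popLevels <- levels(rohSamples(rohset)$population)
    cls <- cut(lenMb, breaks = c(classes$minMb, Inf), right = FALSE,
               labels = classes$label)
    pop <- factor(mcols(segs)$population, levels = popLevels)
    counts <- table(population = pop, class = cls)
    byClass <- as.data.frame(counts, stringsAsFactors = FALSE)
    names(byClass) <- c("population", "class", "count")
    totals <- tapply(rep(1L, length(segs)), pop, sum)
    totals[is.na(totals)] <- 0L
    byClass$percent <- ifelse(totals[byClass$population] > 0,
                              byClass$count / totals[byClass$population] * 100,
                              0)
    byClass <- byClass[order(match(byClass$population, popLevels),
                             match(byClass$class, classes$label)), ]
    rownames(byClass) <- NULL

    nInd <- .popCounts(rohset)
    totRow <- lapply(popLevels, function(pl) {
        sel <- pop == pl
        data.frame(population = pl,
                   total_n = as.integer(totals[pl]),
                   mean_n = as.numeric(totals[pl]) / nInd[pl],
                   total_length_mb = sum(lenMb[sel]),
                   max_mb = if (any(sel)) max(lenMb[sel]) else NA_real_,
                   min_mb = if (any(sel)) min(lenMb[sel]) else NA_real_,
                   stringsAsFactors = FALSE)
    })
    list(byClass = byClass, totals = do.call(rbind, totRow))
}

#' Per-individual ROH burden
#'
#' @param rohset An [ROHSet-class].
#' @return `data.frame` with one row per scanned individual (zero-segment
#'   individuals included): `individual`, `population`, `n_segments`,
#'   `total_length_bp`.
#' @export
perIndividualSummary <- function(rohset) {
    segs <- rohSegments(rohset)
    samples <- rohSamples(rohset)
    ind <- factor(mcols(segs)$individual, levels = samples$individual)
    n <- tapply(rep(1L, length(segs)), ind, sum)
    tot <- tapply(width(segs), ind, sum)
    n[is.na(n)] <- 0L
    tot[is.na(tot)] <- 0
    data.frame(individual = samples$individual,
               population = samples$population,
               n_segments = as.integer(n[samples$individual]),
               total_length_bp = as.numeric(tot[samples$individual]),
               stringsAsFactors = FALSE)
}

#' Genomic inbreeding coefficient FROH per individual
#'
#' FROH is the summed length of an individual's ROH divided by the genome
#' size `genomeSizeBp` (default 931 Mb, the SNP-covered autosomal genome of
#' the chicken Gallus_gallus-5.0 assembly; supply the simulated genome size
#' for simulated cohorts). Per-class coefficients use only the segments of
#' each length class and sum to the total.
#'
#' @param rohset An [ROHSet-class].
#' @param genomeSizeBp Autosomal genome size in bp (> 0).
#' @param classes Length classes as from [rohLengthClasses()].
#' @return `data.frame` with `individual`, `population`, `froh_total` and one
#'   `froh_<class>` column per length class.
#' @export
fROH <- function(rohset, genomeSizeBp = 931e6, classes = rohLengthClasses()) {
    stopifnot(genomeSizeBp > 0)
    segs <- rohSegments(rohset)
    samples <- rohSamples(rohset)
    ind <- factor(mcols(segs)$individual, levels = samples$individual)
    cls <- cut(width(segs) / 1e6, breaks = c(classes$minMb, Inf),
               right = FALSE, labels = classes$label)
    out <- data.frame(individual = samples$individual,
                      population = samples$population,
                      stringsAsFactors = FALSE)
    byCls <- matrix(0, nrow(samples), nrow(classes),
                    dimnames = list(samples$individual, classes$label))
    if (length(segs)) {
        agg <- tapply(width(segs), list(ind, cls), sum)
        agg[is.na(agg)] <- 0
        byCls[rownames(agg), colnames(agg)] <- agg
    }
    byCls <- byCls / genomeSizeBp
    out$froh_total <- rowSums(byCls)
    if (any(out$froh_total > 1))
        warning("total ROH length exceeds the genome size for some ",
                "individuals; check 'genomeSizeBp'")
    cn <- paste0("froh_", gsub("[^0-9A-Za-z.>]+", "_", classes$label))
    for (k in seq_len(nrow(classes))) out[[cn[k]]] <- byCls[, k]
    rownames(out) <- NULL
    out
}

#' Per-chromosome ROH summary
#'
#' For every population x chromosome: the segment count, mean segment length
#' (Mb) and the mean percentage of the chromosome covered by ROH, averaged
#' over all of the population's individuals (individuals without ROH on the
#' chromosome contribute zero coverage).
#'
#' @param rohset An [ROHSet-class].
#' @param chromLengths Chromosome lengths: a [GenomeLayout-class], a
#'   `data.frame` with columns `chrom`/`length`, or a named numeric vector.
#' @return `data.frame` with columns `population`, `chrom`, `n_roh`,
#'   `mean_length_mb`, `percent_covered`.
#' @export
chromosomeCoverage <- function(rohset, chromLengths) {
    lens <- if (is(chromLengths, "GenomeLayout")) {
        setNames(chromLengths@chromosomes$length,
                 chromLengths@chromosomes$chrom)
    } else if (is.data.frame(chromLengths)) {
        setNames(as.numeric(chromLengths$length), chromLengths$chrom)
    } else {
        chromLengths
    }
    segs <- rohSegments(rohset)
    segChr <- as.character(seqnames(segs))
    if (length(segs) && !all(segChr %in% names(lens)))
        stop("segment on chromosome absent from 'chromLengths': ",
             paste(setdiff(segChr, names(lens)), collapse = ", "))
    samples <- rohSamples(rohset)
    nInd <- .popCounts(rohset)
    rows <- list()
    for (pop in levels(samples$population)) {
        for (cname in names(lens)) {
            sel <- mcols(segs)$population == pop & segChr == cname
            covInd <- tapply(width(segs)[sel],
                             factor(mcols(segs)$individual[sel],
                                    levels = samples$individual[
                                        samples$population == pop]),
                             sum)
            covInd[is.na(covInd)] <- 0
            rows[[length(rows) + 1L]] <- data.frame(
                population = pop, chrom = cname,
                n_roh = as.integer(sum(sel)),
                mean_length_mb = if (any(sel))
                    mean(width(segs)[sel]) / 1e6 else NA_real_,
                percent_covered = mean(covInd) / lens[cname] * 100,
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Pearson correlation with a two-sided t-test
#'
#' Product-moment correlation between two equal-length vectors (length >= 3,
#' both with nonzero variance) and the two-sided p-value from the t transform
#' with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors.
#' @return List with elements `r` and `p`.
#' @export
pearsonCorrelation <- function(x, y) {
    if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L) stop("at least 3 complete pairs are required")
    if (sd(x) == 0 || sd(y) == 0) stop("zero variance in 'x' or 'y'")
    ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
    list(r = unname(ct$estimate), p = ct$p.value)
}

#' Population-level FROH summary table
#'
#' Mean per-class FROH and the mean and SD of total FROH per population.
#'
#' @param frohTable Output of [fROH()].
#' @return `data.frame`, one row per population.
#' @export
frohSummary <- function(frohTable) {
    cols <- grep("^froh_", colnames(frohTable), value = TRUE)
    pops <- unique(as.character(frohTable$population))
    rows <- lapply(pops, function(pop) {
        sub <- frohTable[frohTable$population == pop, cols, drop = FALSE]
        out <- as.data.frame(as.list(colMeans(sub)))
        out$froh_total_sd <- sd(sub$froh_total)
        cbind(data.frame(population = pop, n = nrow(sub),
                         stringsAsFactors = FALSE), out)
    })
    do.call(rbind, rows)
}
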