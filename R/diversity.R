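# Per-population diversity metrics and Wright's inbreeding coefficient.

.popColumns <- function(cohort, population) {
    pops <- colData(cohort)$population
    if (!population %in% levels(pops))
        stop("unknown population: ", population)
    which(pops == population)
}

# Alternate-allele frequency and non-missing diploid count per variant within
# one population.
.popFreq <- function(gt) {
    n0 <- rowSums(gt == 0L, na.rm = TRUE)
    n1 <- rowSums(gt == 1L, na.rm = TRUE)
    n2 <- rowSums(gt == 2L, na.rm = TRUE)
    nm <- n0 + n1 + n2
    p <- ifelse(nm > 0, (2 * n2 + n1) / (2 * nm), NA_real_)
    list(p = p, n = nm, n0 = n0, n1 = n1, n2 = n2)
}

#' Observed heterozygosity per individual
#'
#' For each individual, the fraction of its non-missing calls that are
#' heterozygous.
#'
#' @param cohort A [GenotypeCohort-class].
#' @return `data.frame` with columns `individual`, `population`, `ho`.
#' @export
observedHeterozygosity <- function(cohort) {
    gt <- assay(cohort, "GT")
    nonMiss <- colSums(!is.na(gt))
    if (any(nonMiss == 0))
        stop("individual(s) with no non-missing calls: ",
             paste(colnames(gt)[nonMiss == 0], collapse = ", "))
    ho <- colSums(gt == 1L, na.rm = TRUE) / nonMiss
    data.frame(individual = colnames(gt),
               population = colData(cohort)$population,
               ho = unname(ho), stringsAsFactors = FALSE)
}

#' Expected heterozygosity per variant within a population
#'
#' He = 2p(1-p) with p estimated from the population's non-missing calls (no
#' small-sample correction; this mirrors how He is conventionally summarised
#' at the population level).
#'
#' @param cohort A [GenotypeCohort-class].
#' @param population Population label.
#' @return Numeric vector, one value per variant; NA where the population has
#'   no non-missing call.
#' @export
expectedHeterozygosity <- function(cohort, population) {
    cols <- .popColumns(cohort, population)
    if (length(cols) < 2L)
        stop("population must contain at least two individuals")
    f <- .popFreq(assay(cohort, "GT")[, cols, drop = FALSE])
    unname(2 * f$p * (1 - f$p))
}

#' Sites polymorphic within a population
#'
#' @param cohort A [GenotypeCohort-class].
#' @param population Population label.
#' @return Logical vector: TRUE where both alleles are observed at least once
#'   among the population's non-missing calls.
#' @export
polymorphicSites <- function(cohort, population) {
    cols <- .popColumns(cohort, population)
    f <- .popFreq(assay(cohort, "GT")[, cols, drop = FALSE])
    ref <- 2 * f$n0 + f$n1
    alt <- 2 * f$n2 + f$n1
    ref > 0 & alt > 0
}

#' Polymorphic marker ratio (PN)
#'
#' Mean over a population's individuals of the percentage of that
#' population's polymorphic sites at which the individual has a non-missing
#' call. This operational definition (a completeness measure over polymorphic
#' loci) is the default; see the methods vignette for the distinction from
#' the literal "proportion of polymorphic loci" reading, available as
#' [polymorphicSites()].
#'
#' @param cohort A [GenotypeCohort-class].
#' @param population Population label.
#' @return List with `perIndividual` (named percentages), `mean` and `sd`.
#' @export
polymorphicRatio <- function(cohort, population) {
    cols <- .popColumns(cohort, population)
    poly <- polymorphicSites(cohort, population)
    if (!any(poly)) stop("no polymorphic sites in population ", population)
    sub <- assay(cohort, "GT")[poly, cols, drop = FALSE]
    pn <- colSums(!is.na(sub)) / sum(poly) * 100
    list(perIndividual = pn, mean = mean(pn), sd = sd(pn))
}

#' Wright's inbreeding coefficient (Fis) per individual
#'
#' For individual i with L non-missing calls, O observed homozygous calls and
#' expected homozygous count E = sum over its non-missing variants of
#' `1 - 2p(1-p) * 2n/(2n-1)` (method-of-moments expectation with the
#' small-sample correction, n being the population's non-missing diploid
#' count at the variant):
#' \deqn{F_{is} = (O - E) / (L - E)}
#' Negative values indicate heterozygote excess. Individuals with L = E
#' (undefined ratio) are reported as NA with a warning. Monomorphic variants
#' contribute identically to O, E and L and therefore cancel from the
#' statistic.
#'
#' @param cohort A [GenotypeCohort-class].
#' @param population Population label; `NULL` (default) computes every
#'   population in turn.
#' @return `data.frame` with columns `individual`, `population`, `fis`.
#' @export
wrightFis <- function(cohort, population = NULL) {
    if (is.null(population)) {
        out <- lapply(levels(colData(cohort)$population),
                      function(p) wrightFis(cohort, p))
        return(do.call(rbind, out))
    }
    cols <- .popColumns(cohort, population)
    gt <- assay(cohort, "GT")[, cols, drop = FALSE]
    f <- .popFreq(gt)
    usable <- f$n > 0
    eHomVar <- 1 - 2 * f$p * (1 - f$p) * (2 * f$n) / (2 * f$n - 1)
    fis <- vapply(seq_len(ncol(gt)), function(j) {
        idx <- !is.na(gt[, j]) & usable
        L <- sum(idx)
        O <- sum(gt[idx, j] != 1L)
        E <- sum(eHomVar[idx])
        if (abs(L - E) < 1e-12) return(NA_real_)
        (O - E) / (L - E)
    }, numeric(1))
    if (anyNA(fis))
        warning("Fis undefined (L = E) for: ",
                paste(colnames(gt)[is.na(fis)], collapse = ", "))
    data.frame(individual = colnames(gt), population = population,
               fis = fis, stringsAsFactors = FALSE)
}

#' Per-population diversity summary table
#'
#' One row per population with the number of individuals (N), number of
#' polymorphic sites within the population (NOPS), observed heterozygosity
#' (mean and SD over individuals), expected heterozygosity (mean and SD over
#' variants), the polymorphic marker ratio PN (percent, mean and SD over
#' individuals) and Wright's Fis (mean, maximum, minimum over individuals).
#' Ho, He and PN are computed over the sites polymorphic within each
#' population, matching how per-population marker panels are conventionally
#' summarised; Fis is unaffected by this restriction because monomorphic
#' sites cancel from it.
#'
#' @param cohort A [GenotypeCohort-class].
#' @return `data.frame`, one row per population.
#' @export
diversitySummary <- function(cohort) {
    pops <- levels(colData(cohort)$population)
    rows <- lapply(pops, function(pop) {
        cols <- .popColumns(cohort, pop)
        poly <- polymorphicSites(cohort, pop)
        sub <- cohort[poly, cols]
        hoI <- observedHeterozygosity(sub)$ho
        he <- expectedHeterozygosity(sub, pop)
        pn <- polymorphicRatio(cohort, pop)
        fis <- wrightFis(cohort, pop)$fis
        data.frame(population = pop, n = length(cols),
                   n_polymorphic = sum(poly),
                   ho_mean = mean(hoI), ho_sd = sd(hoI),
                   he_mean = mean(he, na.rm = TRUE),
                   he_sd = sd(he, na.rm = TRUE),
                   pn_mean = pn$mean, pn_sd = pn$sd,
                   fis_mean = mean(fis, na.rm = TRUE),
                   fis_max = max(fis, na.rm = TRUE),
                   fis_min = min(fis, na.rm = TRUE),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
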