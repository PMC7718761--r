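# Variant quality control: minor-allele presence, per-variant call rate, and
# within-population exact Hardy-Weinberg filtering.

#' Filter variants on polymorphism, call rate and Hardy-Weinberg equilibrium
#'
#' Applies three filters in order, counting each removed variant once under
#' the first rule that applies:
#' \enumerate{
#'   \item monomorphic: fewer than one copy of the minor allele among all
#'     non-missing calls;
#'   \item call rate: fraction of non-missing calls below `minCallrate`
#'     (default 0.1, a permissive floor appropriate for sequence-derived
#'     panels);
#'   \item Hardy-Weinberg: exact-test p-value below `hweAlpha` (default 1e-6)
#'     in \emph{any} single population. Testing within populations rather
#'     than on the pooled cohort avoids wholesale rejection through the
#'     Wahlund effect when diverged populations are mixed.
#' }
#'
#' @param cohort A [GenotypeCohort-class].
#' @param minCallrate Per-variant call-rate floor in \[0, 1\].
#' @param hweAlpha Hardy-Weinberg rejection threshold.
#' @return List with `cohort` (the filtered [GenotypeCohort-class]) and
#'   `report` (a [QCReport-class]; its genotyping rate is the non-missing
#'   fraction of the retained matrix).
#' @export
filterVariants <- function(cohort, minCallrate = 0.1, hweAlpha = 1e-6) {
    stopifnot(is(cohort, "GenotypeCohort"),
              minCallrate >= 0, minCallrate <= 1, hweAlpha >= 0)
    gt <- assay(cohort, "GT")
    nInd <- ncol(gt)
    n0 <- rowSums(gt == 0L, na.rm = TRUE)
    n1 <- rowSums(gt == 1L, na.rm = TRUE)
    n2 <- rowSums(gt == 2L, na.rm = TRUE)
    nonMiss <- n0 + n1 + n2

    refCopies <- 2 * n0 + n1
    altCopies <- 2 * n2 + n1
    mono <- pmin(refCopies, altCopies) == 0
    lowcall <- !mono & (nonMiss / nInd) < minCallrate

    remain <- !mono & !lowcall
    hweFail <- rep(FALSE, nrow(gt))
    pops <- colData(cohort)$population
    for (pop in levels(pops)) {
        sub <- gt[remain, pops == pop, drop = FALSE]
        if (!ncol(sub)) next
        pv <- .hweVec(rowSums(sub == 0L, na.rm = TRUE),
                      rowSums(sub == 1L, na.rm = TRUE),
                      rowSums(sub == 2L, na.rm = TRUE))
        hweFail[remain] <- hweFail[remain] | (!is.na(pv) & pv < hweAlpha)
    }
    keep <- remain & !hweFail

    rate <- if (any(keep)) mean(!is.na(gt[keep, , drop = FALSE])) else NA_real_
    report <- new("QCReport",
                  nInput = nrow(gt),
                  nRemovedMonomorphic = as.integer(sum(mono)),
                  nRemovedCallrate = as.integer(sum(lowcall)),
                  nRemovedHWE = as.integer(sum(hweFail)),
                  nRetained = as.integer(sum(keep)),
                  genotypingRate = rate)
    if (!any(keep))
        message("no variants survive QC")
    list(cohort = cohort[keep, ], report = report)
}

#' QC report as a one-row data frame
#'
#' @param report A [QCReport-class].
#' @return `data.frame` with the input/removed/retained counts and the
#'   genotyping rate, suitable for TSV export.
#' @export
qcReportTable <- function(report) {
    data.frame(n_input = report@nInput,
               n_removed_monomorphic = report@nRemovedMonomorphic,
               n_removed_callrate = report@nRemovedCallrate,
               n_removed_hwe = report@nRemovedHWE,
               n_retained = report@nRetained,
               genotyping_rate = report@genotypingRate)
}
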