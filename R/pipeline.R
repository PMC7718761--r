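# End-to-end orchestration: simulate (or read) -> QC -> diversity -> ROH ->
# length/FROH/coverage summaries -> islands -> interval overlaps, writing a
# TSV report bundle plus a parameter log. All outputs are deterministic for a
# given configuration.

.cfgGet <- function(cfg, key, default) {
    if (!is.null(cfg[[key]])) cfg[[key]] else default
}

.buildLayout <- function(simCfg) {
    if (is.null(simCfg$layout)) return(genomeLayout())
    ly <- simCfg$layout
    chroms <- if (is.null(ly$chromosomes)) {
        genomeLayout()@chromosomes
    } else {
        do.call(rbind, lapply(ly$chromosomes, function(ch)
            data.frame(chrom = ch$chrom, length = as.numeric(ch$length))))
    }
    genomeLayout(chroms, .cfgGet(ly, "snp_density", 1 / 5000))
}

.buildProfiles <- function(simCfg) {
    if (is.null(simCfg$populations)) return(deskCohortProfiles())
    lapply(simCfg$populations, function(pc) {
        populationProfile(
            name = pc$name,
            nIndividuals = pc$n_individuals,
            targetHet = pc$target_het,
            missingRate = .cfgGet(pc, "missing_rate", 0),
            withinTractHetRate = .cfgGet(pc, "within_tract_het_rate", 0),
            tracts = tractMix(unlist(.cfgGet(pc, "tract_counts",
                                             rep(0, 7)))))
    })
}

.buildScanParams <- function(cfg) {
    sc <- .cfgGet(cfg, "scan", list())
    scanParams(
        windowSnps = .cfgGet(sc, "window_snps", 50L),
        windowMaxHet = .cfgGet(sc, "window_max_het", 3L),
        windowMaxMissing = .cfgGet(sc, "window_max_missing", 5L),
        hitProportion = .cfgGet(sc, "hit_proportion", 0.05),
        minSnps = .cfgGet(sc, "min_snps", 50L),
        minLengthKb = .cfgGet(sc, "min_length_kb", 300),
        maxGapKb = .cfgGet(sc, "max_gap_kb", 1000),
        minDensityKbPerSnp = .cfgGet(sc, "min_density_kb_per_snp", 50))
}

.writeTsv <- function(df, dir, name) {
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
}

#' Run the full ROH analysis pipeline
#'
#' Input is either a simulation block (genome layout, population profiles and
#' a seed) or paths to a VCF, a sample-to-population map and a
#' chromosome-length table -- exactly one of the two. The pipeline applies
#' variant QC, computes the diversity summary, scans for ROH, summarises
#' segments by length class, individual, FROH and chromosome coverage,
#' calls ROH islands per population, and intersects islands between all
#' population pairs and against any annotation interval files. Every table
#' is written as TSV into `outdir`, together with a `run_log.txt` recording
#' all parameters; rerunning with the same configuration reproduces the
#' bundle byte for byte.
#'
#' @param config Configuration list, or the path to a YAML file with the
#'   same structure (see the package vignette for the schema).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the intermediate objects: `cohort`, `truth`
#'   (simulation only), `qc`, `diversity`, `rohset`, `lengthClasses`,
#'   `perIndividual`, `froh`, `coverage`, `islands`, `thresholds`,
#'   `overlaps`.
#' @export
runPipeline <- function(config, outdir) {
    if (is.character(config)) config <- read_yaml(config)
    hasSim <- !is.null(config$simulation)
    hasInput <- !is.null(config$input)
    if (hasSim == hasInput)
        stop("config must contain exactly one of 'simulation' or 'input'")
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    log <- character(0)
    say <- function(...) {
        line <- sprintf(...)
        message(line)
        log <<- c(log, line)
    }

    truth <- NULL
    if (hasSim) {
        layout <- .buildLayout(config$simulation)
        profiles <- .buildProfiles(config$simulation)
        seed <- .cfgGet(config$simulation, "seed", 1L)
        say("stage simulate: seed %d, %d chromosomes, %d populations",
            as.integer(seed), nrow(layout@chromosomes), length(profiles))
        sim <- simulateCohort(layout, profiles, seed = seed)
        cohort <- sim$cohort
        truth <- sim$truth
        writeCohortVCF(cohort, file.path(outdir, "cohort.vcf"))
        writeChromosomeTable(layout, file.path(outdir, "chromosomes.tsv"))
        writeTractsBED(truth, file.path(outdir, "truth_tracts.bed"))
        .writeTsv(data.frame(sample = colnames(cohort),
                             population = colData(cohort)$population),
                  outdir, "population_map.tsv")
        chromLens <- setNames(layout@chromosomes$length,
                              layout@chromosomes$chrom)
    } else {
        inp <- config$input
        for (f in c("vcf", "population_map", "chrom_lengths"))
            if (is.null(inp[[f]]) || !file.exists(inp[[f]]))
                stop("input file missing or not found: ", f)
        say("stage read: %s", inp$vcf)
        cohort <- readGenotypes(inp$vcf, inp$population_map)
        chromLens <- readChromosomeTable(inp$chrom_lengths)
    }
    say("stage input: %d variants x %d individuals", nrow(cohort),
        ncol(cohort))

    qcCfg <- .cfgGet(config, "qc", list())
    qc <- filterVariants(cohort,
                         minCallrate = .cfgGet(qcCfg, "min_callrate", 0.1),
                         hweAlpha = .cfgGet(qcCfg, "hwe_alpha", 1e-6))
    cohort <- qc$cohort
    say("stage qc: %d in, %d monomorphic, %d low call rate, %d HWE, %d retained",
        qc$report@nInput, qc$report@nRemovedMonomorphic,
        qc$report@nRemovedCallrate, qc$report@nRemovedHWE,
        qc$report@nRetained)
    .writeTsv(qcReportTable(qc$report), outdir, "qc_report.tsv")

    div <- diversitySummary(cohort)
    .writeTsv(div, outdir, "diversity.tsv")
    say("stage diversity: %d populations summarised", nrow(div))

    params <- .buildScanParams(config)
    rohset <- suppressMessages(scanCohort(cohort, params))
    say("stage roh: %d segments", length(rohSegments(rohset)))
    .writeTsv(rohSegmentTable(rohset), outdir, "roh_segments.tsv")
    writeROHBed(rohset, file.path(outdir, "roh_segments.bed"))

    lc <- classifyLengths(rohset)
    .writeTsv(lc$byClass, outdir, "roh_length_classes.tsv")
    .writeTsv(lc$totals, outdir, "roh_length_totals.tsv")
    perInd <- perIndividualSummary(rohset)
    .writeTsv(perInd, outdir, "roh_per_individual.tsv")

    genomeSize <- .cfgGet(config, "genome_size_bp", sum(chromLens))
    froh <- fROH(rohset, genomeSizeBp = genomeSize)
    .writeTsv(froh, outdir, "froh_individual.tsv")
    .writeTsv(frohSummary(froh), outdir, "froh_summary.tsv")
    say("stage froh: genome size %.0f bp", genomeSize)

    cov <- chromosomeCoverage(rohset, chromLens)
    .writeTsv(cov, outdir, "chromosome_coverage.tsv")

    isCfg <- .cfgGet(config, "islands", list())
    topFraction <- .cfgGet(isCfg, "top_fraction", 0.01)
    islandGap <- .cfgGet(isCfg, "max_gap_kb", 1000)
    islandMinSnps <- .cfgGet(isCfg, "min_snps", 2L)
    pops <- levels(colData(cohort)$population)
    islands <- list()
    thresholds <- numeric(0)
    for (pop in pops) {
        track <- snpIncidence(rohset, cohort, pop)
        thr <- withCallingHandlers(
            islandThreshold(track, topFraction),
            warning = function(w) invokeRestart("muffleWarning"))
        isl <- callIslands(track, thr, maxGapKb = islandGap,
                           minSnps = islandMinSnps)
        islands[[pop]] <- isl
        thresholds[pop] <- thr
        say("stage islands: %s threshold %.3f, %d islands", pop, thr,
            length(isl))
    }
    islTab <- do.call(rbind, lapply(pops, function(pop)
        islandTable(islands[[pop]], pop)))
    .writeTsv(islTab, outdir, "islands.tsv")
    bed <- islTab[, c("chrom", "start", "end", "population")]
    bed$start <- bed$start - 1L
    write.table(bed, file.path(outdir, "islands.bed"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)

    overlaps <- list()
    if (length(pops) > 1L) {
        for (i in seq_len(length(pops) - 1L)) {
            for (j in (i + 1L):length(pops)) {
                ab <- intersectIntervals(islands[[pops[i]]],
                                         islands[[pops[j]]])
                if (nrow(ab)) {
                    ab$group_a <- pops[i]
                    ab$group_b <- pops[j]
                    overlaps[[length(overlaps) + 1L]] <- ab
                }
            }
        }
    }
    annPaths <- .cfgGet(config, "annotations", character(0))
    for (ap in unlist(annPaths)) {
        ann <- readIntervals(ap)
        for (pop in pops) {
            ab <- intersectIntervals(islands[[pop]], ann)
            if (nrow(ab)) {
                ab$group_a <- pop
                ab$group_b <- basename(ap)
                overlaps[[length(overlaps) + 1L]] <- ab
            }
        }
    }
    ovTab <- if (length(overlaps)) do.call(rbind, overlaps) else
        data.frame(aIndex = integer(0), bIndex = integer(0),
                   aLabel = character(0), bLabel = character(0),
                   chrom = character(0), overlapBp = integer(0),
                   group_a = character(0), group_b = character(0))
    .writeTsv(ovTab, outdir, "island_overlaps.tsv")
    say("stage overlap: %d overlapping pairs", nrow(ovTab))

    log <- c(log,
             sprintf("param scan: %s",
                     paste(names(params), vapply(params, function(v)
                         if (is.null(v)) "NULL" else as.character(v),
                         character(1)), sep = "=", collapse = " ")),
             sprintf("param islands: top_fraction=%g max_gap_kb=%g min_snps=%d",
                     topFraction, islandGap, as.integer(islandMinSnps)),
             sprintf("param genome_size_bp: %.0f", genomeSize))
    writeLines(log, file.path(outdir, "run_log.txt"))

    invisible(list(cohort = cohort, truth = truth, qc = qc$report,
                   diversity = div, rohset = rohset, lengthClasses = lc,
                   perIndividual = perInd, froh = froh, coverage = cov,
                   islands = islands, thresholds = thresholds,
                   overlaps = ovTab))
}
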