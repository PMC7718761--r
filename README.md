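# rohscan

Runs of homozygosity (ROH), genomic inbreeding and ROH islands from diploid
biallelic SNP genotypes.

A run of homozygosity is a contiguous stretch of a diploid genome carrying
identical alleles at every (or nearly every) genotyped site. Long runs mark
autozygosity — both chromosome copies inherited from a recent common
ancestor — so the fraction of the genome under ROH,

    F_ROH = L_ROH / L_total,

is a pedigree-free inbreeding coefficient, and regions where runs pile up
across the individuals of a population ("ROH islands") are candidate
selection sweeps. The package is aimed at population and livestock
geneticists working with multi-population SNP cohorts (the motivating
setting is whole-genome chicken data contrasting commercial layers and
broilers with wild junglefowl), and implements:

* **QC** — minor-allele presence, per-variant call rate (< 0.1 floor), and a
  two-sided exact Hardy–Weinberg test (p < 1e-6, applied within each
  population) — `readGenotypes()`, `filterVariants()`, `hweExactTest()`;
* **diversity & Wright's F_is** — observed/expected heterozygosity,
  polymorphic marker ratio, and
  `F_is = (O - E) / (L - E)` per individual with the small-sample-corrected
  expected homozygosity — `diversitySummary()`, `wrightFis()`;
* **ROH detection** — the sliding-window scan with the standard
  seven-criterion parameterisation (50-SNP windows, ≤ 3 het / ≤ 5 missing
  per window, 0.05 hit-rate floor, ≥ 50 SNPs, ≥ 300 kb, ≤ 1 Mb gaps,
  ≥ 1 SNP / 50 kb) — `scanCohort()`, `callROH()`, `scanParams()`;
* **summaries** — the seven length classes (0.3–1 … > 16 Mb), per-individual
  burden, per-chromosome coverage, and `F_ROH` overall and per class
  (default `L_total` = 931 Mb, the chicken autosomal genome) — `fROH()`,
  `classifyLengths()`, `chromosomeCoverage()`;
* **islands** — per-SNP ROH incidence, population-specific top-1% thresholds
  (nearest-rank quantile), island calling, and interval intersection against
  QTL/annotation BEDs or other populations' islands — `snpIncidence()`,
  `islandThreshold()`, `callIslands()`, `intersectIntervals()`;
* **simulation** — multi-population cohorts with Beta-calibrated allele
  frequencies and planted autozygous tracts as ground truth —
  `simulateCohort()`, `deskCohortProfiles()`;
* **pipeline** — `runPipeline()` composes all stages from one YAML/list
  configuration into a deterministic TSV report bundle (a thin CLI wrapper
  ships in `inst/scripts/run_pipeline.R`).

## Worked example

```r
library(rohscan)

# a small simulated two-population cohort with planted autozygous tracts
sim <- simulateCohort(
  genomeLayout(data.frame(chrom = c("chr1", "chr2"), length = c(10e6, 5e6))),
  list(populationProfile("A", 10, 0.28, tracts = tractMix(c(2, 1, 0.5, 0, 0, 0, 0))),
       populationProfile("B",  8, 0.24)),
  seed = 7)

qc <- filterVariants(sim$cohort)
qc$report
#> Variant QC report
#>   input:              3000
#>   removed monomorphic:98
#>   removed call rate:  0
#>   removed HWE:        0
#>   retained:           2902
#>   genotyping rate:    1.0000

roh <- scanCohort(qc$cohort)
roh
#> ROHSet: 29 segments across 18 individuals
#> segments per population: A=29
#> length range: 0.39-3.74 Mb

classifyLengths(roh)$totals
#>   population total_n mean_n total_length_mb   max_mb   min_mb
#> A          A      29    2.9        37.99412 3.736763 0.389028
#> B          B       0    0.0         0.00000       NA       NA
```

Population A (simulated with ~3.5 planted tracts per individual) yields 29
segments between 0.39 and 3.74 Mb — about 2.9 runs per individual covering
38 Mb in total — while population B, simulated without tracts, produces
none: at these marker densities chance homozygosity almost never satisfies
the 50-SNP / 300-kb / density criteria simultaneously. `fROH(roh,
genomeSizeBp = 15e6)` then converts each individual's summed segment length
into its genomic inbreeding coefficient, and `snpIncidence()` +
`islandThreshold()` + `callIslands()` locate the regions shared across
population A's individuals.

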