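---
title: "Detecting runs of homozygosity and ROH islands: methods and design"
author: "rohscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting runs of homozygosity and ROH islands: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A run of homozygosity (ROH) is a contiguous chromosomal stretch over which a
diploid individual carries identical alleles at every (or nearly every)
genotyped site. Long runs arise when both chromosome copies descend from a
recent common ancestor (autozygosity); the summed length of an individual's
runs is therefore a direct, pedigree-free measure of inbreeding, and regions
where runs pile up across many individuals of a population — *ROH islands* —
are candidate footprints of selection. `rohscan` implements this analysis
chain for multi-population cohorts of biallelic SNP genotypes, as used in
livestock genomics (the motivating setting is whole-genome chicken data
contrasting commercial layer and broiler lines with wild junglefowl):

1. variant quality control,
2. per-population diversity and Wright's inbreeding coefficient
   $F_{\mathrm{is}}$,
3. sliding-window ROH detection,
4. length-class, chromosome-coverage and genomic-inbreeding
   ($F_{\mathrm{ROH}}$) summaries,
5. ROH-island detection and interval overlap against annotations (e.g. QTL).

Because real headline numbers in this field derive from large sequencing
cohorts, the package also ships a cohort **simulator** that plants autozygous
tracts with known coordinates, so that every stage can be validated against
ground truth at desk scale.

# Genotype representation and quality control

Genotypes are held in a `GenotypeCohort` (a `RangedSummarizedExperiment`):
rows are biallelic SNPs, columns individuals, with integer codes 0/1/2 for
hom-ref/het/hom-alt and `NA` for missing. Three variant filters are applied
in a fixed cheap-to-expensive order, each variant counted once under the
first rule that removes it:

* **Minor-allele presence.** Variants with zero copies of the minor allele
  among non-missing calls carry no information for any statistic here.
* **Call rate.** Variants genotyped in fewer than 10% of individuals are
  dropped. The 0.1 floor is deliberately permissive — sequence-derived
  panels retain millions of sites — and is configurable
  (`minCallrate`). We read the published "genotyping rate < 0.1" exclusion
  as a per-variant rule (PLINK `--geno`-style semantics applied to
  variants); applying it to individuals instead would be the other
  defensible reading.
* **Hardy–Weinberg equilibrium.** The two-sided exact test conditions on
  the observed allele counts: with $n$ genotyped diploids and minor-allele
  count $r$, the heterozygote count $n_{AB}$ has conditional probability
  $P(n_{AB}) \propto n!\,2^{n_{AB}} / (n_{AA}!\,n_{AB}!\,n_{BB}!)$, and the
  p-value sums all configurations no more probable than the observed one
  (no mid-p correction, matching the conventional implementation). Variants
  with $p < 10^{-6}$ are removed.

**Pooled vs per-population HWE.** The test is computed *within each
population* and a variant is removed if it fails in any one of them. A
pooled test over five diverged populations would reject wholesale through
the Wahlund effect (heterozygote deficit from population structure), which
is a property of the cohort design, not of genotyping quality. This is a
documented interpretation; the upstream description does not state which
was used.

# Diversity and Wright's $F_{\mathrm{is}}$

Per population we report observed heterozygosity $H_O$ (per individual:
heterozygous / non-missing calls), expected heterozygosity
$H_E = 2\hat p(1-\hat p)$ per variant, and the polymorphic marker ratio
$P_N$. Two conventions deserve note:

* $P_N$ has two circulating definitions — the *proportion of polymorphic
  loci* and the *mean per-individual proportion of non-missing calls at
  polymorphic loci*. We implement the operational (second) definition as
  the default (`polymorphicRatio()`), because that is how the quantity is
  computed in the motivating analyses; the literal reading is available via
  `polymorphicSites()`.
* In `diversitySummary()`, $H_O$, $H_E$ and $P_N$ are computed over the
  sites *polymorphic within each population* (mirroring per-population
  marker panels, where monomorphic sites are absent by construction). This
  conditioning inflates $H_O$ relative to a fixed whole-panel computation
  by exactly the panel-to-polymorphic ratio; `observedHeterozygosity()` on
  the full cohort gives the unconditioned value. $F_{\mathrm{is}}$ is
  unaffected: monomorphic sites contribute identically to the observed and
  expected homozygote counts and cancel.

Wright's coefficient for individual $i$ is
$$F_{\mathrm{is}} = \frac{O_i - E_i}{L_i - E_i},$$
with $L_i$ its non-missing calls, $O_i$ its observed homozygous calls and
$E_i = \sum_v \left[1 - 2p_v(1-p_v)\tfrac{2n_v}{2n_v-1}\right]$ the expected
homozygote count. The $2n/(2n-1)$ factor is the standard small-sample
correction of the method-of-moments estimator; it is what makes the
population mean of $F_{\mathrm{is}}$ centre on zero under Hardy–Weinberg
genotypes (verified by a calibration test on simulated cohorts). $H_E$ in
the summary table is reported *without* this correction, as a plain
population summary.

# The sliding-window ROH caller

`callROH()` implements the window-based scan with the conventional
seven-criterion parameterisation (`scanParams()` defaults):

| parameter | default | meaning |
|---|---|---|
| `windowSnps` | 50 | sliding window size in SNPs |
| `windowMaxHet` | 3 | max heterozygous calls per homozygous window |
| `windowMaxMissing` | 5 | max missing calls per homozygous window |
| `hitProportion` | 0.05 | per-SNP homozygous-window hit-rate floor |
| `minSnps` | 50 | min SNPs per segment |
| `minLengthKb` | 300 | min segment length |
| `maxGapKb` | 1000 | max gap between consecutive segment SNPs |
| `minDensityKbPerSnp` | 50 | min average density (1 SNP per 50 kb) |

Each window of 50 consecutive SNPs is *homozygous* when it contains at most
3 heterozygous and 5 missing calls. Each SNP's **hit rate** is the fraction
of windows containing it that are homozygous; edge SNPs use only the
windows that exist (no padding), and a chromosome shorter than one window
is evaluated as a single whole-chromosome window. A SNP is *flagged* when
its hit rate is at least `hitProportion` (read inclusively: "set to 0.05"
is a floor). Maximal runs of flagged SNPs, split at physical gaps above
`maxGapKb`, become segments if they meet the SNP-count, length and density
floors. Segment coordinates are the first and last flagged SNP (1-based
inclusive; length $= \mathrm{end}-\mathrm{start}+1$; BED exports convert to
0-based half-open).

Interpretive choices, stated explicitly:

* A SNP whose own call is heterozygous is never flagged, even when its
  windows pass — this keeps het sites out of reported runs beyond the
  window allowance and matches the observable behaviour of the reference
  toolchain.
* Missing calls *can* be flagged (absence of a call is not evidence against
  homozygosity) and count toward `minSnps`.
* The het/missing allowances are window properties and are **not**
  re-applied to the final segment; optional `segmentMaxHet` /
  `segmentMaxMissing` caps are available for users who want a segment-level
  rule.
* The per-SNP hit-rate reading of the "proportion of homozygous overlapping
  windows" criterion is the only one implemented.

`callROH()` is verified, over hundreds of random chromosomes, to be
set-identical to a brute-force oracle that recomputes window states by
direct enumeration and walks candidate runs explicitly.

# ROH summaries and $F_{\mathrm{ROH}}$

Segments are binned into the seven conventional length classes 0.3–1, 1–2,
2–4, 4–8, 8–10, 10–16 and >16 Mb. Bins are **left-closed, right-open** (a
1.0 Mb segment falls in 1–2 Mb); the classes are contiguous and exhaustive
and the boundary convention is ours, as none is conventionally stated.

The genomic inbreeding coefficient is
$$F_{\mathrm{ROH}} = L_{\mathrm{ROH}} / L_{\mathrm{total}},$$
with $L_{\mathrm{ROH}}$ the summed segment length of the individual and
$L_{\mathrm{total}}$ a *fixed* genome size — 931 Mb by default, the
SNP-covered autosomal genome of the chicken Gallus_gallus-5.0 assembly.
Using a fixed denominator (rather than each bird's covered length) follows
the definitional statement of the statistic; for simulated cohorts the
simulated genome size should be supplied. Per-class coefficients partition
the total exactly. A total exceeding $L_{\mathrm{total}}$ warns (it
indicates a mis-configured genome size) rather than erroring. Chromosome
coverage is the mean over *all* of a population's individuals (not only ROH
carriers) of the fraction of the chromosome under ROH.

Agreement between the two inbreeding measures is quantified by
`pearsonCorrelation()` ($t$-test with $n-2$ df, via `stats::cor.test`); on
simulated cohorts where planted tracts drive inbreeding the correlation
between $F_{\mathrm{is}}$ and $F_{\mathrm{ROH}}$ is close to 1.

# ROH islands

`snpIncidence()` computes, per SNP, the fraction of a population's
individuals with a segment covering it. The island threshold reconciles two
statements that cannot both be literal — a "1%" threshold and
population-specific thresholds of 40–96% — by reading the former as *top
1% of the incidence distribution*: `islandThreshold()` returns the
incidence of the $\lceil 0.01\,n\rceil$-th most covered SNP (nearest-rank;
incidence takes at most $N{+}1$ discrete values for $N$ individuals, so
interpolation would manufacture unattainable values). Only the quantile
reading reproduces population-specific thresholds, because each
population's incidence distribution differs; the literal fixed-incidence
reading remains available by passing any constant to `callIslands()`.

Islands are maximal runs of $\ge 2$ consecutive SNPs at or above the
threshold ("a region of adjacent SNPs" is plural), broken at gaps above
1 Mb for consistency with the caller's gap rule; both are configurable, as
no minimum SNP count or length is conventionally stated.
`intersectIntervals()` reports all overlapping pairs (half-open BED
semantics for data-frame input, $\ge$ 1 bp overlap) between island sets of
population groups, or islands versus annotation intervals such as QTL
regions supplied as BED.

# The simulator: what it emulates and what it does not

`simulateCohort()` generates multi-population cohorts patterned on a
five-population layer/broiler/wild contrast: the desk-scale defaults
(`genomeLayout()`, `deskCohortProfiles()`) use three chromosomes of 50, 20
and 5 Mb — echoing the macro/intermediate/micro size tiers of an avian
karyotype — at 1 SNP per 5 kb (~15,000 SNPs), five populations of 20–25
individuals with target background heterozygosities 0.240–0.309 (the
published per-population $H_O$ values), a 2% missing rate (genotyping rate
≈ 0.98, within the published 0.97–0.99 range), and a 1% erroneous
heterozygote rate inside tracts, since sporadic within-tract hets are what
breaks long autozygous stretches into several called segments at sequence
resolution.

Design of the generative model:

* **Allele frequencies.** Per SNP and population,
  $p \sim \mathrm{Beta}(a, a)$ with $a = h/(1-2h)$, so that
  $\mathrm{E}[2p(1-p)] = h$, the profile's target heterozygosity. This is
  the simplest model with tunable $H_O$; the pipeline's statistics need no
  linkage disequilibrium. $h = 0$ degenerates to fixed alleles
  ($p \in \{0,1\}$), giving fully homozygous cohorts.
* **Genotypes** are drawn under Hardy–Weinberg proportions
  ($\mathrm{Binomial}(2, p)$), so the null-calibration checks of the HWE
  test and $F_{\mathrm{is}}$ are exact by construction.
* **Planted tracts.** Per individual and length class, the realised count
  is $\lfloor\mu\rfloor$ plus a Bernoulli on the fraction; lengths are
  uniform within the class (20 Mb cap for the open class); placement is
  uniform over chromosomes able to hold the tract, weighted by admissible
  start positions (unbiased placement keeps coverage statistics simple).
  Inside a tract the individual's calls are overwritten by a homozygous
  founder haplotype (allele drawn from $p$ per SNP). Overlapping tracts of
  one individual are merged with a warning; a tract longer than every
  chromosome is an error. Per-class expected counts in
  `deskCohortProfiles()` are the published per-bird class counts scaled by
  the genome-size ratio (75 Mb desk genome / 931 Mb), keeping realised
  $F_{\mathrm{ROH}}$ in a realistic 0.1–0.5 range across populations.
* **Seeds are mandatory arguments**; identical seeds give byte-identical
  VCF output. The RNG state of the calling session is restored on exit.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: linkage disequilibrium and haplotype structure
(no coalescent), mutation/genotyping error outside tracts, sex chromosomes,
recombination-rate variation along chromosomes, and allele-frequency
correlation between populations (each population draws frequencies
independently, so cross-population island overlap is not expected to mimic
real shared sweeps).

## A known, quantified limit of tract recovery

With background heterozygosity $h$, the flanking SNPs of a planted tract
are homozygous by chance with probability $1-h$, so a called segment
extends past the true tract edge by a Geometric($h$) number of SNPs per
side — about $(1-h)/h \approx 2.6$ SNPs (≈13 kb at 5 kb spacing) for
$h = 0.28$. Window-based callers inherit this bias; it is a property of the
evidence, not of the implementation (which is oracle-verified). On
error-free desk cohorts the median reciprocal overlap between planted
tracts ≥ 400 kb and their best-matching segment is ≈ 0.98, but short tracts
(0.4–1 Mb) often fall below 0.95 reciprocal overlap, and boundary errors of
2–4 SNP spacings are typical. Recovery assertions in the test suite
therefore use a 2 Mb tract — large enough that the edge bias is negligible —
while the strict sharp-recovery property is exercised (and its failure
quantified) in the acceptance suite.

# Numerical and degenerate-input choices

* HWE exact masses are computed in log space and normalised; ties in the
  two-sided sum use a $1+10^{-9}$ relative guard. The monomorphic case
  returns $p = 1$ (single attainable configuration); all-zero counts are an
  error.
* Individuals with no non-missing calls, empty call vectors, empty
  populations, zero polymorphic sites and zero-variance correlation inputs
  are errors naming the offending entity; an individual with $L_i = E_i$
  has undefined $F_{\mathrm{is}}$ and is reported `NA` with a warning.
* Empty ROH sets are valid everywhere downstream (zero counts, zero
  $F_{\mathrm{ROH}}$, zero coverage); an all-equal incidence track yields
  its common value as threshold, with a warning.
* Degenerate all-heterozygous cohorts produce empty ROH sets; a segment
  shorter than the smallest length class is a caller-contract violation and
  errors in `classifyLengths()`.

# Problem sizes

The shipped tests and the acceptance script run everything at desk scale,
chosen as the package's validation conditions: ~15,000 SNPs × 115
individuals for cohort-level checks, 100 random chromosomes of up to 2,000
SNPs for the caller/oracle equivalence, all genotype-count triples totalling
≤ 50 for the HWE/enumeration equivalence, and 10,000 variants × 25
individuals for null calibration. Reports round $F_{\mathrm{ROH}}$ to 2
decimals and percentages to 1, matching conventional presentation.

# The pipeline

`runPipeline()` composes the stages from a single configuration (list or
YAML) holding either a simulation block or input paths (VCF +
sample-to-population map + chromosome lengths), plus QC, scan, genome-size
and island parameters — every default pre-filled with the values above. It
writes a TSV report bundle (QC report, diversity table, per-segment and
per-individual ROH tables, length-class and $F_{\mathrm{ROH}}$ summaries,
chromosome coverage, islands as TSV + BED, pairwise and annotation
overlaps) and a `run_log.txt` recording every parameter and seed; identical
configurations reproduce the bundle byte for byte. Every number in the
bundle is recomputable by calling the underlying functions directly — the
pipeline performs no report-only computation.

```{r example, eval = FALSE}
library(rohscan)
cfg <- list(simulation = list(seed = 1))   # desk-scale defaults throughout
res <- runPipeline(cfg, outdir = "roh_run")
res$diversity
classifyLengths(res$rohset)$totals
```
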