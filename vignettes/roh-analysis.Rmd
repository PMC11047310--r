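---
title: "Detecting runs of homozygosity and genomic inbreeding with rohscan"
author: "rohscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting runs of homozygosity and genomic inbreeding with rohscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
```

## The problem

A run of homozygosity (ROH) is an uninterrupted stretch of homozygous
genotypes in one diploid genome. Long runs arise when both chromosome
copies descend from a recent common ancestor (autozygosity), so the
genome fraction covered by ROHs is a direct, pedigree-free estimate of
inbreeding, and genomic regions where many individuals of a population
carry overlapping ROHs mark putative selection sweeps. rohscan
implements the complete analysis chain used in livestock resequencing
studies — typically run with PLINK's `--homozyg` machinery — as tested,
scriptable R: genotype QC, sliding-window ROH detection, length-class
and inbreeding summaries, ROH-island detection and consensus-region
selection, plus a genotype simulator with planted autozygous tracts
that makes every stage verifiable against known truth.

## Genotype model and quality control

Genotypes are diploid biallelic SNP calls on autosomes, coded 0 (hom
reference), 1 (het), 2 (hom alternate), `NA` (missing); the container
(`GenotypeMatrix`) extends `RangedSummarizedExperiment`, with variants
as rows. Half-missing diploid calls are treated as missing, phase is
ignored, and non-autosomal or multi-allelic records are dropped at
import.

`applyQC()` applies the usual resequencing-panel filters in a fixed,
logged order: samples with more than 10% missing calls, then SNPs with
more than 10% missingness, then SNPs failing an exact two-sided
Hardy–Weinberg test at p < 10^-3, then (optionally) SNPs below 5%
minor allele frequency. Two profiles are exposed because ROH detection
and population-structure analyses want different panels: `"roh"`
disables the MAF filter (rare alleles carry homozygosity signal;
removing them inflates apparent homozygosity around them), `"structure"`
keeps it.

The HWE test is the exact conditional test: given the observed allele
counts, the distribution of heterozygote counts is enumerated and the
p-value is the summed probability of all configurations no more likely
than the observed one. The test is computed on the pooled analysed
sample set. Pooling across structured populations is conservative (the
Wahlund effect depresses heterozygosity genome-wide), but it is the
common single-VCF workflow; per-population testing can be had by
subsetting the matrix and is deliberately not the default. SNPs with
no non-missing calls cannot be tested and are kept rather than
silently removed.

## The sliding-window ROH caller

Detection follows the PLINK-style two-stage logic, with all parameters
in `rohCallParams()`:

* **Window scan.** A window of `windowSnp = 50` consecutive SNPs slides
  along each sample × chromosome. A window is *homozygous* if it holds
  at most `windowHetMax = 1` heterozygote and `windowMissingMax = 5`
  missing calls. Each SNP's *hit fraction* is the proportion of
  homozygous windows among the windows containing it; only instantiated
  windows count, so SNPs near chromosome ends have denominators below
  50. A SNP is *eligible* when the fraction reaches
  `windowThreshold = 0.05`. Chromosomes shorter than one window are
  scanned with a single truncated window rather than skipped.
* **Segment assembly.** Candidate runs are maximal stretches of
  eligible SNPs, split wherever consecutive SNPs lie more than
  `maxGapKb = 500` kb apart (the split precedes all other filters, so a
  long gap always terminates a run). Runs are trimmed so both endpoints
  are non-missing homozygous calls, then kept if they hold at least
  `minSnp = 30` SNPs, span at least `minLengthKb = 200` kb and are no
  sparser than `maxDensityKbPerSnp = 30` kb per SNP.

Conventions the reference tooling leaves unstated are fixed here and
unit-tested: segment length is the inclusive span
(`end − start + 1`), `n_snps` counts every SNP between the endpoints
(including interior heterozygous/missing calls admitted by the window
rule), two runs separated by at least one ineligible SNP are never
merged, and no segment-level heterozygote cap is imposed beyond what
window eligibility admits. The whole caller is validated against a
brute-force oracle (explicit window enumeration and naive run
assembly) on hundreds of randomised instances, and every emitted
segment is re-checked by an independent validator
(`validateSegments()`).

A consequence worth knowing: a tract needs roughly one full window of
SNPs before interior windows go homozygous, so at 5 kb marker spacing
runs much below ~250 kb are systematically missed, and every called
segment loses a few SNPs of length at each end to trimming. This is
inherent to the windowed method, not an artifact of this
implementation; it is why the recovery experiments below quantify
sensitivity explicitly.

## Length classes, FROH and summaries

Segments are classed as small (< 0.3 Mb), medium (0.3–1.5 Mb, bounds
included — boundary lengths go to the middle class) and large
(> 1.5 Mb); short runs reflect ancient relatedness, long runs recent
inbreeding. `summarizeClasses()` reports per-class counts, percentage
shares, summed lengths and mean ± SD (population SD, divisor N).
`frohPerSample()` computes the genomic inbreeding coefficient

F_ROH = Σ L_ROH / L_auto,

the summed ROH length over the autosomal length covered by the panel.
`lAutoMb` defaults to 2466.19 Mb (a caprine whole-genome panel) but is
an explicit, logged parameter — set it for your own panel. The
population roll-up divides by the number of samples carrying at least
one ROH, the denominator convention of published ROH summary tables;
`classSummaryFromTotals()` and `frohFromTotals()` expose the same
arithmetic for checking printed tables directly.

## ROH islands

`rohIncidence()` computes, per SNP, the fraction of a population's
individuals whose ROH set covers the position; the denominator is all
analysed individuals, not only ROH carriers. The island threshold is
the nearest-rank top-0.1% value of the incidence track (the
`ceiling(0.001 n)`-th largest value), and islands are maximal runs of
consecutive SNPs *strictly* above it, with at least `minSnps = 2`
members (a one-SNP "contiguous string" is degenerate). Thresholds are
computed per population, matching how island panels are reported; a
global scan is a matter of pooling the samples yourself.

Two numerical consequences of the strict comparison are intentional
and tested: a constant track yields no islands, and when the top of
the incidence distribution is a plateau wider than the 0.1% tail (for
example, a tract shared identically by many individuals in a small
genome) the threshold ties with the plateau and nothing qualifies. Real
incidence tracks vary continuously near sweeps because haplotype
extents differ between carriers; the simulator's island experiment
reproduces exactly that geometry (nested tract extents around a shared
core) and uses a genome large enough (450 Mb at 0.2 SNP/kb) that the
0.1% tail exceeds the shared core's SNP count.

## Consensus regions

`poolSegments()` groups overlapping segments across individuals per
chromosome and reports each pool's consensus interval (CON, the member
intersection) and union span. The reference tool's pooling internals
are not publicly specified, so rohscan defines a deterministic greedy
rule and documents it as its own: the segment overlapped by the most
other unpooled segments seeds a pool (ties: longest, then leftmost,
then first sample ID); candidates overlapping the seed are admitted in
(start, end, sample) order whenever they intersect the running CON,
which shrinks to each admitted member; pools need at least two
members; pooling repeats until no overlapping pair remains. The rule
is permutation-invariant and every pool satisfies
CON ⊆ member ⊆ UNION by construction (both properties are asserted in
the tests). Selection then keeps pools whose CON exceeds 0.1 Mb and
whose carriers exceed 30% of the reference sample set — both strict
inequalities, and the denominator is the combined analysed animals of
the designated breeds (per-breed denominators can be had by filtering
segments per breed first).

## The synthetic-data generator

The simulator exists so that every downstream stage is testable
without external data; it emulates a post-QC resequencing panel, not
raw sequencing:

* SNP positions are uniform along each chromosome at `snpDensity`
  (default 0.1/kb; the validation experiments use 0.2–0.4/kb, stated
  below). Alternate-allele frequencies are uniform on
  `mafRange = [0.05, 0.5]`.
* Background genotypes are independent Hardy–Weinberg draws per sample.
  There is **no background linkage disequilibrium**: chance background
  ROHs are therefore rarer than in real data, and island/consensus
  experiments create sharing through tracts planted at common
  positions, since incidence rather than LD drives those statistics.
* Autozygosity is modelled by direct tract planting rather than
  pedigree or coalescent simulation — that gives exact ground truth
  and desk-scale runtime. Inside a tract each SNP becomes homozygous
  with the allele drawn by its population frequency, then heterozygote
  miscalls (`hetErrorRate`) and missingness are sprinkled.
* `designPopulation()` draws tract lengths from a small/medium/large
  mixture (defaults 0.45/0.53/0.02 by count, mirroring the class
  proportions typical of resequencing-scale ROH tables; class ranges
  0.2–0.3, 0.3–1.5 and 1.5–4 Mb) until the planted total reaches the
  target F_ROH, overshooting by at most one tract, and places them
  without overlap with uniformly broken gaps. The small class starts
  at 0.2 Mb so every planted tract is in principle callable under the
  default segment filters.
* All randomness flows from the mandatory config seed; identical
  configs give identical data.

What passing tests consequently do and do not show: recovery and
sensitivity results certify the detection machinery against exact
truth under HWE backgrounds with known error rates; they do not
certify behaviour under background LD, allele-frequency skew, batch
missingness or array-specific artifacts, which real panels have.

## Validation experiments and problem sizes

The test suite and the acceptance script re-run these experiments from
scratch (sizes chosen as sensible desk-scale designs):

* **Caller–oracle equivalence:** 500 random instances (60–300 SNPs,
  randomised parameters) must match the brute-force oracle exactly.
* **FROH recovery:** designed F_ROH ∈ {0.02, 0.05, 0.10, 0.25, 0.45},
  six samples each on a 240 Mb genome at 0.4 SNP/kb, error-free; the
  mean pipeline F_ROH must land within ±0.02 of each design with
  perfect rank ordering (the observed error is below 0.01).
* **Tract sensitivity:** 80 planted tracts of 0.5–2 Mb at 5 kb
  spacing; at least 95% of planted length must be recovered (observed:
  ~99.5%).
* **Island recovery:** a tract shared by 18/20 samples with nested
  extents must yield exactly one island over its core.
* **Consensus thresholding:** a tract planted identically in 20, 30,
  31 and 50 of 100 samples must be selected exactly when the sharing
  fraction exceeds 30%.
* **HWE exactness:** agreement with an independent enumeration oracle
  to 10^-9 for totals up to 200.
* **Printed-table arithmetic:** the bundled per-population ROH totals
  and class-count table from a published 123-animal caprine
  resequencing analysis are pushed through `frohFromTotals()` /
  `classSummaryFromTotals()` and must reproduce the published
  coefficients (0.0263–0.4780) and percentages at printed precision.

## Worked example

```{r example, eval = FALSE}
cfg <- simulationConfig(nSamples = 12,
                        chromLengths = c("1" = 1.2e7, "2" = 8e6),
                        snpDensity = 0.25, seed = 1234)
sim <- simulatePopulation(targetFroh = 0.12, cfg)
gm  <- applyQC(sim$gm, qcParams("roh"))
segs <- callROH(gm)
head(segs)
frohPerSample(segs, lAutoMb = 20, samples = sampleIDs(gm))
summarizeClasses(segs)
```

For file-based inputs the same chain is one call:
`runPipeline("config.yaml")` reads a VCF or genotype TSV plus a
population map, and writes the QC report, segment table, class
summary, per-individual and per-population F_ROH, per-population
incidence tracks and islands, and the consensus-region table into an
output directory together with a resolved copy of the configuration.

## Known limitations

* The caller is validated against this package's own specification and
  oracle, not bit-for-bit against PLINK binaries; in particular
  PLINK's undocumented end-trimming details may differ at segment
  margins.
* The pooling rule is a documented in-package definition of
  "overlapping ROH pools", not a reverse-engineering of
  `--homozyg-group` verbose output.
* No support for genotype likelihoods, phasing, X-chromosome runs, or
  HMM-based ROH callers; panels arrive as VCF or plain TSV, not binary
  PLINK filesets.
* Simulated backgrounds are LD-free (see above), so false-positive
  rates measured on simulations understate those on real dense panels.
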