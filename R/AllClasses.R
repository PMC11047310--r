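#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom stats rbinom runif setNames sd cor
#' @importFrom utils read.delim write.table head
NULL

#' GenotypeMatrix: diploid SNP genotypes with a variant map
#'
#' An S4 container for a samples x SNPs diploid genotype matrix, built on
#' \linkS4class{RangedSummarizedExperiment}. Rows are variants (with
#' chromosome, position, marker id and ref/alt alleles held in the
#' \code{rowRanges}), columns are samples. The single assay \code{"GT"}
#' holds integer genotype codes: \code{0} = homozygous reference,
#' \code{1} = heterozygous, \code{2} = homozygous alternate, \code{NA} =
#' missing. Only autosomes are admitted; positions are strictly increasing
#' within each chromosome and no two variants share a (chromosome,
#' position) pair.
#'
#' @slot .. inherits all slots from \code{RangedSummarizedExperiment}.
#' @seealso \code{\link{GenotypeMatrix}} (constructor),
#'   \code{\link{genotypeCalls}}, \code{\link{variantMap}},
#'   \code{\link{readVCF}}
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
    msg <- character(0)
    if (!"GT" %in% SummarizedExperiment::assayNames(object))
        return("assay 'GT' is required")
    gt <- SummarizedExperiment::assay(object, "GT")
    if (!is.numeric(gt))
        msg <- c(msg, "assay 'GT' must be numeric (codes 0/1/2/NA)")
    else {
        bad <- gt[!is.na(gt)]
        if (length(bad) && !all(bad %in% c(0, 1, 2)))
            msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
    }
    rr <- SummarizedExperiment::rowRanges(object)
    if (length(rr)) {
        chr <- as.character(GenomicRanges::seqnames(rr))
        if (!all(.isAutosome(chr)))
            msg <- c(msg, "all variants must lie on autosomes")
        pos <- GenomicRanges::start(rr)
        if (anyDuplicated(paste(chr, pos)))
            msg <- c(msg, "duplicate (chromosome, position) variants")
        ord <- order(match(chr, unique(chr)), pos)
        if (is.unsorted(ord) && !identical(ord, seq_along(ord)))
            msg <- c(msg, "positions must be sorted within chromosome")
        by <- split(pos, chr)
        if (any(vapply(by, is.unsorted, logical(1), strictly = TRUE)))
            msg <- c(msg, "positions must be strictly increasing within chromosome")
    }
    if (is.null(colnames(object)) && ncol(object) > 0)
        msg <- c(msg, "sample names are required")
    if (length(msg)) msg else TRUE
})

#' Quality-control parameters for SNP genotype data
#'
#' Thresholds for the marker/sample filters applied by
#' \code{\link{applyQC}}: per-sample missingness, per-SNP missingness,
#' exact Hardy-Weinberg test p-value and (optionally) minor allele
#' frequency. \code{minMAF = NA} disables the MAF filter, which is the
#' convention for ROH input panels (low-MAF markers carry homozygosity
#' signal and their removal biases run detection).
#'
#' @slot maxSampleMissing numeric(1), drop samples with missing fraction
#'   strictly above this (default 0.1).
#' @slot maxGenoMissing numeric(1), drop SNPs with missing fraction
#'   strictly above this (default 0.1).
#' @slot hwePThreshold numeric(1), drop SNPs whose exact Hardy-Weinberg
#'   p-value is strictly below this (default 1e-3).
#' @slot minMAF numeric(1) or NA, drop SNPs with minor allele frequency
#'   strictly below this; NA disables the filter.
#' @seealso \code{\link{qcParams}}, \code{\link{applyQC}}
#' @export
setClass("QCParams", representation(
    maxSampleMissing = "numeric",
    maxGenoMissing   = "numeric",
    hwePThreshold    = "numeric",
    minMAF           = "numeric"
))

setValidity("QCParams", function(object) {
    msg <- character(0)
    frac <- c(maxSampleMissing = object@maxSampleMissing,
              maxGenoMissing   = object@maxGenoMissing)
    if (any(frac < 0 | frac > 1, na.rm = TRUE))
        msg <- c(msg, "missingness fractions must lie in [0, 1]")
    if (!is.na(object@hwePThreshold) &&
        (object@hwePThreshold <= 0 || object@hwePThreshold >= 1))
        msg <- c(msg, "hwePThreshold must lie in (0, 1)")
    if (!is.na(object@minMAF) && (object@minMAF < 0 || object@minMAF > 0.5))
        msg <- c(msg, "minMAF must lie in [0, 0.5] or be NA")
    if (length(msg)) msg else TRUE
})

#' Sliding-window ROH calling parameters
#'
#' Parameters of the PLINK-style sliding-window run-of-homozygosity
#' scan. Defaults reproduce a widely used whole-genome-resequencing
#' configuration: 50-SNP windows allowing at most 1 heterozygote and 5
#' missing calls, window hit-rate threshold 0.05, and segment filters of
#' at least 30 SNPs, at least 200 kb, at most 30 kb per SNP and no
#' internal gap above 500 kb.
#'
#' @slot windowSnp integer(1), SNPs per sliding window.
#' @slot windowHetMax integer(1), maximum heterozygous calls for a window
#'   to count as homozygous.
#' @slot windowMissingMax integer(1), maximum missing calls per window.
#' @slot windowThreshold numeric(1), minimum fraction of homozygous
#'   windows (among windows containing the SNP) for a SNP to be eligible.
#' @slot minSnp integer(1), minimum SNPs per emitted segment.
#' @slot minLengthKb numeric(1), minimum segment length in kb.
#' @slot maxDensityKbPerSnp numeric(1), maximum kb per SNP inside a
#'   segment (inverse marker density).
#' @slot maxGapKb numeric(1), maximum distance between consecutive SNPs
#'   inside a segment, in kb.
#' @seealso \code{\link{rohCallParams}}, \code{\link{callROH}}
#' @export
setClass("ROHCallParams", representation(
    windowSnp          = "integer",
    windowHetMax       = "integer",
    windowMissingMax   = "integer",
    windowThreshold    = "numeric",
    minSnp             = "integer",
    minLengthKb        = "numeric",
    maxDensityKbPerSnp = "numeric",
    maxGapKb           = "numeric"
))

setValidity("ROHCallParams", function(object) {
    msg <- character(0)
    if (object@windowSnp < 1L) msg <- c(msg, "windowSnp must be >= 1")
    if (object@windowHetMax < 0L || object@windowMissingMax < 0L)
        msg <- c(msg, "window het/missing caps must be >= 0")
    if (object@windowThreshold <= 0 || object@windowThreshold > 1)
        msg <- c(msg, "windowThreshold must lie in (0, 1]")
    if (object@minSnp < 1L) msg <- c(msg, "minSnp must be >= 1")
    if (object@minLengthKb <= 0) msg <- c(msg, "minLengthKb must be > 0")
    if (object@maxDensityKbPerSnp <= 0) msg <- c(msg, "maxDensityKbPerSnp must be > 0")
    if (object@maxGapKb <= 0) msg <- c(msg, "maxGapKb must be > 0")
    if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic genotype simulator
#'
#' Describes a simulated diploid population: sample count, autosome
#' lengths, marker density, the distribution allele frequencies are drawn
#' from, the heterozygote-miscall rate inside planted autozygous tracts,
#' genome-wide missingness, and the mandatory random seed (all
#' randomness in the simulator flows from it; there is no implicit
#' entropy source).
#'
#' @slot nSamples integer(1), number of diploid individuals.
#' @slot chromLengths named numeric, autosome lengths in bp.
#' @slot snpDensity numeric(1), mean SNPs per kb.
#' @slot mafRange numeric(2), bounds of the uniform distribution the
#'   per-SNP alternate-allele frequency is drawn from.
#' @slot hetErrorRate numeric(1), probability a tract SNP is miscalled
#'   heterozygous.
#' @slot missingRate numeric(1), probability any call is missing.
#' @slot seed integer(1), random seed (mandatory).
#' @seealso \code{\link{simulationConfig}}, \code{\link{simulateBackground}}
#' @export
setClass("SimulationConfig", representation(
    nSamples     = "integer",
    chromLengths = "numeric",
    snpDensity   = "numeric",
    mafRange     = "numeric",
    hetErrorRate = "numeric",
    missingRate  = "numeric",
    seed         = "integer"
))

setValidity("SimulationConfig", function(object) {
    msg <- character(0)
    if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
    if (!length(object@chromLengths) || any(object@chromLengths <= 0))
        msg <- c(msg, "chromLengths must be positive")
    if (is.null(names(object@chromLengths)))
        msg <- c(msg, "chromLengths must be named by chromosome")
    if (object@snpDensity <= 0) msg <- c(msg, "snpDensity must be > 0")
    if (length(object@mafRange) != 2L || any(object@mafRange < 0) ||
        any(object@mafRange > 1) || object@mafRange[1] > object@mafRange[2])
        msg <- c(msg, "mafRange must be increasing bounds in [0, 1]")
    for (r in c(object@hetErrorRate, object@missingRate))
        if (r < 0 || r > 1) msg <- c(msg, "rates must lie in [0, 1]")
    if (is.na(object@seed)) msg <- c(msg, "seed is mandatory")
    if (length(msg)) msg else TRUE
})
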