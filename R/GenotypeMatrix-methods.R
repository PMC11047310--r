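#' Construct a GenotypeMatrix
#'
#' Builds the central genotype container from a code matrix and a variant
#' map. Variants are reordered by (chromosome, position); non-autosomal
#' variants are rejected (drop them before construction, as
#' \code{\link{readVCF}} does).
#'
#' @param calls numeric/integer matrix of genotype codes, variants in
#'   rows and samples in columns (0 hom-ref, 1 het, 2 hom-alt, NA
#'   missing). Column names are the sample IDs.
#' @param variants data.frame with columns \code{chrom}, \code{pos} and
#'   optionally \code{id}, \code{ref}, \code{alt} (and extra per-variant
#'   columns such as \code{af}, kept as row metadata).
#' @return A \linkS4class{GenotypeMatrix}.
#' @examples
#' gm <- GenotypeMatrix(
#'     calls = matrix(c(0, 1, 2, 0, NA, 2), nrow = 3,
#'                    dimnames = list(NULL, c("s1", "s2"))),
#'     variants = data.frame(chrom = "1", pos = c(100, 200, 300)))
#' gm
#' @export
GenotypeMatrix <- function(calls, variants) {
    if (!is.matrix(calls)) calls <- as.matrix(calls)
    storage.mode(calls) <- "integer"
    if (nrow(calls) != nrow(variants))
        stop("nrow(calls) must equal nrow(variants)")
    if (is.null(colnames(calls)))
        colnames(calls) <- sprintf("S%03d", seq_len(ncol(calls)))
    chrom <- as.character(variants$chrom)
    pos <- as.numeric(variants$pos)
    ord <- order(match(chrom, unique(chrom)), pos)
    calls <- calls[ord, , drop = FALSE]
    variants <- variants[ord, , drop = FALSE]
    chrom <- chrom[ord]; pos <- pos[ord]
    rr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
    meta <- variants[setdiff(names(variants), c("chrom", "pos"))]
    if (!"id" %in% names(meta))
        meta$id <- paste(chrom, format(pos, scientific = FALSE, trim = TRUE), sep = "_")
    if (!"ref" %in% names(meta)) meta$ref <- NA_character_
    if (!"alt" %in% names(meta)) meta$alt <- NA_character_
    S4Vectors::mcols(rr) <- S4Vectors::DataFrame(meta, row.names = NULL)
    names(rr) <- meta$id
    rownames(calls) <- meta$id
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(GT = calls), rowRanges = rr)
    new("GenotypeMatrix", se)
}

#' @rdname genotypeCalls
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' Accessors for GenotypeMatrix objects
#'
#' \code{genotypeCalls} returns the integer code matrix (variants x
#' samples); \code{variantMap} the per-SNP map as a data.frame;
#' \code{sampleIDs} the sample names; \code{alleleFreqs} the per-SNP
#' alternate-allele frequency (the simulator's true frequency when
#' recorded, otherwise estimated from non-missing calls).
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @return \code{genotypeCalls}: integer matrix; \code{variantMap}:
#'   data.frame with columns chrom, pos, id, ref, alt (plus any extra
#'   metadata); \code{sampleIDs}: character; \code{alleleFreqs}: numeric.
#' @name genotypeCalls
#' @aliases variantMap sampleIDs alleleFreqs
#' @export
setMethod("genotypeCalls", "GenotypeMatrix", function(x)
    SummarizedExperiment::assay(x, "GT"))

#' @rdname genotypeCalls
#' @export
setGeneric("variantMap", function(x) standardGeneric("variantMap"))

#' @rdname genotypeCalls
#' @export
setMethod("variantMap", "GenotypeMatrix", function(x) {
    rr <- SummarizedExperiment::rowRanges(x)
    out <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                      pos = GenomicRanges::start(rr),
                      stringsAsFactors = FALSE)
    cbind(out, as.data.frame(S4Vectors::mcols(rr)), row.names = NULL)
})

#' @rdname genotypeCalls
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname genotypeCalls
#' @export
setMethod("sampleIDs", "GenotypeMatrix", function(x) colnames(x))

#' @rdname genotypeCalls
#' @export
setGeneric("alleleFreqs", function(x) standardGeneric("alleleFreqs"))

#' @rdname genotypeCalls
#' @export
setMethod("alleleFreqs", "GenotypeMatrix", function(x) {
    mc <- S4Vectors::mcols(SummarizedExperiment::rowRanges(x))
    if ("af" %in% names(mc)) return(as.numeric(mc$af))
    rowMeans(genotypeCalls(x), na.rm = TRUE) / 2
})

#' @rdname qcReport
#' @export
setGeneric("qcReport", function(x) standardGeneric("qcReport"))

#' Retrieve the QC report attached by applyQC
#'
#' @param x a \linkS4class{GenotypeMatrix} returned by
#'   \code{\link{applyQC}}.
#' @return data.frame with one row per filter step (step, removed,
#'   remaining counts), or NULL when no QC has been run.
#' @name qcReport
#' @export
setMethod("qcReport", "GenotypeMatrix", function(x)
    S4Vectors::metadata(x)$qcReport)

setMethod("show", "GenotypeMatrix", function(object) {
    chr <- unique(as.character(GenomicRanges::seqnames(
        SummarizedExperiment::rowRanges(object))))
    cat("GenotypeMatrix:", nrow(object), "SNPs x", ncol(object), "samples\n")
    cat("  chromosomes:", paste(head(chr, 8), collapse = ", "),
        if (length(chr) > 8) "..." else "", "\n")
    gt <- genotypeCalls(object)
    cat(sprintf("  missing: %.2f%%  het: %.2f%%\n",
                100 * mean(is.na(gt)),
                100 * mean(gt == 1L, na.rm = TRUE)))
    if (!is.null(qcReport(object))) cat("  QC: applied (see qcReport())\n")
})

setMethod("show", "QCParams", function(object) {
    cat("QCParams\n")
    cat("  maxSampleMissing:", object@maxSampleMissing, "\n")
    cat("  maxGenoMissing:  ", object@maxGenoMissing, "\n")
    cat("  hwePThreshold:   ", object@hwePThreshold, "\n")
    cat("  minMAF:          ",
        if (is.na(object@minMAF)) "disabled" else object@minMAF, "\n")
})

setMethod("show", "ROHCallParams", function(object) {
    cat("ROHCallParams (sliding-window homozygosity scan)\n")
    cat(sprintf("  window: %d SNPs, <=%d het, <=%d missing, threshold %.3g\n",
                object@windowSnp, object@windowHetMax, object@windowMissingMax,
                object@windowThreshold))
    cat(sprintf("  segment: >=%d SNPs, >=%g kb, <=%g kb/SNP, gap <=%g kb\n",
                object@minSnp, object@minLengthKb, object@maxDensityKbPerSnp,
                object@maxGapKb))
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nSamples, "samples,",
        length(object@chromLengths), "autosomes,",
        sprintf("%.1f Mb total\n", sum(object@chromLengths) / 1e6))
    cat(sprintf("  density %.3g SNP/kb, maf U[%g, %g], hetErr %g, missing %g, seed %d\n",
                object@snpDensity, object@mafRange[1], object@mafRange[2],
                object@hetErrorRate, object@missingRate, object@seed))
})
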