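#' Read diploid biallelic SNP genotypes from a VCF file
#'
#' Imports GT fields from a VCF 4.x file into a
#' \linkS4class{GenotypeMatrix}. Only biallelic SNP records (single-base
#' REF and ALT) on autosomes are kept; multi-allelic records, indels and
#' non-autosomal records are skipped with a logged count. Phase is
#' ignored; half-missing diploid calls (e.g. \code{"0/."}) are coded
#' missing.
#'
#' @param path path to a VCF (plain or bgzipped) with GT genotypes.
#' @return A \linkS4class{GenotypeMatrix}. Skip counts are stored in
#'   \code{metadata(x)$readLog}.
#' @export
readVCF <- function(path) {
    if (!file.exists(path)) stop("cannot read VCF: ", path)
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
    if (!"GT" %in% rownames(VariantAnnotation::geno(VariantAnnotation::header(vcf))))
        stop("VCF has no GT genotype field: ", path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(VariantAnnotation::ref(vcf))
    altL <- VariantAnnotation::alt(vcf)
    nAlt <- S4Vectors::elementNROWS(altL)
    chrom <- as.character(GenomicRanges::seqnames(rr))

    biallelic <- nAlt == 1L
    alt <- rep(NA_character_, length(ref))
    alt[biallelic] <- as.character(unlist(altL[biallelic]))
    isSnp <- biallelic & nchar(ref) == 1L & !is.na(alt) & nchar(alt) == 1L &
        ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
    isAuto <- .isAutosome(chrom)
    keep <- isSnp & isAuto

    log <- c(records = length(ref),
             skipped_multiallelic_or_indel = sum(!isSnp),
             skipped_non_autosomal = sum(isSnp & !isAuto),
             retained = sum(keep))
    message(sprintf("readVCF: %d records, kept %d biallelic autosomal SNPs (%d non-SNP/multi-allelic, %d non-autosomal skipped)",
                    log[["records"]], log[["retained"]],
                    log[["skipped_multiallelic_or_indel"]],
                    log[["skipped_non_autosomal"]]))
    if (!sum(keep)) stop("empty matrix: no usable biallelic autosomal SNP records in ", path)

    gt <- VariantAnnotation::geno(vcf)$GT[keep, , drop = FALSE]
    calls <- .decodeGT(gt)
    variants <- data.frame(chrom = chrom[keep],
                           pos = GenomicRanges::start(rr)[keep],
                           id = names(rr)[keep],
                           ref = ref[keep], alt = alt[keep],
                           stringsAsFactors = FALSE)
    # de-duplicate (chrom,pos): keep first occurrence
    dup <- duplicated(paste(variants$chrom, variants$pos))
    if (any(dup)) {
        message("readVCF: dropped ", sum(dup), " duplicate-position records")
        calls <- calls[!dup, , drop = FALSE]
        variants <- variants[!dup, , drop = FALSE]
    }
    gm <- GenotypeMatrix(calls, variants)
    S4Vectors::metadata(gm)$readLog <- log
    gm
}

# GT strings ("0/1", "1|1", "./.", "0/.") -> integer codes; any missing
# allele makes the whole call missing
.decodeGT <- function(gt) {
    u <- unique(as.vector(gt))
    code <- vapply(u, function(s) {
        al <- strsplit(s, "[/|]")[[1]]
        if (length(al) != 2L || any(al == ".") || any(is.na(al))) return(NA_integer_)
        al <- suppressWarnings(as.integer(al))
        if (anyNA(al) || any(al > 1L)) return(NA_integer_)
        sum(al)
    }, integer(1))
    m <- matrix(code[match(as.vector(gt), u)], nrow = nrow(gt),
                dimnames = dimnames(gt))
    m
}

#' Read/write genotypes as a plain tabular file
#'
#' The tabular alternative to VCF: a TSV with columns \code{chrom},
#' \code{pos}, \code{id}, \code{ref}, \code{alt} followed by one column
#' per sample holding codes 0/1/2/NA. Non-autosomal rows are dropped on
#' read.
#'
#' @param path file path.
#' @param gm a \linkS4class{GenotypeMatrix} (for writing).
#' @return \code{readGenotypeTSV}: a \linkS4class{GenotypeMatrix};
#'   \code{writeGenotypeTSV}: the path, invisibly.
#' @export
readGenotypeTSV <- function(path) {
    if (!file.exists(path)) stop("cannot read genotype table: ", path)
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                     colClasses = c(chrom = "character"))
    fixed <- c("chrom", "pos", "id", "ref", "alt")
    miss <- setdiff(fixed, names(df))
    if (length(miss)) stop("genotype table lacks column(s): ",
                           paste(miss, collapse = ", "))
    auto <- .isAutosome(df$chrom)
    if (any(!auto))
        message("readGenotypeTSV: dropped ", sum(!auto), " non-autosomal rows")
    df <- df[auto, , drop = FALSE]
    if (!nrow(df)) stop("empty matrix: no autosomal rows in ", path)
    samples <- setdiff(names(df), fixed)
    if (!length(samples)) stop("genotype table has no sample columns")
    calls <- as.matrix(df[samples])
    GenotypeMatrix(calls, df[fixed])
}

#' @rdname readGenotypeTSV
#' @export
writeGenotypeTSV <- function(gm, path) {
    stopifnot(is(gm, "GenotypeMatrix"))
    vm <- variantMap(gm)[c("chrom", "pos", "id", "ref", "alt")]
    .writeTSV(cbind(vm, as.data.frame(genotypeCalls(gm))), path)
}

#' Read a sample-to-population map
#'
#' Two-column TSV (\code{sample_id}, \code{population}); returns a named
#' character vector keyed by sample. Duplicated sample IDs are an error
#' (every analysed sample has exactly one population).
#'
#' @param path file path.
#' @return named character vector: population code per sample.
#' @export
readPopulationMap <- function(path) {
    if (!file.exists(path)) stop("cannot read population map: ", path)
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("population map needs two columns (sample_id, population)")
    if (anyDuplicated(df[[1]]))
        stop("population map assigns some sample more than one population")
    setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Write and read ROH segment tables
#'
#' Segments travel as TSV with columns \code{sample}, \code{population},
#' \code{chrom}, \code{start_bp}, \code{end_bp}, \code{n_snps},
#' \code{length_kb}; coordinates are 1-based inclusive. The population
#' column is written as NA when absent.
#'
#' @param segments segment data.frame (see \code{\link{callROH}}).
#' @param path file path.
#' @return \code{writeSegments}: the path, invisibly;
#'   \code{readSegments}: the segment data.frame.
#' @export
writeSegments <- function(segments, path) {
    .checkSegments(segments)
    if (!"population" %in% names(segments))
        segments$population <- rep(NA_character_, nrow(segments))
    cols <- c("sample", "population", "chrom", "start_bp", "end_bp",
              "n_snps", "length_kb")
    .writeTSV(segments[cols], path)
}

#' @rdname writeSegments
#' @export
readSegments <- function(path) {
    if (!file.exists(path)) stop("cannot read segments: ", path)
    df <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = c(chrom = "character", sample = "character"))
    df$n_snps <- as.integer(df$n_snps)
    df
}

#' Write genomic intervals as BED
#'
#' Converts 1-based inclusive intervals (columns \code{chrom},
#' \code{start_bp}, \code{end_bp}, plus an optional \code{name} column)
#' to the 0-based half-open BED convention.
#'
#' @param intervals data.frame with chrom/start_bp/end_bp (1-based
#'   inclusive) or a GRanges.
#' @param path output file.
#' @return the path, invisibly.
#' @examples
#' \dontrun{
#' # interval chr1:100-299 becomes the BED line "chr1  99  299"
#' writeBED(data.frame(chrom = "chr1", start_bp = 100, end_bp = 299), "out.bed")
#' }
#' @export
writeBED <- function(intervals, path) {
    if (is(intervals, "GRanges"))
        intervals <- data.frame(
            chrom = as.character(GenomicRanges::seqnames(intervals)),
            start_bp = GenomicRanges::start(intervals),
            end_bp = GenomicRanges::end(intervals))
    bed <- data.frame(chrom = intervals$chrom,
                      start = format(intervals$start_bp - 1, scientific = FALSE, trim = TRUE),
                      end = format(intervals$end_bp, scientific = FALSE, trim = TRUE))
    if ("name" %in% names(intervals)) bed$name <- intervals$name
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}
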