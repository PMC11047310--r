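# internal helpers

# autosome = chromosome label that is an integer, optionally "chr"-prefixed
.isAutosome <- function(chr) {
    grepl("^(chr)?[0-9]+$", chr, ignore.case = TRUE)
}

.segmentColumns <- c("sample", "chrom", "start_bp", "end_bp", "n_snps", "length_kb")

.emptySegments <- function() {
    data.frame(sample = character(0), chrom = character(0),
               start_bp = numeric(0), end_bp = numeric(0),
               n_snps = integer(0), length_kb = numeric(0),
               stringsAsFactors = FALSE)
}

.checkSegments <- function(segments) {
    miss <- setdiff(.segmentColumns, names(segments))
    if (length(miss))
        stop("segment table is missing column(s): ", paste(miss, collapse = ", "))
    invisible(segments)
}

# segments data.frame -> GRanges with sample (and any extra columns) as mcols
.segmentsToGRanges <- function(segments) {
    .checkSegments(segments)
    gr <- GenomicRanges::GRanges(
        seqnames = segments$chrom,
        ranges = IRanges::IRanges(start = segments$start_bp, end = segments$end_bp))
    S4Vectors::mcols(gr)$sample <- segments$sample
    gr
}

.variantGRanges <- function(variants) {
    if (is(variants, "GenotypeMatrix"))
        return(SummarizedExperiment::rowRanges(variants))
    GenomicRanges::GRanges(seqnames = variants$chrom,
                           ranges = IRanges::IRanges(variants$pos, width = 1L))
}

# 1-based inclusive interval length in kb
.lengthKb <- function(start_bp, end_bp) (end_bp - start_bp + 1) / 1000

.writeTSV <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE, na = "NA")
    invisible(path)
}
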