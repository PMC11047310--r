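#' Per-SNP ROH incidence within a population
#'
#' For every SNP, the fraction of a population's individuals whose ROH
#' set covers the SNP position (segment start <= pos <= segment end).
#' The denominator is all analysed individuals of the population,
#' including those without any ROH. This is the statistic plotted in
#' ROH Manhattan plots and thresholded to find ROH islands.
#'
#' @param segments segment data.frame (any samples outside
#'   \code{popSamples} are ignored).
#' @param variants a \linkS4class{GenotypeMatrix} or a data.frame with
#'   \code{chrom} and \code{pos} columns defining the SNP track.
#' @param popSamples character vector of the population's sample IDs
#'   (must be non-empty).
#' @return data.frame: chrom, pos, incidence.
#' @export
rohIncidence <- function(segments, variants, popSamples) {
    if (!length(popSamples)) stop("rohIncidence: empty population")
    snps <- .variantGRanges(variants)
    vm <- if (is(variants, "GenotypeMatrix")) variantMap(variants) else variants
    out <- data.frame(chrom = as.character(vm$chrom), pos = vm$pos,
                      incidence = 0, stringsAsFactors = FALSE)
    segs <- segments[segments$sample %in% popSamples, , drop = FALSE]
    if (nrow(segs)) {
        # per-sample reduce guards against double counting should a
        # caller ever emit overlapping segments for one individual
        bySample <- split(segs, segs$sample)
        counts <- integer(length(snps))
        for (d in bySample) {
            gr <- GenomicRanges::reduce(.segmentsToGRanges(d))
            counts <- counts + (GenomicRanges::countOverlaps(snps, gr) > 0L)
        }
        out$incidence <- counts / length(popSamples)
    }
    out
}

#' Top-fraction incidence threshold for island calling
#'
#' The nearest-rank upper percentile of the incidence track: with
#' \code{topFraction = 0.001} the threshold is the
#' \code{ceiling(0.001 * n)}-th largest incidence value (the 99.9th
#' percentile). Island membership then requires incidence strictly
#' above the threshold, so ties at the threshold value are excluded; a
#' constant track yields no islands.
#'
#' @param track incidence data.frame from \code{\link{rohIncidence}}.
#' @param topFraction fraction of SNPs defining the tail (default
#'   0.001).
#' @return the threshold incidence value.
#' @export
islandThreshold <- function(track, topFraction = 0.001) {
    if (!nrow(track)) stop("islandThreshold: empty incidence track")
    k <- max(1L, ceiling(topFraction * nrow(track)))
    sort(track$incidence, decreasing = TRUE)[k]
}

#' Call ROH islands from an incidence track
#'
#' Islands are maximal runs of consecutive SNPs (in map order, within a
#' chromosome) whose incidence strictly exceeds the threshold; runs with
#' fewer than \code{minSnps} SNPs are dropped (a single qualifying SNP
#' is a degenerate "contiguous string"). The island span runs from the
#' first to the last member SNP.
#'
#' @param track incidence data.frame.
#' @param threshold incidence threshold, typically
#'   \code{\link{islandThreshold}}.
#' @param minSnps minimum member SNPs per island (default 2).
#' @return data.frame: chrom, start_bp, end_bp, n_snps, peak_incidence.
#' @export
callIslands <- function(track, threshold, minSnps = 2L) {
    empty <- data.frame(chrom = character(0), start_bp = numeric(0),
                        end_bp = numeric(0), n_snps = integer(0),
                        peak_incidence = numeric(0), stringsAsFactors = FALSE)
    if (!nrow(track)) return(empty)
    res <- list()
    for (ch in unique(track$chrom)) {
        d <- track[track$chrom == ch, , drop = FALSE]
        d <- d[order(d$pos), , drop = FALSE]
        above <- d$incidence > threshold
        if (!any(above)) next
        r <- rle(above)
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
        for (k in which(r$values & r$lengths >= minSnps)) {
            i <- starts[k]; j <- ends[k]
            res[[length(res) + 1L]] <- data.frame(
                chrom = ch, start_bp = d$pos[i], end_bp = d$pos[j],
                n_snps = j - i + 1L,
                peak_incidence = max(d$incidence[i:j]),
                stringsAsFactors = FALSE)
        }
    }
    if (!length(res)) return(empty)
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Annotate intervals with overlapping gene names
#'
#' Joins islands (or any interval table with \code{chrom},
#' \code{start_bp}, \code{end_bp}) against gene intervals from a BED or
#' GFF3 file (or a ready GRanges); a gene is listed when its interval
#' overlaps the island span by at least one base pair.
#'
#' @param intervals interval data.frame (1-based inclusive).
#' @param genes path to a BED/GFF3 file, or a GRanges whose names or
#'   name/Name/gene_name/gene_id/ID metadata column carries the gene
#'   identifier.
#' @return the interval data.frame with a comma-separated \code{genes}
#'   column (empty string when nothing overlaps).
#' @export
annotateIntervals <- function(intervals, genes) {
    if (is.character(genes)) genes <- rtracklayer::import(genes)
    stopifnot(is(genes, "GRanges"))
    nm <- NULL
    mc <- S4Vectors::mcols(genes)
    for (col in c("name", "Name", "gene_name", "gene_id", "ID"))
        if (col %in% names(mc)) { nm <- as.character(mc[[col]]); break }
    if (is.null(nm)) nm <- if (!is.null(names(genes))) names(genes) else
        as.character(genes)
    intervals$genes <- ""
    if (!nrow(intervals)) return(intervals)
    gr <- GenomicRanges::GRanges(intervals$chrom,
                                 IRanges::IRanges(intervals$start_bp,
                                                  intervals$end_bp))
    hits <- GenomicRanges::findOverlaps(gr, genes)
    if (length(hits)) {
        byIv <- split(nm[S4Vectors::subjectHits(hits)],
                      S4Vectors::queryHits(hits))
        for (q in names(byIv))
            intervals$genes[as.integer(q)] <-
                paste(unique(byIv[[q]]), collapse = ",")
    }
    intervals
}

#' Per-population ROH island scan
#'
#' Convenience wrapper: computes the incidence track, threshold and
#' islands separately for each population (thresholds are
#' population-specific, as island analyses are usually reported per
#' population; pool samples yourself for a global scan).
#'
#' @param segments segment data.frame.
#' @param variants SNP track (see \code{\link{rohIncidence}}).
#' @param popmap named character vector sample -> population.
#' @param topFraction,minSnps see \code{\link{islandThreshold}} and
#'   \code{\link{callIslands}}.
#' @param genes optional gene intervals for annotation.
#' @return named list per population, each with \code{track} (including
#'   an \code{above_threshold} flag), \code{threshold} and
#'   \code{islands}.
#' @export
islandScan <- function(segments, variants, popmap, topFraction = 0.001,
                       minSnps = 2L, genes = NULL) {
    pops <- unique(popmap)
    out <- lapply(pops, function(p) {
        samples <- names(popmap)[popmap == p]
        track <- rohIncidence(segments, variants, samples)
        thr <- islandThreshold(track, topFraction)
        isl <- callIslands(track, thr, minSnps)
        if (nrow(isl)) isl$population <- p
        if (!is.null(genes) && nrow(isl)) isl <- annotateIntervals(isl, genes)
        track$above_threshold <- track$incidence > thr
        list(track = track, threshold = thr, islands = isl)
    })
    names(out) <- pops
    out
}
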