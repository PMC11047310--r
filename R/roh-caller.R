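#' Construct sliding-window ROH calling parameters
#'
#' Defaults correspond to the PLINK \code{--homozyg} settings commonly
#' used for whole-genome resequencing panels: \code{--homozyg-window-snp
#' 50 --homozyg-window-het 1 --homozyg-window-missing 5
#' --homozyg-window-threshold 0.05 --homozyg-snp 30 --homozyg-kb 200
#' --homozyg-density 30 --homozyg-gap 500}.
#'
#' @param windowSnp,windowHetMax,windowMissingMax,windowThreshold window
#'   scan settings (see \linkS4class{ROHCallParams}).
#' @param minSnp,minLengthKb,maxDensityKbPerSnp,maxGapKb segment filters.
#' @return a \linkS4class{ROHCallParams}.
#' @export
rohCallParams <- function(windowSnp = 50L, windowHetMax = 1L,
                          windowMissingMax = 5L, windowThreshold = 0.05,
                          minSnp = 30L, minLengthKb = 200,
                          maxDensityKbPerSnp = 30, maxGapKb = 500) {
    new("ROHCallParams",
        windowSnp = as.integer(windowSnp),
        windowHetMax = as.integer(windowHetMax),
        windowMissingMax = as.integer(windowMissingMax),
        windowThreshold = as.numeric(windowThreshold),
        minSnp = as.integer(minSnp),
        minLengthKb = as.numeric(minLengthKb),
        maxDensityKbPerSnp = as.numeric(maxDensityKbPerSnp),
        maxGapKb = as.numeric(maxGapKb))
}

#' Per-SNP eligibility under the sliding homozygous-window scan
#'
#' Slides a window of \code{windowSnp} consecutive SNPs along one
#' chromosome of one sample. A window is homozygous when it contains at
#' most \code{windowHetMax} heterozygous and \code{windowMissingMax}
#' missing calls. Each SNP's hit fraction is the share of homozygous
#' windows among the windows that contain it; SNPs near the chromosome
#' ends belong to fewer than \code{windowSnp} windows and only those
#' instantiated windows enter the denominator. A SNP is eligible when
#' its hit fraction reaches \code{windowThreshold}. Chromosomes with
#' fewer SNPs than one window are evaluated with a single truncated
#' window.
#'
#' @param genotypes integer codes (0/1/2/NA) of one sample on one
#'   chromosome, position-ordered.
#' @param positions base-pair positions, sorted ascending.
#' @param params a \linkS4class{ROHCallParams}.
#' @return logical vector, one entry per SNP.
#' @export
windowEligibility <- function(genotypes, positions, params = rohCallParams()) {
    n <- length(genotypes)
    if (n == 0L) return(logical(0))
    if (length(positions) != n)
        stop("genotypes and positions differ in length")
    if (is.unsorted(positions)) stop("positions must be sorted ascending")
    het <- !is.na(genotypes) & genotypes == 1L
    mis <- is.na(genotypes)
    W <- params@windowSnp
    if (n < W) {   # single truncated window covering the chromosome
        ok <- sum(het) <= params@windowHetMax &&
              sum(mis) <= params@windowMissingMax
        return(rep(ok, n))
    }
    nW <- n - W + 1L
    chet <- cumsum(het); cmis <- cumsum(mis)
    wHet <- chet[W:n] - c(0L, chet[seq_len(nW - 1L)])
    wMis <- cmis[W:n] - c(0L, cmis[seq_len(nW - 1L)])
    wOk <- wHet <= params@windowHetMax & wMis <= params@windowMissingMax
    cok <- c(0L, cumsum(wOk))
    i <- seq_len(n)
    lo <- pmax(1L, i - W + 1L)       # first window containing SNP i
    hi <- pmin(i, nW)                # last window containing SNP i
    hits <- cok[hi + 1L] - cok[lo]
    hits / (hi - lo + 1L) >= params@windowThreshold
}

#' Call ROH segments for one sample
#'
#' Candidate runs are maximal stretches of eligible SNPs
#' (\code{\link{windowEligibility}}), split wherever two consecutive
#' SNPs are more than \code{maxGapKb} apart; each run is then trimmed so
#' that both endpoints are non-missing homozygous calls, and kept only
#' if it holds at least \code{minSnp} SNPs, spans at least
#' \code{minLengthKb} kb and is no sparser than
#' \code{maxDensityKbPerSnp} kb per SNP. Segment length is the inclusive
#' base-pair span; \code{n_snps} counts every SNP between the endpoints.
#'
#' @param genotypes,positions one sample's codes and sorted positions;
#'   may span several chromosomes when \code{chrom} is given.
#' @param chrom chromosome label per SNP (or a single label; default
#'   \code{"1"}).
#' @param params a \linkS4class{ROHCallParams}.
#' @param sample sample ID recorded in the output.
#' @return segment data.frame: sample, chrom, start_bp, end_bp, n_snps,
#'   length_kb (possibly zero rows).
#' @export
callSampleROH <- function(genotypes, positions, chrom = "1",
                          params = rohCallParams(), sample = "sample") {
    n <- length(genotypes)
    chrom <- if (length(chrom) == 1L) rep(chrom, n) else as.character(chrom)
    if (length(chrom) != n) stop("chrom must match genotypes in length")
    out <- lapply(unique(chrom), function(ch) {
        sel <- chrom == ch
        segs <- .callChromosome(genotypes[sel], positions[sel], params)
        if (nrow(segs)) segs$chrom <- ch
        segs
    })
    out <- do.call(rbind, out[vapply(out, nrow, integer(1)) > 0])
    if (is.null(out)) return(.emptySegments())
    out$sample <- sample
    out <- out[order(match(out$chrom, unique(chrom)), out$start_bp),
               .segmentColumns, drop = FALSE]
    rownames(out) <- NULL
    out
}

# core per-chromosome scan; genotypes/positions on one chromosome
.callChromosome <- function(genotypes, positions, params) {
    empty <- data.frame(start_bp = numeric(0), end_bp = numeric(0),
                        n_snps = integer(0), length_kb = numeric(0))
    n <- length(genotypes)
    if (!n) return(empty)
    elig <- windowEligibility(genotypes, positions, params)
    if (!any(elig)) return(empty)
    r <- rle(elig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gapBp <- params@maxGapKb * 1000
    hom <- !is.na(genotypes) & genotypes != 1L
    res <- list()
    for (k in which(r$values)) {
        i <- starts[k]; j <- ends[k]
        # split at inter-SNP gaps above the cap
        cut <- which(diff(positions[i:j]) > gapBp)
        subStarts <- c(i, i + cut)
        subEnds <- c(i + cut - 1L, j)
        for (m in seq_along(subStarts)) {
            s <- subStarts[m]; e <- subEnds[m]
            while (s <= e && !hom[s]) s <- s + 1L   # trim to homozygous ends
            while (e >= s && !hom[e]) e <- e - 1L
            if (s > e) next
            nSnp <- e - s + 1L
            lenKb <- .lengthKb(positions[s], positions[e])
            if (nSnp >= params@minSnp && lenKb >= params@minLengthKb &&
                lenKb / nSnp <= params@maxDensityKbPerSnp)
                res[[length(res) + 1L]] <-
                    data.frame(start_bp = positions[s], end_bp = positions[e],
                               n_snps = nSnp, length_kb = lenKb)
        }
    }
    if (!length(res)) return(empty)
    do.call(rbind, res)
}

#' @rdname callROH
#' @export
setGeneric("callROH", function(gm, params = rohCallParams(), ...)
    standardGeneric("callROH"))

#' Call ROH segments for every sample of a genotype matrix
#'
#' Runs the sliding-window scan per sample and chromosome and returns
#' all segments ordered by (sample, chromosome, start). Samples are
#' independent, so permuting the sample order only permutes the output.
#'
#' @param gm a \linkS4class{GenotypeMatrix} that has passed the
#'   "roh" QC profile (MAF filter disabled).
#' @param params a \linkS4class{ROHCallParams}.
#' @param ... unused.
#' @return segment data.frame with columns sample, chrom, start_bp,
#'   end_bp, n_snps, length_kb (1-based inclusive coordinates).
#' @name callROH
#' @export
setMethod("callROH", "GenotypeMatrix", function(gm, params = rohCallParams(), ...) {
    if (!nrow(gm) || !ncol(gm))
        stop("callROH: empty genotype matrix")
    vm <- variantMap(gm)
    calls <- genotypeCalls(gm)
    out <- lapply(colnames(calls), function(s)
        callSampleROH(calls[, s], vm$pos, vm$chrom, params, sample = s))
    out <- do.call(rbind, out)
    out <- out[order(out$sample, match(out$chrom, unique(vm$chrom)),
                     out$start_bp), , drop = FALSE]
    rownames(out) <- NULL
    out
})

#' Independently validate emitted ROH segments
#'
#' Re-checks every segment invariant directly against the genotype
#' matrix, without reusing the caller's internals: minimum SNP count,
#' minimum length, marker density, maximum internal gap, homozygous
#' non-missing boundary SNPs, consistency of \code{n_snps} and
#' \code{length_kb}, and non-overlap within a sample.
#'
#' @param segments segment data.frame.
#' @param gm the \linkS4class{GenotypeMatrix} they were called from.
#' @param params the \linkS4class{ROHCallParams} used.
#' @return \code{TRUE} when all checks pass, otherwise a character
#'   vector describing each violation.
#' @export
validateSegments <- function(segments, gm, params = rohCallParams()) {
    .checkSegments(segments)
    vm <- variantMap(gm)
    calls <- genotypeCalls(gm)
    issues <- character(0)
    bad <- function(i, what) sprintf("segment %d (%s %s:%d-%d): %s", i,
        segments$sample[i], segments$chrom[i], segments$start_bp[i],
        segments$end_bp[i], what)
    for (i in seq_len(nrow(segments))) {
        sel <- vm$chrom == segments$chrom[i] &
               vm$pos >= segments$start_bp[i] & vm$pos <= segments$end_bp[i]
        pos <- vm$pos[sel]
        g <- calls[sel, segments$sample[i]]
        if (length(pos) != segments$n_snps[i])
            issues <- c(issues, bad(i, "n_snps mismatch"))
        lenKb <- .lengthKb(segments$start_bp[i], segments$end_bp[i])
        if (abs(lenKb - segments$length_kb[i]) > 1e-6)
            issues <- c(issues, bad(i, "length_kb mismatch"))
        if (length(pos) < params@minSnp)
            issues <- c(issues, bad(i, "below minSnp"))
        if (lenKb < params@minLengthKb)
            issues <- c(issues, bad(i, "below minLengthKb"))
        if (length(pos) && lenKb / length(pos) > params@maxDensityKbPerSnp)
            issues <- c(issues, bad(i, "density above maxDensityKbPerSnp"))
        if (length(pos) > 1 && any(diff(pos) > params@maxGapKb * 1000))
            issues <- c(issues, bad(i, "internal gap above maxGapKb"))
        if (length(g)) {
            endOk <- function(x) !is.na(x) && x != 1L
            if (!endOk(g[1]) || !endOk(g[length(g)]))
                issues <- c(issues, bad(i, "boundary SNP not homozygous"))
            if (!pos[1] == segments$start_bp[i] ||
                !pos[length(pos)] == segments$end_bp[i])
                issues <- c(issues, bad(i, "span not delimited by SNPs"))
        }
    }
    # non-overlap within sample
    bySample <- split(segments, paste(segments$sample, segments$chrom))
    for (d in bySample) {
        d <- d[order(d$start_bp), ]
        if (nrow(d) > 1 && any(d$start_bp[-1] <= d$end_bp[-nrow(d)]))
            issues <- c(issues, paste("overlapping segments for",
                                      d$sample[1], "on", d$chrom[1]))
    }
    if (length(issues)) issues else TRUE
}
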