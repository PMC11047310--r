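#' Configure the synthetic genotype simulator
#'
#' @param nSamples number of diploid individuals.
#' @param chromLengths named numeric vector of autosome lengths in bp
#'   (names are the chromosome labels, e.g. \code{c("1" = 6e7)}).
#' @param snpDensity mean SNPs per kb (default 0.1, i.e. one marker per
#'   10 kb; resequencing panels are denser, pass a larger value to
#'   emulate them).
#' @param mafRange bounds of the uniform alternate-allele-frequency draw
#'   (default \code{c(0.05, 0.5)}, mimicking a MAF-filtered panel).
#' @param hetErrorRate probability a SNP inside a planted autozygous
#'   tract is miscalled heterozygous (default 0).
#' @param missingRate probability any call is missing (default 0).
#' @param seed integer random seed; mandatory, all simulator randomness
#'   derives from it.
#' @return a \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(10, c("1" = 5e7, "2" = 4e7), seed = 1)
#' cfg
#' @export
simulationConfig <- function(nSamples, chromLengths, snpDensity = 0.1,
                             mafRange = c(0.05, 0.5), hetErrorRate = 0,
                             missingRate = 0, seed) {
    if (missing(seed)) stop("simulationConfig: 'seed' is mandatory")
    new("SimulationConfig",
        nSamples = as.integer(nSamples),
        chromLengths = chromLengths,
        snpDensity = as.numeric(snpDensity),
        mafRange = as.numeric(mafRange),
        hetErrorRate = as.numeric(hetErrorRate),
        missingRate = as.numeric(missingRate),
        seed = as.integer(seed))
}

#' Simulate a Hardy-Weinberg background genotype matrix
#'
#' Places SNPs uniformly along each chromosome at the configured density,
#' draws a per-SNP alternate-allele frequency from the configured uniform
#' range, and samples genotypes independently per individual from
#' Hardy-Weinberg proportions (Binomial(2, p) alternate-allele dosage).
#' Missing calls are sprinkled at \code{missingRate}. SNPs are
#' independent (no background linkage disequilibrium); autozygosity is
#' added separately by \code{\link{plantTracts}}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param seed overrides \code{config@seed}; pass \code{NULL} to
#'   continue from the current RNG state (used internally by
#'   \code{\link{simulatePopulation}}).
#' @return a \linkS4class{GenotypeMatrix}; the true allele frequency is
#'   kept in the variant metadata column \code{af}.
#' @export
simulateBackground <- function(config, seed = config@seed) {
    stopifnot(is(config, "SimulationConfig"))
    if (!is.null(seed)) set.seed(seed)
    chroms <- names(config@chromLengths)
    pieces <- lapply(chroms, function(ch) {
        len <- config@chromLengths[[ch]]
        n <- round(len * config@snpDensity / 1000)
        if (n < 1)
            stop("snpDensity yields zero SNPs on chromosome ", ch)
        data.frame(chrom = ch,
                   pos = sort(sample.int(len, n)),
                   stringsAsFactors = FALSE)
    })
    variants <- do.call(rbind, pieces)
    nv <- nrow(variants); ns <- config@nSamples
    variants$af <- runif(nv, config@mafRange[1], config@mafRange[2])
    calls <- matrix(rbinom(nv * ns, 2L, variants$af), nrow = nv, ncol = ns,
                    dimnames = list(NULL, sprintf("S%03d", seq_len(ns))))
    if (config@missingRate > 0)
        calls[runif(nv * ns) < config@missingRate] <- NA_integer_
    variants$ref <- "A"; variants$alt <- "G"   # placeholder alleles
    GenotypeMatrix(calls, variants)
}

#' Plant autozygous tracts into a genotype matrix
#'
#' Inside each truth tract, every SNP of the carrier sample is set
#' homozygous with the allele drawn by its population frequency (an
#' identity-by-descent draw: alternate homozygote with probability equal
#' to the SNP's alternate-allele frequency). Heterozygote miscalls are
#' then sprinkled at \code{hetErrorRate} and missingness applied at
#' \code{missingRate} within the tract. Overlapping tracts of the same
#' sample are merged with a warning.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param tracts data.frame with columns \code{sample}, \code{chrom},
#'   \code{start_bp}, \code{end_bp} (1-based inclusive), as produced by
#'   \code{\link{designPopulation}}.
#' @param config a \linkS4class{SimulationConfig} (error/missing rates).
#' @param seed overrides \code{config@seed}; \code{NULL} keeps the
#'   current RNG state.
#' @return the modified \linkS4class{GenotypeMatrix}.
#' @export
plantTracts <- function(gm, tracts, config, seed = config@seed) {
    stopifnot(is(gm, "GenotypeMatrix"))
    if (!is.null(seed)) set.seed(seed)
    if (!nrow(tracts)) return(gm)
    tracts <- .mergeOverlappingTracts(tracts)
    vm <- variantMap(gm)
    af <- alleleFreqs(gm)
    calls <- genotypeCalls(gm)
    for (k in seq_len(nrow(tracts))) {
        t <- tracts[k, ]
        j <- match(t$sample, colnames(calls))
        if (is.na(j)) stop("tract sample not in matrix: ", t$sample)
        idx <- which(vm$chrom == t$chrom & vm$pos >= t$start_bp &
                     vm$pos <= t$end_bp)
        if (!length(idx)) next   # tract falls in a marker gap
        g <- rbinom(length(idx), 1L, af[idx]) * 2L
        if (config@hetErrorRate > 0)
            g[runif(length(idx)) < config@hetErrorRate] <- 1L
        if (config@missingRate > 0)
            g[runif(length(idx)) < config@missingRate] <- NA_integer_
        calls[idx, j] <- g
    }
    out <- GenotypeMatrix(calls, vm)
    S4Vectors::metadata(out) <- S4Vectors::metadata(gm)
    out
}

.mergeOverlappingTracts <- function(tracts) {
    key <- paste(tracts$sample, tracts$chrom)
    merged <- lapply(split(tracts, key), function(d) {
        d <- d[order(d$start_bp), , drop = FALSE]
        overlaps <- nrow(d) > 1 &&
            any(d$start_bp[-1] <= cummax(d$end_bp)[-nrow(d)])
        if (overlaps) {
            warning("overlapping tracts for sample ", d$sample[1],
                    " on chromosome ", d$chrom[1], " merged")
            ir <- IRanges::reduce(IRanges::IRanges(d$start_bp, d$end_bp))
            d <- data.frame(sample = d$sample[1], chrom = d$chrom[1],
                            start_bp = IRanges::start(ir),
                            end_bp = IRanges::end(ir),
                            stringsAsFactors = FALSE)
        }
        d
    })
    out <- do.call(rbind, merged)
    rownames(out) <- NULL
    out
}

# length classes used when designing tracts, in Mb
.designClassRanges <- list(small = c(0.2, 0.3), medium = c(0.3, 1.5),
                           large = c(1.5, 4.0))

#' Design planted autozygous tracts that reach a target inbreeding level
#'
#' Draws, per sample, tract lengths from a mixture of length classes
#' (small/medium/large, matching the ROH length classification) until the
#' planted total reaches \code{targetFroh} times the genome length, then
#' places the tracts non-overlapping on the chromosomes with uniformly
#' distributed spacing. The stopping rule overshoots by at most one tract
#' length. Default mixture weights (0.45/0.53/0.02 by count) follow the
#' class proportions typical of resequencing-scale ROH tables; the small
#' class is drawn above 0.2 Mb so that every planted tract is in
#' principle callable at default segment filters.
#'
#' @param targetFroh target genomic inbreeding coefficient in [0, 0.6].
#' @param config a \linkS4class{SimulationConfig}.
#' @param lengthMix named numeric proportions for classes small, medium,
#'   large (must sum to 1).
#' @param seed overrides \code{config@seed}; \code{NULL} keeps the RNG
#'   state.
#' @return data.frame of truth tracts: \code{sample}, \code{chrom},
#'   \code{start_bp}, \code{end_bp}, \code{length_bp},
#'   \code{design_class}. Empty for \code{targetFroh = 0}.
#' @export
designPopulation <- function(targetFroh, config,
                             lengthMix = c(small = 0.45, medium = 0.53,
                                           large = 0.02),
                             seed = config@seed) {
    stopifnot(is(config, "SimulationConfig"))
    if (targetFroh < 0 || targetFroh > 0.6)
        stop("targetFroh must lie in [0, 0.6]")
    if (abs(sum(lengthMix) - 1) > 1e-8)
        stop("lengthMix proportions must sum to 1")
    if (!is.null(seed)) set.seed(seed)
    empty <- data.frame(sample = character(0), chrom = character(0),
                        start_bp = numeric(0), end_bp = numeric(0),
                        length_bp = numeric(0), design_class = character(0),
                        stringsAsFactors = FALSE)
    if (targetFroh == 0) return(empty)
    genome <- sum(config@chromLengths)
    target <- targetFroh * genome
    classes <- names(.designClassRanges)
    mix <- lengthMix[classes]
    samples <- sprintf("S%03d", seq_len(config@nSamples))
    out <- vector("list", config@nSamples)
    for (s in seq_along(samples)) {
        lens <- numeric(0); cls <- character(0)
        while (sum(lens) < target) {
            cl <- sample(classes, 1L, prob = mix)
            rg <- .designClassRanges[[cl]]
            lens <- c(lens, runif(1, rg[1], rg[2]) * 1e6)
            cls <- c(cls, cl)
        }
        placed <- .placeTracts(lens, config@chromLengths)
        if (is.null(placed))
            stop("designPopulation: target FROH unreachable on the given chromosomes")
        out[[s]] <- data.frame(sample = samples[s], chrom = placed$chrom,
                               start_bp = placed$start, end_bp = placed$end,
                               length_bp = lens, design_class = cls,
                               stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res[order(res$sample, match(res$chrom, names(config@chromLengths)),
              res$start_bp), , drop = FALSE]
}

# assign tract lengths to chromosomes (capacity-proportional), then lay
# them out with uniformly broken gaps; returns NULL when they cannot fit
.placeTracts <- function(lens, chromLengths) {
    free <- chromLengths
    assign <- character(length(lens))
    for (i in order(lens, decreasing = TRUE)) {
        ok <- names(free)[free >= lens[i]]
        if (!length(ok)) return(NULL)
        ch <- if (length(ok) == 1L) ok else
            sample(ok, 1L, prob = free[ok])
        assign[i] <- ch
        free[ch] <- free[ch] - lens[i]
    }
    res <- data.frame(chrom = assign, start = NA_real_, end = NA_real_,
                      stringsAsFactors = FALSE)
    for (ch in unique(assign)) {
        idx <- which(assign == ch)
        l <- lens[idx]
        slack <- chromLengths[[ch]] - sum(l)
        cuts <- sort(runif(length(l), 0, 1)) * slack
        starts <- floor(cuts + cumsum(c(0, l[-length(l)]))) + 1
        res$start[idx] <- starts
        res$end[idx] <- starts + round(l) - 1
    }
    res
}

#' Simulate a full population with planted autozygosity
#'
#' Convenience wrapper: designs truth tracts for the target FROH, draws
#' the Hardy-Weinberg background and plants the tracts, deriving the
#' three stage seeds from the single config seed.
#'
#' @inheritParams designPopulation
#' @return list with elements \code{gm} (the
#'   \linkS4class{GenotypeMatrix}) and \code{truth} (the tract
#'   data.frame).
#' @examples
#' cfg <- simulationConfig(4, c("1" = 2e7), snpDensity = 0.2, seed = 7)
#' sim <- simulatePopulation(0.1, cfg)
#' table(sim$truth$design_class)
#' @export
simulatePopulation <- function(targetFroh, config,
                               lengthMix = c(small = 0.45, medium = 0.53,
                                             large = 0.02)) {
    truth <- designPopulation(targetFroh, config, lengthMix,
                              seed = config@seed)
    gm <- simulateBackground(config, seed = config@seed + 1L)
    gm <- plantTracts(gm, truth, config, seed = config@seed + 2L)
    list(gm = gm, truth = truth)
}

#' Snap tract boundaries to marker positions
#'
#' Adds \code{snap_start}/\code{snap_end} columns: the first and last
#' marker positions inside each tract (NA when the tract covers no
#' marker). The raw design interval is retained for overlap scoring.
#'
#' @param tracts truth-tract data.frame.
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @return the tract data.frame with snapped coordinates.
#' @export
snapTracts <- function(tracts, gm) {
    vm <- variantMap(gm)
    tracts$snap_start <- NA_real_; tracts$snap_end <- NA_real_
    for (k in seq_len(nrow(tracts))) {
        p <- vm$pos[vm$chrom == tracts$chrom[k] &
                    vm$pos >= tracts$start_bp[k] & vm$pos <= tracts$end_bp[k]]
        if (length(p)) {
            tracts$snap_start[k] <- min(p)
            tracts$snap_end[k] <- max(p)
        }
    }
    tracts
}

#' Score called ROH segments against planted truth tracts
#'
#' A truth tract is recovered when some called segment of the same
#' sample attains at least \code{minReciprocalOverlap} in both
#' directions (overlap / called length and overlap / truth length); a
#' called segment is a true positive when it matches some truth tract
#' the same way. Also reports the fraction of planted tract length
#' covered by calls (length sensitivity) and the ratio of total called
#' to total planted length.
#'
#' @param called segment data.frame (\code{\link{callROH}}).
#' @param truth truth-tract data.frame (\code{\link{designPopulation}}).
#' @param minReciprocalOverlap reciprocal-overlap threshold in (0, 1].
#' @return list with \code{perClass} (data.frame: class, n_truth,
#'   n_recovered, sensitivity), \code{sensitivity}, \code{precision},
#'   \code{lengthSensitivity} (planted length covered / planted length),
#'   \code{lengthRatio} (called / planted total length). Undefined
#'   quantities (no truth, or no calls for precision) are NA.
#' @export
evaluateRecovery <- function(called, truth, minReciprocalOverlap = 0.5) {
    hasTruth <- nrow(truth) > 0
    hasCalls <- nrow(called) > 0
    classes <- if ("design_class" %in% names(truth)) truth$design_class
               else rep("all", nrow(truth))
    recovered <- logical(nrow(truth))
    matchedCall <- logical(nrow(called))
    covered <- 0
    if (hasTruth && hasCalls) {
        for (i in seq_len(nrow(truth))) {
            sel <- called$sample == truth$sample[i] &
                   called$chrom == truth$chrom[i]
            if (!any(sel)) next
            cs <- called[sel, , drop = FALSE]
            ov <- pmin(cs$end_bp, truth$end_bp[i]) -
                  pmax(cs$start_bp, truth$start_bp[i]) + 1
            ov[ov < 0] <- 0
            covered <- covered + sum(ov)
            lenT <- truth$end_bp[i] - truth$start_bp[i] + 1
            lenC <- cs$end_bp - cs$start_bp + 1
            hit <- ov / lenC >= minReciprocalOverlap &
                   ov / lenT >= minReciprocalOverlap
            recovered[i] <- any(hit)
            matchedCall[which(sel)[hit]] <- TRUE
        }
    } else if (hasTruth && !hasCalls) {
        recovered[] <- FALSE
    }
    perClass <- do.call(rbind, lapply(unique(classes), function(cl) {
        sel <- classes == cl
        data.frame(class = cl, n_truth = sum(sel),
                   n_recovered = sum(recovered[sel]),
                   sensitivity = if (any(sel)) mean(recovered[sel]) else NA_real_)
    }))
    totalTruth <- if (hasTruth) sum(truth$end_bp - truth$start_bp + 1) else 0
    totalCalled <- if (hasCalls) sum(called$end_bp - called$start_bp + 1) else 0
    list(perClass = perClass,
         sensitivity = if (hasTruth) mean(recovered) else NA_real_,
         precision = if (hasCalls) mean(matchedCall) else NA_real_,
         lengthSensitivity = if (totalTruth > 0) covered / totalTruth else NA_real_,
         lengthRatio = if (totalTruth > 0) totalCalled / totalTruth else NA_real_)
}
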