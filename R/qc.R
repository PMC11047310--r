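#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value is the summed probability of every heterozygote count no more
#' probable than the observed one, under the hypergeometric-type
#' distribution of heterozygote counts given the allele counts (the
#' standard exact HWE test used for genotype QC). Monomorphic sites have
#' a single attainable configuration and return 1.
#'
#' @param nHomRef,nHet,nHomAlt genotype counts at one SNP (vectors are
#'   recycled elementwise).
#' @return numeric vector of p-values in (0, 1]. A site with zero
#'   non-missing genotypes is undefined and returns NA (such SNPs are
#'   kept, not tested, by \code{\link{applyQC}}).
#' @examples
#' hweExactP(25, 50, 25)   # perfect HWE proportions -> 1
#' hweExactP(50, 0, 50)    # complete heterozygote deficit -> ~0
#' @export
hweExactP <- function(nHomRef, nHet, nHomAlt) {
    n <- max(length(nHomRef), length(nHet), length(nHomAlt))
    nHomRef <- rep_len(nHomRef, n); nHet <- rep_len(nHet, n)
    nHomAlt <- rep_len(nHomAlt, n)
    vapply(seq_len(n), function(i)
        .hweExactP1(nHomRef[i], nHet[i], nHomAlt[i]), numeric(1))
}

.hweExactP1 <- function(nAA, nAB, nBB) {
    if (anyNA(c(nAA, nAB, nBB))) return(NA_real_)
    if (any(c(nAA, nAB, nBB) < 0)) stop("genotype counts must be >= 0")
    N <- nAA + nAB + nBB
    if (N == 0) return(NA_real_)
    nA <- 2 * nAA + nAB
    n1 <- min(nA, 2 * N - nA)          # rare allele count
    if (n1 == 0) return(1)             # monomorphic: single configuration
    hets <- seq(n1 %% 2, n1, by = 2)   # attainable heterozygote counts
    # log P(h | n1, N) up to a constant; normalised below
    logp <- lgamma(N + 1) - lgamma((n1 - hets) / 2 + 1) - lgamma(hets + 1) -
        lgamma(N - (n1 + hets) / 2 + 1) + hets * log(2)
    logp <- logp - max(logp)
    p <- exp(logp); p <- p / sum(p)
    obs <- p[match(nAB, hets)]
    if (is.na(obs)) stop("impossible heterozygote count for the allele counts")
    min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Construct QC parameters
#'
#' Two profiles mirror common practice for resequencing panels:
#' \code{"structure"} keeps the MAF filter at 0.05 (population-structure
#' analyses), \code{"roh"} disables MAF filtering so that low-frequency
#' markers inside homozygous runs are retained. Individual thresholds can
#' be overridden; set a threshold to \code{NA} to disable that filter.
#'
#' @param profile \code{"roh"} (default) or \code{"structure"}.
#' @param maxSampleMissing,maxGenoMissing,hwePThreshold,minMAF override
#'   the profile's thresholds (see \linkS4class{QCParams}).
#' @return a \linkS4class{QCParams} object.
#' @examples
#' qcParams("structure")
#' qcParams("roh")           # minMAF disabled
#' @export
qcParams <- function(profile = c("roh", "structure"),
                     maxSampleMissing = 0.1, maxGenoMissing = 0.1,
                     hwePThreshold = 1e-3, minMAF = NULL) {
    profile <- match.arg(profile)
    if (is.null(minMAF))
        minMAF <- if (profile == "structure") 0.05 else NA_real_
    new("QCParams",
        maxSampleMissing = as.numeric(maxSampleMissing),
        maxGenoMissing = as.numeric(maxGenoMissing),
        hwePThreshold = as.numeric(hwePThreshold),
        minMAF = as.numeric(minMAF))
}

#' Apply SNP and sample quality control
#'
#' Filters are applied in a fixed, logged order: (1) drop samples with
#' missing-call fraction above \code{maxSampleMissing}; (2) drop SNPs
#' with missing fraction above \code{maxGenoMissing} (recomputed on the
#' retained samples); (3) drop SNPs failing the exact Hardy-Weinberg test
#' at \code{hwePThreshold} (computed on the pooled sample set; SNPs with
#' no non-missing calls are kept untested); (4) if \code{minMAF} is set,
#' drop SNPs below it. Setting a threshold to \code{NA} disables that
#' step. The per-step removal counts are attached as the QC report
#' (\code{\link{qcReport}}). Running \code{applyQC} a second time with
#' the same parameters changes nothing.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param params a \linkS4class{QCParams} object.
#' @return the filtered \linkS4class{GenotypeMatrix} with the report in
#'   its metadata. If a step removes every SNP an error names that step.
#' @export
applyQC <- function(gm, params = qcParams()) {
    stopifnot(is(gm, "GenotypeMatrix"), is(params, "QCParams"))
    if (!nrow(gm) || !ncol(gm)) stop("applyQC: empty genotype matrix")
    report <- data.frame(step = character(0), removed = integer(0),
                         remaining = integer(0), stringsAsFactors = FALSE)
    note <- function(step, removed, remaining)
        rbind(report, data.frame(step = step, removed = removed,
                                 remaining = remaining))

    gt <- genotypeCalls(gm)

    # 1. sample missingness
    dropS <- logical(ncol(gt))
    if (!is.na(params@maxSampleMissing))
        dropS <- colMeans(is.na(gt)) > params@maxSampleMissing
    report <- note("sample_missingness", sum(dropS), ncol(gt) - sum(dropS))
    gm2 <- gm[, !dropS]
    gt <- genotypeCalls(gm2)
    keep <- rep(TRUE, nrow(gt))

    fail <- function(step) stop("applyQC: step '", step,
                                "' removed every SNP; nothing left to analyse")

    # 2. SNP missingness
    if (!is.na(params@maxGenoMissing) && ncol(gt)) {
        bad <- rowMeans(is.na(gt[keep, , drop = FALSE])) > params@maxGenoMissing
        report <- note("snp_missingness", sum(bad), sum(keep) - sum(bad))
        keep[keep] <- !bad
        if (!any(keep)) fail("snp_missingness")
    } else report <- note("snp_missingness", 0L, sum(keep))

    # 3. exact HWE
    if (!is.na(params@hwePThreshold) && ncol(gt)) {
        sub <- gt[keep, , drop = FALSE]
        p <- hweExactP(rowSums(sub == 0L, na.rm = TRUE),
                       rowSums(sub == 1L, na.rm = TRUE),
                       rowSums(sub == 2L, na.rm = TRUE))
        bad <- !is.na(p) & p < params@hwePThreshold
        report <- note("hwe_exact", sum(bad), sum(keep) - sum(bad))
        keep[keep] <- !bad
        if (!any(keep)) fail("hwe_exact")
    } else report <- note("hwe_exact", 0L, sum(keep))

    # 4. minor allele frequency (disabled for the "roh" profile)
    if (!is.na(params@minMAF) && ncol(gt)) {
        sub <- gt[keep, , drop = FALSE]
        af <- rowMeans(sub, na.rm = TRUE) / 2
        maf <- pmin(af, 1 - af)
        bad <- is.na(maf) | maf < params@minMAF
        report <- note("maf", sum(bad), sum(keep) - sum(bad))
        keep[keep] <- !bad
        if (!any(keep)) fail("maf")
    } else report <- note("maf", 0L, sum(keep))

    out <- gm2[keep, ]
    out <- as(out, "GenotypeMatrix")
    S4Vectors::metadata(out)$qcReport <- report
    out
}
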