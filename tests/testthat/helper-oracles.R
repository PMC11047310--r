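# Independent oracles used to verify the package's implementations.
# They deliberately take different computational routes.

# Exact HWE p-value by recurrence over heterozygote counts (the
# implementation uses direct log-gamma evaluation instead).
hweOracleP <- function(nAA, nAB, nBB) {
    N <- nAA + nAB + nBB
    if (N == 0) return(NA_real_)
    nA <- 2 * nAA + nAB
    n1 <- min(nA, 2 * N - nA)
    if (n1 == 0) return(1)
    hets <- seq(n1 %% 2, n1, by = 2)
    w <- numeric(length(hets))
    w[1] <- 1
    if (length(hets) > 1) {
        for (k in seq_len(length(hets) - 1)) {
            h <- hets[k]
            homR <- (n1 - h) / 2          # rare-allele homozygotes at h
            homC <- N - homR - h          # common-allele homozygotes at h
            # P(h+2)/P(h) = 4*homR*homC / ((h+2)*(h+1))
            w[k + 1] <- w[k] * 4 * homR * homC / ((h + 2) * (h + 1))
        }
    }
    p <- w / sum(w)
    obs <- p[match(nAB, hets)]
    min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

# Brute-force sliding-window ROH caller: explicit loops over windows and
# SNPs, then naive run assembly, gap splitting, trimming and filtering.
rohOracleEligibility <- function(g, pos, params) {
    n <- length(g)
    W <- params@windowSnp
    isHet <- function(x) !is.na(x) & x == 1L
    winOK <- function(i, j) {
        sum(isHet(g[i:j])) <= params@windowHetMax &&
            sum(is.na(g[i:j])) <= params@windowMissingMax
    }
    if (n == 0) return(logical(0))
    if (n < W) return(rep(winOK(1, n), n))
    ok <- vapply(seq_len(n - W + 1), function(s) winOK(s, s + W - 1), logical(1))
    vapply(seq_len(n), function(i) {
        starts <- max(1, i - W + 1):min(i, n - W + 1)
        mean(ok[starts]) >= params@windowThreshold
    }, logical(1))
}

rohOracleCall <- function(g, pos, params) {
    elig <- rohOracleEligibility(g, pos, params)
    hom <- !is.na(g) & g != 1L
    segs <- list()
    i <- 1; n <- length(g)
    while (i <= n) {
        if (!elig[i]) { i <- i + 1; next }
        j <- i
        while (j < n && elig[j + 1]) j <- j + 1
        # split at long gaps
        pieces <- list(); a <- i
        for (k in i:j) {
            if (k < j && pos[k + 1] - pos[k] > params@maxGapKb * 1000) {
                pieces[[length(pieces) + 1]] <- c(a, k); a <- k + 1
            }
        }
        pieces[[length(pieces) + 1]] <- c(a, j)
        for (pc in pieces) {
            s <- pc[1]; e <- pc[2]
            while (s <= e && !hom[s]) s <- s + 1
            while (e >= s && !hom[e]) e <- e - 1
            if (s > e) next
            nSnp <- e - s + 1
            kb <- (pos[e] - pos[s] + 1) / 1000
            if (nSnp >= params@minSnp && kb >= params@minLengthKb &&
                kb / nSnp <= params@maxDensityKbPerSnp)
                segs[[length(segs) + 1]] <-
                    data.frame(start_bp = pos[s], end_bp = pos[e],
                               n_snps = nSnp, length_kb = kb)
        }
        i <- j + 1
    }
    if (!length(segs))
        return(data.frame(start_bp = numeric(0), end_bp = numeric(0),
                          n_snps = integer(0), length_kb = numeric(0)))
    out <- do.call(rbind, segs)
    rownames(out) <- NULL
    out
}

# random one-chromosome instance for caller equivalence checks;
# genotype mix tuned so eligible runs, gaps and near-threshold windows
# all actually occur
randomRohInstance <- function(seed) {
    set.seed(seed)
    n <- sample(60:300, 1)
    gaps <- sample(c(sample(500:20000, n - 1, replace = TRUE)), n - 1)
    if (runif(1) < 0.5)   # sprinkle a few gap-splitting jumps
        gaps[sample(n - 1, sample(1:3, 1))] <- sample(450000:900000, 1)
    pos <- cumsum(c(sample(1:1000, 1), gaps))
    pHet <- runif(1, 0, 0.25)
    pMis <- runif(1, 0, 0.08)
    g <- sample(c(0L, 2L), n, replace = TRUE)
    r <- runif(n)
    g[r < pHet] <- 1L
    g[r > 1 - pMis] <- NA_integer_
    params <- rohCallParams(
        windowSnp = sample(c(20L, 50L), 1),
        windowHetMax = sample(0:2, 1),
        windowMissingMax = sample(c(2L, 5L), 1),
        windowThreshold = sample(c(0.05, 0.2), 1),
        minSnp = sample(c(10L, 30L), 1),
        minLengthKb = sample(c(50, 200), 1),
        maxDensityKbPerSnp = sample(c(30, 60), 1),
        maxGapKb = sample(c(100, 500), 1))
    list(g = g, pos = pos, params = params)
}

# tiny VCF writer for I/O tests
writeTestVCF <- function(path, records, samples = c("s1", "s2")) {
    hdr <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
    writeLines(c(hdr, records), path)
    path
}

vcfRecord <- function(chrom, pos, ref, alt, gts, id = ".") {
    paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
          collapse = "\t")
}
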