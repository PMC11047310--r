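trackOf <- function(pos, incidence, chrom = "1")
    data.frame(chrom = chrom, pos = pos, incidence = incidence,
               stringsAsFactors = FALSE)

test_that("incidence is the per-SNP fraction of covered individuals", {
    variants <- data.frame(chrom = "1", pos = 1:30 * 1e4)
    none <- rohIncidence(.emptySegs <- data.frame(sample = character(0),
        chrom = character(0), start_bp = numeric(0), end_bp = numeric(0),
        n_snps = integer(0), length_kb = numeric(0)), variants, c("a", "b"))
    expect_true(all(none$incidence == 0))

    segs <- data.frame(sample = "a", chrom = "1",
                       start_bp = 1e5, end_bp = 2e5, n_snps = 11L,
                       length_kb = 100.001)
    one <- rohIncidence(segs, variants, "a")
    expect_equal(one$incidence, as.numeric(variants$pos >= 1e5 &
                                           variants$pos <= 2e5))
    expect_error(rohIncidence(segs, variants, character(0)), "empty")
})

test_that("incidence equals a naive per-SNP membership count", {
    set.seed(8)
    samples <- paste0("s", 1:12)
    segs <- do.call(rbind, lapply(samples, function(s) {
        n <- sample(0:4, 1)
        if (!n) return(NULL)
        start <- sort(sample(1:80, n)) * 1e4
        len <- sample(5:20, n, replace = TRUE) * 1e4
        # keep per-sample segments disjoint
        start <- start + cumsum(c(0, rep(3e5, n - 1)))
        data.frame(sample = s, chrom = sample(c("1", "2"), n, replace = TRUE),
                   start_bp = start, end_bp = start + len,
                   n_snps = 50L, length_kb = len / 1000)
    }))
    variants <- data.frame(chrom = rep(c("1", "2"), each = 150),
                           pos = rep(1:150 * 1e4, 2))
    got <- rohIncidence(segs, variants, samples)
    naive <- vapply(seq_len(nrow(variants)), function(i) {
        covered <- vapply(samples, function(s) {
            d <- segs[segs$sample == s & segs$chrom == variants$chrom[i], ,
                      drop = FALSE]
            any(d$start_bp <= variants$pos[i] & d$end_bp >= variants$pos[i])
        }, logical(1))
        sum(covered) / length(samples)
    }, numeric(1))
    expect_equal(got$incidence, naive)
})

test_that("the island threshold is the nearest-rank top-fraction value", {
    inc <- c(rep(0.1, 9990), rep(0.9, 10))
    track <- trackOf(seq_along(inc) * 100, inc)
    thr <- islandThreshold(track, 0.001)
    expect_equal(thr, 0.9)
    # ties at the threshold are excluded under the strict comparison
    expect_equal(nrow(callIslands(track, thr)), 0)

    # constant track: nothing strictly exceeds the threshold
    flat <- trackOf(1:500 * 100, rep(0.4, 500))
    expect_equal(nrow(callIslands(flat, islandThreshold(flat))), 0)

    # seeded random track: nearest rank vs explicit sort
    set.seed(13)
    inc <- runif(5000)
    track <- trackOf(1:5000 * 100, inc)
    k <- ceiling(0.001 * 5000)
    expect_equal(islandThreshold(track, 0.001),
                 sort(inc, decreasing = TRUE)[k])
})

test_that("islands are maximal contiguous runs above threshold", {
    inc <- rep(0.1, 40)
    inc[10:14] <- 0.8; inc[16:18] <- 0.8   # broken by one low SNP at 15
    inc[30] <- 0.9                          # lone qualifying SNP
    track <- trackOf(1:40 * 1e4, inc)
    isl <- callIslands(track, 0.5, minSnps = 2)
    expect_equal(nrow(isl), 2)              # the lone SNP is dropped
    expect_equal(isl$start_bp, c(10e4, 16e4))
    expect_equal(isl$end_bp, c(14e4, 18e4))
    expect_equal(isl$n_snps, c(5L, 3L))
    # flanking SNPs do not qualify
    expect_true(all(inc[c(9, 15, 19)] <= 0.5))
    # with minSnps = 1 the lone SNP becomes an island
    expect_equal(nrow(callIslands(track, 0.5, minSnps = 1)), 3)
})

test_that("at most the top fraction of SNPs (minus ties) can seed islands", {
    for (seed in 1:20) {
        set.seed(seed)
        n <- 4000
        inc <- round(runif(n), 3)
        track <- trackOf(seq_len(n) * 250, inc)
        thr <- islandThreshold(track, 0.001)
        expect_lte(sum(inc > thr), ceiling(0.001 * n))
    }
})

test_that("gene annotation lists 1-bp overlaps but not abutting intervals", {
    isl <- data.frame(chrom = "1", start_bp = 1e6, end_bp = 2e6,
                      n_snps = 10L, peak_incidence = 0.8)
    genes <- GenomicRanges::GRanges("1", IRanges::IRanges(
        start = c(2e6, 2e6 + 1, 5e5, 1.5e6),
        end = c(2.5e6, 2.5e6, 2.5e6, 1.6e6)))
    names(genes) <- c("OVER1BP", "ABUT", "CONTAINS", "INSIDE")
    got <- annotateIntervals(isl, genes)$genes
    expect_equal(got, "OVER1BP,CONTAINS,INSIDE")

    # BED input is half-open: a gene ending where the island starts
    # (in BED coordinates) does not overlap
    bed <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("1\t500000\t999999\tBEFORE", "1\t999999\t1500000\tHITS"), bed)
    got2 <- annotateIntervals(isl, bed)$genes
    expect_equal(got2, "HITS")
})

test_that("random island-gene joins match a quadratic all-pairs oracle", {
    set.seed(33)
    isl <- data.frame(chrom = sample(c("1", "2"), 15, replace = TRUE),
                      start_bp = sample(1:500, 15) * 1e4)
    isl$end_bp <- isl$start_bp + sample(1:80, 15) * 1e4
    isl$n_snps <- 5L; isl$peak_incidence <- 0.5
    gpos <- sample(1:600, 40) * 1e4
    genes <- GenomicRanges::GRanges(sample(c("1", "2"), 40, replace = TRUE),
                                    IRanges::IRanges(gpos, gpos + 5e4))
    names(genes) <- paste0("G", 1:40)
    got <- annotateIntervals(isl, genes)$genes
    for (i in seq_len(nrow(isl))) {
        hits <- names(genes)[as.character(GenomicRanges::seqnames(genes)) ==
                isl$chrom[i] &
                GenomicRanges::start(genes) <= isl$end_bp[i] &
                GenomicRanges::end(genes) >= isl$start_bp[i]]
        want <- paste(unique(hits), collapse = ",")
        expect_equal(got[i], want, info = paste("island", i))
    }
})

test_that("a tract shared by most samples surfaces as one island", {
    # 20 samples, 18 carriers with nested tract extents around a common
    # core: incidence decays with distance from the core, so exactly one
    # contiguous region exceeds the top-0.1% threshold. The genome must
    # be large enough that the 0.1% tail holds more SNPs than the shared
    # core, otherwise the threshold ties with the core plateau and the
    # strict comparison empties the island (a documented property of
    # nearest-rank thresholds on plateaued incidence).
    cfg <- simulationConfig(20, setNames(rep(7.5e7, 6), as.character(1:6)),
                            snpDensity = 0.2, seed = 505)
    gm <- simulateBackground(cfg)
    center <- 2.4e7
    halfWidths <- 1e5 + (1:18) * 2.5e4
    tracts <- data.frame(sample = sprintf("S%03d", 1:18), chrom = "1",
                         start_bp = center - halfWidths,
                         end_bp = center + halfWidths)
    gm <- plantTracts(gm, tracts, cfg, seed = 506)
    segs <- callROH(gm)
    popmap <- setNames(rep("POP", 20), sampleIDs(gm))
    scan <- islandScan(segs, gm, popmap)
    isl <- scan$POP$islands
    expect_equal(nrow(isl), 1)
    expect_equal(isl$chrom, "1")
    expect_gt(isl$peak_incidence, 0.8)
    expect_true(isl$start_bp <= center && isl$end_bp >= center)
    expect_gte(isl$start_bp, center - max(halfWidths))
    expect_lte(isl$end_bp, center + max(halfWidths))
})
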