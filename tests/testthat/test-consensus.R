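seg <- function(sample, chrom, start, end)
    data.frame(sample = sample, chrom = chrom, start_bp = start,
               end_bp = end, n_snps = 50L, length_kb = (end - start + 1) / 1000,
               stringsAsFactors = FALSE)

test_that("identical segments in two animals pool with CON = UNION", {
    segs <- rbind(seg("a", "1", 1e6, 2e6), seg("b", "1", 1e6, 2e6))
    res <- poolSegments(segs)
    expect_equal(nrow(res$pools), 1)
    expect_equal(res$pools$con_start, 1e6)
    expect_equal(res$pools$con_end, 2e6)
    expect_equal(res$pools$union_start, 1e6)
    expect_equal(res$pools$union_end, 2e6)
    expect_equal(res$pools$n_animals, 2L)

    # disjoint segments never pool
    apart <- rbind(seg("a", "1", 1e6, 2e6), seg("b", "1", 3e6, 4e6))
    expect_equal(nrow(poolSegments(apart)$pools), 0)
    expect_equal(nrow(poolSegments(segs[0, ])$pools), 0)
})

test_that("the greedy staircase trace is reproduced exactly", {
    # Four overlapping segments with an empty 4-way intersection.
    # Hand trace of the pooling rule: C overlaps A, B and D (3 overlaps,
    # the maximum) and seeds the pool. Candidates in (start, end) order:
    # A [100,1000] intersects CON=[900,2000] -> CON [900,1000];
    # B [500,1500] intersects -> CON stays [900,1000];
    # D [1600,2600] misses the running CON -> rejected.
    # Pool = {A,B,C}, CON [900,1000], UNION [100,2000]; D stays unpooled.
    segs <- rbind(seg("a", "1", 100, 1000),
                  seg("b", "1", 500, 1500),
                  seg("c", "1", 900, 2000),
                  seg("d", "1", 1600, 2600))
    res <- poolSegments(segs)
    expect_equal(nrow(res$pools), 1)
    expect_equal(res$pools$con_start, 900)
    expect_equal(res$pools$con_end, 1000)
    expect_equal(res$pools$union_start, 100)
    expect_equal(res$pools$union_end, 2000)
    expect_setequal(res$members$sample, c("a", "b", "c"))
})

test_that("pool geometry invariants hold on random inputs", {
    for (rep in 1:15) {
        set.seed(600 + rep)
        n <- sample(10:40, 1)
        start <- sample(1:300, n, replace = TRUE) * 1e4
        segs <- data.frame(sample = sample(paste0("s", 1:8), n, replace = TRUE),
                           chrom = sample(c("1", "2"), n, replace = TRUE),
                           start_bp = start,
                           end_bp = start + sample(20:150, n, replace = TRUE) * 1e4,
                           n_snps = 50L, length_kb = 1)
        segs$length_kb <- (segs$end_bp - segs$start_bp + 1) / 1000
        res <- poolSegments(segs)
        for (id in res$pools$pool_id) {
            p <- res$pools[res$pools$pool_id == id, ]
            m <- res$members[res$members$pool_id == id, ]
            expect_gte(nrow(m), 2)
            # CON inside every member, every member inside UNION
            expect_true(all(m$start_bp <= p$con_start & m$end_bp >= p$con_end))
            expect_true(all(m$start_bp >= p$union_start &
                            m$end_bp <= p$union_end))
            expect_equal(p$n_animals, length(unique(m$sample)))
        }
        # each segment belongs to at most one pool
        key <- paste(res$members$sample, res$members$chrom,
                     res$members$start_bp, res$members$end_bp)
        expect_false(anyDuplicated(key) > 0)

        # permutation invariance
        perm <- segs[sample(nrow(segs)), ]
        res2 <- poolSegments(perm)
        expect_equal(res2$pools, res$pools, ignore_attr = TRUE)
    }
})

test_that("consensus filters are strict on both thresholds", {
    pools <- data.frame(pool_id = c("P1", "P2", "P3", "P4"),
                        chrom = "1",
                        con_start = 1e6,
                        con_end = 1e6 + c(9e4, 2e5, 2e5, 2e5) - 1,
                        con_kb = c(90, 200, 200, 200),
                        union_start = 1, union_end = 5e6,
                        n_members = c(25L, 25L, 19L, 18L),
                        n_animals = c(25L, 25L, 19L, 18L))
    ref <- paste0("s", 1:62)   # e.g. two breeds totalling 62 animals
    kept <- filterConsensus(pools, ref)
    # P1: CON 0.09 Mb -> dropped; P3: 19/62 = 0.306 -> kept
    expect_setequal(kept$pool_id, c("P2", "P3"))
    # a fraction of exactly 0.30 fails the strict comparison
    ref20 <- paste0("s", 1:20)
    pools6 <- pools[3, ]; pools6$n_animals <- 6L
    expect_equal(nrow(filterConsensus(pools6, ref20)), 0)
    pools7 <- pools6; pools7$n_animals <- 7L
    expect_equal(nrow(filterConsensus(pools7, ref20)), 1)
})

test_that("consensus report annotates genes and round-trips", {
    segs <- rbind(seg("a", "1", 1e6, 2e6), seg("b", "1", 1.2e6, 2.2e6),
                  seg("c", "1", 1.1e6, 1.9e6))
    res <- poolSegments(segs)
    sel <- filterConsensus(res$pools, c("a", "b", "c"))
    genes <- GenomicRanges::GRanges("1", IRanges::IRanges(1.5e6, 1.6e6))
    names(genes) <- "FGF5LIKE"
    path <- withr::local_tempfile(fileext = ".tsv")
    rep <- consensusReport(sel, res$members,
                           popmap = c(a = "IMC", b = "IMC", c = "HSC"),
                           genes = genes, path = path)
    expect_equal(rep$genes, "FGF5LIKE")
    expect_equal(unname(rep$n_IMC), 2)
    expect_equal(unname(rep$n_HSC), 1)
    back <- read.delim(path)
    expect_equal(back$con_start, rep$con_start)
    expect_equal(back$members, "a,b,c")

    # empty selection: header-only file
    consensusReport(sel[0, ], res$members, path = path)
    expect_equal(length(readLines(path)), 1)
})

test_that("a shared tract is selected iff its sharing fraction exceeds 30%", {
    for (f in c(0.2, 0.3, 0.31, 0.5)) {
        nCar <- round(f * 100)
        cfg <- simulationConfig(100, c("1" = 8e6), snpDensity = 0.4,
                                seed = 800)
        gm <- simulateBackground(cfg)
        carriers <- sprintf("S%03d", seq_len(nCar))
        tracts <- data.frame(sample = carriers, chrom = "1",
                             start_bp = 3e6, end_bp = 4e6)
        gm <- plantTracts(gm, tracts, cfg, seed = 801)
        segs <- callROH(gm)
        pooled <- poolSegments(segs)
        sel <- filterConsensus(pooled$pools, sampleIDs(gm))
        expect_equal(nrow(sel) > 0, f > 0.30,
                     info = sprintf("fraction %.2f", f))
    }
})
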