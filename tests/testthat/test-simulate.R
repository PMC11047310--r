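test_that("simulation is fully determined by the seed", {
    cfg <- simulationConfig(6, c("1" = 5e6, "2" = 4e6), snpDensity = 0.2,
                            hetErrorRate = 0.01, missingRate = 0.02, seed = 9)
    a <- simulatePopulation(0.1, cfg)
    b <- simulatePopulation(0.1, cfg)
    expect_identical(genotypeCalls(a$gm), genotypeCalls(b$gm))
    expect_identical(a$truth, b$truth)
    expect_error(simulationConfig(5, c("1" = 1e6)), "seed")
})

test_that("background genotypes follow Hardy-Weinberg at the drawn frequency", {
    # allele frequency pinned at 0.5: expected heterozygosity 0.5
    cfg <- simulationConfig(200, c("1" = 1e7), snpDensity = 0.1,
                            mafRange = c(0.5, 0.5), seed = 21)
    gm <- simulateBackground(cfg)
    gt <- genotypeCalls(gm)
    nCalls <- length(gt)
    hetRate <- mean(gt == 1L)
    se <- sqrt(0.25 / nCalls)
    expect_lt(abs(hetRate - 0.5), 3 * se)
    # genotype frequencies near (0.25, 0.5, 0.25)
    expect_lt(abs(mean(gt == 0L) - 0.25), 4 * sqrt(0.25 * 0.75 / nCalls))
})

test_that("boundary rates behave: full missingness, zero SNPs", {
    cfg <- simulationConfig(3, c("1" = 1e6), snpDensity = 0.1,
                            missingRate = 1, seed = 4)
    expect_true(all(is.na(genotypeCalls(simulateBackground(cfg)))))
    tiny <- simulationConfig(3, c("1" = 1e6, "2" = 100), snpDensity = 0.1,
                             seed = 4)
    expect_error(simulateBackground(tiny), "zero SNPs")
})

test_that("planted tracts are homozygous and respect error rates", {
    cfg <- simulationConfig(2, c("1" = 2e7), snpDensity = 0.2, seed = 31)
    gm <- simulateBackground(cfg)
    tract <- data.frame(sample = "S001", chrom = "1",
                        start_bp = 5e6, end_bp = 1e7)
    planted <- plantTracts(gm, tract, cfg)
    vm <- variantMap(planted)
    inside <- vm$chrom == "1" & vm$pos >= 5e6 & vm$pos <= 1e7
    g <- genotypeCalls(planted)[inside, "S001"]
    expect_true(all(g %in% c(0L, 2L)))          # error-free: no HET, no NA
    # the other sample is untouched
    expect_identical(genotypeCalls(planted)[, "S002"],
                     genotypeCalls(gm)[, "S002"])
    # a tract covering no marker leaves the matrix unchanged
    gap <- data.frame(sample = "S001", chrom = "1",
                      start_bp = 1, end_bp = 2)   # before the first marker
    expect_identical(genotypeCalls(plantTracts(gm, gap, cfg)),
                     genotypeCalls(gm))
})

test_that("heterozygote sprinkling inside tracts is binomial", {
    # ~1000-SNP tract, het error 1%: mean het count across seeds must sit
    # within 3 SE of the binomial expectation
    nSeeds <- 50
    hets <- numeric(nSeeds)
    nSnps <- numeric(nSeeds)
    for (s in seq_len(nSeeds)) {
        cfg <- simulationConfig(1, c("1" = 1e7), snpDensity = 0.1,
                                hetErrorRate = 0.01, seed = 1000 + s)
        gm <- simulateBackground(cfg)
        tract <- data.frame(sample = "S001", chrom = "1",
                            start_bp = 1, end_bp = 1e7)
        g <- genotypeCalls(plantTracts(gm, tract, cfg))[, 1]
        hets[s] <- sum(g == 1L, na.rm = TRUE)
        nSnps[s] <- length(g)
    }
    expected <- 0.01 * sum(nSnps)
    se <- sqrt(sum(nSnps) * 0.01 * 0.99)
    expect_lt(abs(sum(hets) - expected), 3 * se)
})

test_that("overlapping tracts for one sample are merged with a warning", {
    cfg <- simulationConfig(1, c("1" = 1e7), snpDensity = 0.1, seed = 3)
    gm <- simulateBackground(cfg)
    tracts <- data.frame(sample = "S001", chrom = "1",
                         start_bp = c(1e6, 2e6), end_bp = c(3e6, 4e6))
    expect_warning(plantTracts(gm, tracts, cfg), "merged")
})

test_that("designPopulation hits its total-length target per sample", {
    cfg <- simulationConfig(5, c("1" = 6e7, "2" = 4e7), snpDensity = 0.1,
                            seed = 55)
    expect_equal(nrow(designPopulation(0, cfg)), 0)
    truth <- designPopulation(0.25, cfg)
    maxTract <- 4e6   # upper bound of the large design class
    for (s in unique(truth$sample)) {
        tot <- sum(truth$length_bp[truth$sample == s])
        expect_gte(tot, 0.25 * 1e8)
        expect_lte(tot, 0.25 * 1e8 + maxTract)
        # non-overlapping placement within each chromosome
        for (ch in c("1", "2")) {
            d <- truth[truth$sample == s & truth$chrom == ch, ]
            d <- d[order(d$start_bp), ]
            if (nrow(d) > 1)
                expect_true(all(d$start_bp[-1] > d$end_bp[-nrow(d)]))
            expect_true(all(d$end_bp <= cfg@chromLengths[[ch]]))
        }
    }
    expect_error(designPopulation(0.7, cfg), "targetFroh")
})

test_that("recovery scoring handles identity, misses and thresholds", {
    truth <- data.frame(sample = "S001", chrom = "1",
                        start_bp = 1e6, end_bp = 2e6, design_class = "medium")
    asCalled <- data.frame(sample = "S001", chrom = "1",
                           start_bp = 1e6, end_bp = 2e6, n_snps = 100L,
                           length_kb = 1000.001)
    hit <- evaluateRecovery(asCalled, truth, 0.9)
    expect_equal(hit$sensitivity, 1)
    expect_equal(hit$precision, 1)

    none <- evaluateRecovery(asCalled[0, ], truth, 0.9)
    expect_equal(none$sensitivity, 0)
    expect_true(is.na(none$precision))

    empty <- evaluateRecovery(asCalled[0, ], truth[0, ], 0.9)
    expect_true(is.na(empty$sensitivity) && is.na(empty$precision))

    # a call shifted to 50% overlap misses a 0.7 reciprocal threshold
    shifted <- asCalled
    shifted$start_bp <- 1.5e6; shifted$end_bp <- 2.5e6
    expect_equal(evaluateRecovery(shifted, truth, 0.7)$sensitivity, 0)
    expect_equal(evaluateRecovery(shifted, truth, 0.5)$sensitivity, 1)
})

test_that("pipeline FROH tracks the designed inbreeding monotonically", {
    designs <- c(0.02, 0.1, 0.3)
    means <- vapply(designs, function(f) {
        cfg <- simulationConfig(3, c("1" = 3e7), snpDensity = 0.3,
                                seed = 7000 + round(1000 * f))
        sim <- simulatePopulation(f, cfg)
        segs <- callROH(sim$gm)
        mean(frohPerSample(segs, lAutoMb = 30,
                           samples = sampleIDs(sim$gm))$froh)
    }, numeric(1))
    expect_equal(cor(means, designs, method = "spearman"), 1)
})
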