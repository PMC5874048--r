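oneTxAnn <- function(start, end, strand = "+") {
    grl <- GRangesList(T1 = GRanges("chr1", IRanges(start, end),
                                    strand = strand))
    TranscriptAnnotation(grl, c(T1 = "G1"))
}

test_that("downstream windows tile outward from the 3' end on both strands", {
    cfg <- pipelineConfig(windowSize = 250, nWindows = 2)
    # + strand transcript ending at base 1000
    wP <- placeWindows(oneTxAnn(1, 1000, "+"), cfg)[["T1"]]
    expect_identical(start(wP), c(1001L, 1251L))
    expect_identical(end(wP), c(1250L, 1500L))
    # - strand transcript starting at base 1001: windows walk leftward
    wM <- placeWindows(oneTxAnn(1001, 2000, "-"), cfg)[["T1"]]
    expect_identical(start(wM), c(751L, 501L))
    expect_identical(end(wM), c(1000L, 750L))
    expect_identical(as.character(strand(wM)), c("-", "-"))
})

test_that("the terminal window is the last W nt inside the span", {
    cfg <- pipelineConfig(windowSize = 250, nWindows = 2)
    tP <- placeWindows(oneTxAnn(1, 1000, "+"), cfg, side = "terminal")[["T1"]]
    expect_identical(start(tP), 751L)
    expect_identical(end(tP), 1000L)
    tM <- placeWindows(oneTxAnn(1001, 2000, "-"), cfg,
                       side = "terminal")[["T1"]]
    expect_identical(start(tM), 1001L)
    expect_identical(end(tM), 1250L)
})

test_that("profiles normalize window signal to the terminal window", {
    cfg <- pipelineConfig(windowSize = 250, nWindows = 2)
    ann <- oneTxAnn(1, 500, "+")
    v <- numeric(1000)
    v[251:500] <- 100 / 250            # terminal sums to 100
    v[501:750] <- 44 / 250
    v[751:1000] <- 20 / 250
    ps <- transcriptProfiles(ann, toyCoverage(plus = list(chr1 = v)), cfg)
    expect_equal(ps@terminalSignal, 100)
    expect_equal(unname(ps@windowSignals[1, ]), c(44, 20))
    expect_equal(unname(ps@normalized[1, ]), c(0.44, 0.20))
    expect_true(ps@valid)
})

test_that("profiles below the terminal floor or off-chromosome are invalid", {
    cfg <- pipelineConfig(windowSize = 250, nWindows = 2)
    ann <- oneTxAnn(1, 500, "+")
    ps0 <- transcriptProfiles(ann, toyCoverage(), cfg)
    expect_false(ps0@valid)
    expect_identical(ps0@reason, "terminal-floor")
    expect_error(metageneProfile(ps0), "no analyzable transcripts")

    # span shorter than one window
    psShort <- transcriptProfiles(oneTxAnn(1, 100, "+"), toyCoverage(), cfg)
    expect_identical(psShort@reason, "short-span")

    # minus-strand transcript too close to the chromosome start
    psOob <- transcriptProfiles(oneTxAnn(201, 600, "-"), toyCoverage(), cfg)
    expect_identical(psOob@reason, "out-of-bounds")
})

test_that("mean-of-ratios averaging matches hand-computed values", {
    ps <- makeProfileSet(matrix(c(1, 0, 0, 0, 2, 1), ncol = 2, byrow = TRUE),
                         terminalSignal = c(1, 1, 1))
    st <- metageneStats(metageneProfile(ps))
    expect_equal(st$mean, c(1, 1 / 3))
    expect_identical(st$n, rep(3L, 2) |> as.integer())
    # a single profile aggregates to itself
    one <- makeProfileSet(matrix(c(0.7, 0.2), nrow = 1),
                          terminalSignal = 1)
    expect_equal(metageneStats(metageneProfile(one))$mean, c(0.7, 0.2))
})

test_that("mean_of_ratios and pooled_ratio disagree exactly as defined", {
    ps <- makeProfileSet(matrix(c(100, 0), ncol = 1),
                         terminalSignal = c(100, 300))
    mor <- metageneStats(metageneProfile(ps, mode = "mean_of_ratios"))$mean
    pr <- metageneStats(metageneProfile(ps, mode = "pooled_ratio"))$mean
    expect_equal(mor, 0.5)
    expect_equal(pr, 0.25)
    # pooled_ratio is invariant to duplicating every transcript
    dup <- makeProfileSet(matrix(c(100, 0, 100, 0), ncol = 1),
                          terminalSignal = c(100, 300, 100, 300))
    expect_equal(metageneStats(metageneProfile(dup, mode = "pooled_ratio"))$mean,
                 pr)
})

test_that("substituting the terminal window for window 1 normalizes to 1", {
    sim <- simSmall(n = 30, seed = 21)
    cfg <- pipelineConfig()
    ps <- transcriptProfiles(sim$ann, sim$cov, cfg)
    term <- unlist(placeWindows(sim$ann, cfg, side = "terminal"),
                   use.names = FALSE)
    selfNorm <- intervalSum(sim$cov, term) / ps@terminalSignal
    expect_identical(unname(selfNorm[ps@valid]),
                     rep(1, sum(ps@valid)))
})

test_that("profiles and meta-genes are invariant to sequencing depth", {
    sim <- simSmall(n = 30, seed = 23)
    cfg <- pipelineConfig()
    ps1 <- transcriptProfiles(sim$ann, sim$cov, cfg)
    ps3 <- transcriptProfiles(sim$ann, scaleCoverage(sim$cov, 3), cfg)
    expect_identical(ps1@valid, ps3@valid)
    expect_equal(ps1@normalized[ps1@valid, ], ps3@normalized[ps3@valid, ],
                 tolerance = 1e-9)
    expect_equal(metageneStats(metageneProfile(ps1))$mean,
                 metageneStats(metageneProfile(ps3))$mean, tolerance = 1e-9)
})

test_that("mirroring the genome reproduces the meta-gene exactly", {
    sim <- simSmall(n = 40, seed = 29)
    L <- sim$params@chromLength
    cfg <- pipelineConfig()
    psO <- transcriptProfiles(sim$ann, sim$cov, cfg)
    psM <- transcriptProfiles(mirrorAnnotation(sim$ann, L),
                              mirrorCoverage(sim$cov, L), cfg)
    expect_identical(psO@valid, psM@valid)
    expect_equal(psO@normalized[psO@valid, ], psM@normalized[psM@valid, ],
                 tolerance = 1e-12)
})

test_that("identical conditions compare to exactly zero difference", {
    ps <- makeProfileSet(matrix(runif(20), ncol = 4),
                         terminalSignal = rep(2, 5))
    cmp <- compareConditions(ps, ps, pipelineConfig(seed = 5))
    expect_identical(cmp$diff, rep(0, 4))
    expect_true(all(cmp$ci_lo <= cmp$diff & cmp$diff <= cmp$ci_hi))
    # deterministic given the seed
    cmp2 <- compareConditions(ps, ps, pipelineConfig(seed = 5))
    expect_identical(cmp, cmp2)
})

test_that("a real read-through contrast is detected with CIs excluding zero", {
    cfg <- pipelineConfig(seed = 42)
    p <- simulationParams(nTranscripts = 100, seed = 42)
    sim <- simulateAnnotation(p)
    covW <- simulateCoverage(sim$annotation, sim$truth, alpha = 0.05,
                             seed = 101)
    covM <- simulateCoverage(sim$annotation, sim$truth, alpha = 0.6,
                             seed = 102)
    psW <- transcriptProfiles(sim$annotation, covW, cfg, "wt", "r1")
    psM <- transcriptProfiles(sim$annotation, covM, cfg, "mut", "r1")
    cmp <- compareConditions(psW, psM, cfg)
    k2kb <- cmp$window <= 8          # windows within 2 kb of the TES
    expect_true(all(cmp$diff[k2kb] > 0))
    expect_true(all(cmp$ci_lo[k2kb] > 0))
})

test_that("null contrasts between same-alpha replicates mostly cover zero", {
    cfg <- pipelineConfig(nWindows = 10, seed = 7)
    p <- simulationParams(nTranscripts = 60, seed = 17)
    sim <- simulateAnnotation(p)
    covered <- 0L
    total <- 0L
    for (rep in 1:20) {
        c1 <- simulateCoverage(sim$annotation, sim$truth, alpha = 0.3,
                               seed = 1000 + rep)
        c2 <- simulateCoverage(sim$annotation, sim$truth, alpha = 0.3,
                               seed = 2000 + rep)
        cmp <- compareConditions(
            transcriptProfiles(sim$annotation, c1, cfg),
            transcriptProfiles(sim$annotation, c2, cfg),
            cfg, nBoot = 400L)
        covered <- covered + sum(cmp$ci_lo <= 0 & cmp$ci_hi >= 0)
        total <- total + nrow(cmp)
    }
    expect_gte(covered / total, 0.9)
})

test_that("the analytic oracle inverts back to the simulated alpha", {
    sim <- simSmall(n = 100, seed = 31, alpha = 0.4)
    ps <- transcriptProfiles(sim$ann, sim$cov, pipelineConfig())
    mg <- metageneProfile(ps)
    expect_equal(estimateReadthroughFraction(mg, 1000), 0.4,
                 tolerance = 0.05)
})
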