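test_that("annotation simulation is deterministic and respects its contract", {
    p <- simulationParams(nTranscripts = 50, seed = 7)
    sim <- simulateAnnotation(p)
    expect_identical(length(sim$annotation), 50L)
    # same-strand downstream gaps are at least the configured minimum
    spans <- transcriptRanges(sim$annotation)
    o <- order(start(spans))
    gaps <- start(spans)[o][-1] - end(spans)[o][-50]
    expect_true(all(gaps > p@intergenicMinGap))
    # clearance holds by construction at the default 5 kb
    expect_true(all(downstreamClearance(sim$annotation, 5000)))
    # byte-identical GTF output across reruns
    f1 <- tempfile(); f2 <- tempfile()
    writeGtf(simulateAnnotation(p)$annotation, f1)
    writeGtf(simulateAnnotation(p)$annotation, f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("splicedFraction = 1 yields only multi-exon transcripts", {
    sim <- simulateAnnotation(simulationParams(nTranscripts = 30, seed = 2,
                                               splicedFraction = 1))
    expect_true(all(isSpliced(sim$annotation)))
})

test_that("an infeasible chromosome length is rejected with the minimum", {
    p <- simulationParams(nTranscripts = 50, chromLength = 1000, seed = 7)
    expect_error(simulateAnnotation(p), "need at least [0-9]+ nt")
})

test_that("alpha = 0 with no background leaves downstream bases exactly zero", {
    sim <- simSmall(n = 30, seed = 4, alpha = 0)
    down <- unlist(placeWindows(sim$ann, pipelineConfig()),
                   use.names = FALSE)
    expect_identical(intervalSum(sim$cov, down), numeric(length(down)))
})

test_that("exonic coverage matches the truth within Poisson error", {
    sim <- simSmall(n = 30, seed = 10, alpha = 0.2)
    tpmDetail <- computeTpm(sim$ann, sim$cov, detail = TRUE)
    obs <- tpmDetail$exonic_signal / tpmDetail$exonic_length
    cT <- sim$truth$c_t[match(tpmDetail$transcript_id,
                              sim$truth$transcript_id)]
    se <- sqrt(cT / tpmDetail$exonic_length)
    expect_true(all(abs(obs - cT) < 4 * se))
})

test_that("replicates with different seeds differ but share the expectation", {
    sim <- simSmall(n = 40, seed = 6, alpha = 0.3)
    cov2 <- simulateCoverage(sim$ann, sim$truth, alpha = 0.3, seed = 999)
    expect_false(isTRUE(all.equal(totalSignal(sim$cov), totalSignal(cov2))))
    cfg <- pipelineConfig()
    m1 <- metageneStats(metageneProfile(
        transcriptProfiles(sim$ann, sim$cov, cfg)))$mean
    m2 <- metageneStats(metageneProfile(
        transcriptProfiles(sim$ann, cov2, cfg)))$mean
    expect_equal(m1[1:8], m2[1:8], tolerance = 0.1)
})

test_that("the analytic expectation matches its closed form and limits", {
    expect_equal(expectedMetagene(0.5, 1000, 250, 1),
                 0.5 * 4 * (1 - exp(-0.25)), tolerance = 1e-12)
    expect_equal(expectedMetagene(0.5, 1000, 250, 1), 0.4424,
                 tolerance = 1e-4)
    expect_identical(expectedMetagene(0, 1000, 250, 1:5), rep(0, 5))
    # lambda -> infinity: every window tends to alpha
    expect_equal(expectedMetagene(0.37, 1e12, 250, c(1, 7, 20)),
                 rep(0.37, 3), tolerance = 1e-6)
})

test_that("the continuous formula tracks the discrete per-base sum closely", {
    W <- 250
    for (lambda in c(500, 1000, 2000)) {
        for (k in c(1, 4, 10)) {
            d <- ((k - 1) * W):(k * W - 1)
            discrete <- sum(exp(-d / lambda)) / W   # alpha = 1 reference
            cont <- expectedMetagene(1, lambda, W, k)
            expect_lt(abs(cont - discrete) / discrete, 0.005)
        }
    }
})

test_that("noiseless simulation reproduces the analytic window values", {
    sim <- simSmall(n = 30, seed = 8, alpha = 0.5, noise = "none")
    cfg <- pipelineConfig()
    ps <- transcriptProfiles(sim$ann, sim$cov, cfg)
    expect_true(all(ps@valid))
    expected <- expectedMetagene(0.5, 1000, 250, 1:20)
    for (k in c(1, 2, 5, 10))
        expect_equal(unname(ps@normalized[, k]),
                     rep(expected[k], nrow(ps@normalized)),
                     tolerance = 2e-3)
})

test_that("a simulated bundle is complete, parseable and deterministic", {
    p <- simulationParams(nTranscripts = 12, replicates = 2, seed = 19)
    d1 <- tempfile(); d2 <- tempfile()
    b <- simulateBundle(p, d1, conditions = c(wt = 0.05, mut = 0.6))
    expect_true(file.exists(file.path(d1, "annotation.gtf")))
    expect_true(file.exists(file.path(d1, "truth.tsv")))
    expect_true(file.exists(file.path(d1, "params.yaml")))
    covs <- list.files(d1, pattern = "bedgraph$")
    expect_length(covs, 2 * 2 * 2)   # condition x replicate x strand
    ann <- readGtf(file.path(d1, "annotation.gtf"))
    expect_identical(length(ann), 12L)
    cov <- readBedGraphPair(file.path(d1, "wt_rep1.plus.bedgraph"),
                            file.path(d1, "wt_rep1.minus.bedgraph"))
    expect_gt(totalSignal(cov), 0)
    simulateBundle(p, d2, conditions = c(wt = 0.05, mut = 0.6))
    for (f in c("annotation.gtf", "truth.tsv", covs))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)),
                         label = paste("file", f))
})
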