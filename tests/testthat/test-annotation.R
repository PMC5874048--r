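test_that("GTF exons are parsed with 1-based inclusive coordinates intact", {
    path <- writeToyGtf(data.frame(
        chrom = "chr1", start = c(1, 201), end = c(100, 300),
        strand = "+", gene = "G1", tx = "T1"))
    ann <- readGtf(path)
    ex <- exonsByTranscript(ann)[["T1"]]
    expect_identical(start(ex), c(1L, 201L))
    expect_identical(end(ex), c(100L, 300L))
    expect_true(isSpliced(ann)[["T1"]])
    expect_identical(unname(exonicLengths(ann)[["T1"]]), 200L)
    span <- transcriptRanges(ann)
    expect_identical(start(span), 1L)
    expect_identical(end(span), 300L)
})

test_that("the 3' end follows the strand: leftmost coordinate on minus", {
    path <- writeToyGtf(data.frame(
        chrom = "chr1", start = c(1, 201), end = c(100, 300),
        strand = "-", gene = "G1", tx = "T1"))
    ann <- readGtf(path)
    tes <- terminationSites(ann)
    expect_identical(start(tes), 1L)
    expect_identical(as.character(strand(tes)), "-")
    # and the rightmost end on plus
    pathP <- writeToyGtf(data.frame(
        chrom = "chr1", start = c(1, 201), end = c(100, 300),
        strand = "+", gene = "G1", tx = "T2"))
    expect_identical(start(terminationSites(readGtf(pathP))), 300L)
})

test_that("degenerate and malformed GTF inputs are handled as specified", {
    empty <- tempfile(fileext = ".gtf")
    writeLines("# just a comment", empty)
    expect_warning(ann <- readGtf(empty), "no exon")
    expect_identical(length(ann), 0L)

    # non-exon features are ignored
    path <- writeToyGtf(data.frame(
        chrom = "chr1", start = c(1, 1, 201), end = c(300, 100, 300),
        strand = "+", gene = "G1", tx = "T1",
        feature = c("transcript", "exon", "exon")))
    ann <- readGtf(path)
    expect_identical(lengths(exonsByTranscript(ann))[["T1"]], 2L)

    # mixed strands within a transcript name the transcript
    bad <- writeToyGtf(data.frame(
        chrom = "chr1", start = c(1, 201), end = c(100, 300),
        strand = c("+", "-"), gene = "G1", tx = "T1"))
    expect_error(readGtf(bad), "T1.*mixed strands")

    # missing transcript_id names the file
    noattr <- tempfile(fileext = ".gtf")
    writeLines("chr1\ttest\texon\t1\t100\t.\t+\t.\tgene_id \"G1\";", noattr)
    expect_error(readGtf(noattr), "transcript_id")
})

test_that("overlapping exons within a transcript are merged with a warning", {
    path <- writeToyGtf(data.frame(
        chrom = "chr1", start = c(1, 50), end = c(100, 200),
        strand = "+", gene = "G1", tx = "T1"))
    expect_warning(ann <- readGtf(path), "merged overlapping")
    ex <- exonsByTranscript(ann)[["T1"]]
    expect_identical(length(ex), 1L)
    expect_identical(start(ex), 1L)
    expect_identical(end(ex), 200L)
})

test_that("GTF round trip preserves every exon coordinate", {
    sim <- simSmall(n = 30, seed = 11)
    out <- tempfile(fileext = ".gtf")
    writeGtf(sim$ann, out)
    back <- readGtf(out)
    expect_identical(sort(transcriptIds(back)), sort(transcriptIds(sim$ann)))
    for (id in transcriptIds(sim$ann)) {
        a <- exonsByTranscript(sim$ann)[[id]]
        b <- exonsByTranscript(back)[[id]]
        expect_identical(start(a), start(b))
        expect_identical(end(a), end(b))
        expect_identical(as.character(strand(a)), as.character(strand(b)))
    }
})

test_that("downstream clearance respects distance, strand and shared 3' ends", {
    # T1 last base 1000 (+); neighbour occupies 1401..2000 on +
    mk <- function(nbStrand) {
        grl <- GRangesList(
            T1 = GRanges("chr1", IRanges(1, 1000), strand = "+"),
            NB = GRanges("chr1", IRanges(1401, 2000), strand = nbStrand))
        TranscriptAnnotation(grl, c(T1 = "G1", NB = "G2"))
    }
    annP <- mk("+")
    expect_false(downstreamClearance(annP, 500)[["T1"]])
    expect_true(downstreamClearance(annP, 300)[["T1"]])
    # opposite-strand neighbour never blocks
    annM <- mk("-")
    expect_true(downstreamClearance(annM, 500)[["T1"]])
    # isoforms of the same gene sharing the identical TES are ignored
    grl <- GRangesList(
        A1 = GRanges("chr1", IRanges(1, 1000), strand = "+"),
        A2 = GRanges("chr1", IRanges(500, 1000), strand = "+"))
    annIso <- TranscriptAnnotation(grl, c(A1 = "GA", A2 = "GA"))
    expect_true(all(downstreamClearance(annIso, 500)))
    # unknown transcript errors
    expect_error(downstreamClearance(annIso, 500, "nope"), "not in annotation")
})

test_that("mirroring the genome maps each 3' end to the mirrored position", {
    sim <- simSmall(n = 40, seed = 3)
    L <- sim$params@chromLength
    mirrored <- mirrorAnnotation(sim$ann, L)
    tesO <- terminationSites(sim$ann)
    tesM <- terminationSites(mirrored)
    expect_identical(start(tesM), L - start(tesO) + 1L)
    expect_identical(as.character(strand(tesM)),
                     ifelse(as.character(strand(tesO)) == "+", "-", "+"))
})
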