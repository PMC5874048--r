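suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(S4Vectors)
})

# write a GTF from a data.frame of 1-based inclusive exon rows
writeToyGtf <- function(rows, path = tempfile(fileext = ".gtf"),
                        feature = "exon") {
    feat <- if (is.null(rows$feature)) rep(feature, nrow(rows)) else rows$feature
    lines <- sprintf(
        "%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
        rows$chrom, feat, rows$start, rows$end, rows$strand,
        rows$gene, rows$tx)
    writeLines(lines, path)
    path
}

# StrandedCoverage from named lists of per-base numeric vectors (1-based)
toyCoverage <- function(plus = list(), minus = list()) {
    asRl <- function(l) as(lapply(l, Rle), "SimpleRleList")
    StrandedCoverage(plus = asRl(plus), minus = asRl(minus))
}

# independent per-base oracle for interval sums
bruteIntervalSum <- function(cov, gr) {
    vapply(seq_along(gr), function(i) {
        rl <- strandCoverage(cov, as.character(strand(gr))[i])
        r <- rl[[as.character(seqnames(gr))[i]]]
        if (is.null(r)) return(0)
        v <- as.numeric(r)
        total <- 0
        for (pos in seq.int(start(gr)[i], end(gr)[i]))
            if (pos >= 1 && pos <= length(v)) total <- total + v[pos]
        total
    }, numeric(1))
}

# reflect an annotation through position L (strands swap)
mirrorAnnotation <- function(ann, L) {
    ex <- exonsByTranscript(ann)
    flat <- unlist(ex, use.names = FALSE)
    gr <- GRanges(seqnames(flat),
                  IRanges(L - end(flat) + 1L, L - start(flat) + 1L),
                  strand = ifelse(as.character(strand(flat)) == "+", "-", "+"))
    grl <- S4Vectors::split(gr, rep(seq_along(ex), lengths(ex)))
    names(grl) <- names(ex)
    out <- TranscriptAnnotation(grl, geneIds(ann))
    sl <- seqlengths(exonsByTranscript(ann))
    e2 <- out@exons
    seqlengths(e2) <- sl
    out@exons <- e2
    out
}

# reflect coverage through position L (strands swap, vectors reversed)
mirrorCoverage <- function(cov, L) {
    flip <- function(rl) {
        out <- lapply(rl, function(r) {
            v <- as.numeric(r)
            if (length(v) < L) v <- c(v, numeric(L - length(v)))
            Rle(rev(v))
        })
        as(out, "SimpleRleList")
    }
    StrandedCoverage(plus = flip(strandCoverage(cov, "-")),
                     minus = flip(strandCoverage(cov, "+")))
}

# directly assemble a TranscriptProfileSet from matrices (aggregation tests)
makeProfileSet <- function(windowSignals, terminalSignal,
                           valid = rep(TRUE, nrow(windowSignals)),
                           W = 250L, condition = "", replicate = "") {
    n <- nrow(windowSignals)
    K <- ncol(windowSignals)
    normalized <- windowSignals / terminalSignal
    normalized[!valid, ] <- NA_real_
    new("TranscriptProfileSet",
        transcriptId = sprintf("T%d", seq_len(n)),
        terminalSignal = terminalSignal,
        windowSignals = windowSignals,
        normalized = normalized,
        valid = valid,
        reason = ifelse(valid, "", "terminal-floor"),
        terminalExonShort = rep(FALSE, n),
        condition = condition, replicate = replicate,
        windowSize = as.integer(W), nWindows = as.integer(K),
        terminalFloor = 1)
}

# small simulated dataset shared by several tests
simSmall <- function(n = 50, seed = 7, alpha = 0.5, noise = "poisson",
                     covSeed = seed + 1, ...) {
    p <- simulationParams(nTranscripts = n, seed = seed, ...)
    sim <- simulateAnnotation(p)
    cov <- simulateCoverage(sim$annotation, sim$truth, alpha = alpha,
                            seed = covSeed, noise = noise)
    list(params = attr(sim$truth, "params"), ann = sim$annotation,
         truth = sim$truth, cov = cov)
}
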