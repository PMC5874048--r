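#' Place analysis windows relative to transcript 3' ends
#'
#' \code{side = "downstream"} yields, per transcript, K contiguous W-nt
#' genomic windows starting at the TES and ordered by increasing distance
#' from it (increasing coordinates on \code{+}, decreasing on \code{-}).
#' \code{side = "terminal"} yields the single W-nt window just inside the
#' transcript span, adjacent to the TES — the normalization reference (the
#' last W nt of the gene body). Windows are genomic: they ignore the exon
#' structure, matching the windowed-density definition of the meta-gene.
#'
#' @param ann a \linkS4class{TranscriptAnnotation} (or a subset of one).
#' @param config a \linkS4class{PipelineConfig} (uses windowSize, nWindows).
#' @param side \code{"downstream"} or \code{"terminal"}.
#' @return a named \code{GRangesList}, one element per transcript with K
#'   windows (downstream) or 1 window (terminal). Windows may extend beyond
#'   chromosome bounds; validity is assessed in [transcriptProfiles()].
#' @export
placeWindows <- function(ann, config = pipelineConfig(),
                         side = c("downstream", "terminal")) {
    side <- match.arg(side)
    spans <- transcriptRanges(ann)
    W <- config@windowSize
    K <- if (side == "downstream") config@nWindows else 1L
    n <- length(spans)
    st <- as.character(strand(spans))
    chrom <- rep(as.character(seqnames(spans)), each = K)
    k <- rep(seq_len(K), times = n)
    E <- rep(BiocGenerics::end(spans), each = K)      # last transcribed base (+)
    S <- rep(BiocGenerics::start(spans), each = K)    # last transcribed base (-)
    plus <- rep(st == "+", each = K)
    if (side == "downstream") {
        starts <- ifelse(plus, E + (k - 1L) * W + 1L, S - k * W)
        ends <- ifelse(plus, E + k * W, S - (k - 1L) * W - 1L)
    } else {
        starts <- ifelse(plus, E - W + 1L, S)
        ends <- ifelse(plus, E, S + W - 1L)
    }
    gr <- suppressWarnings(GRanges(chrom, IRanges(starts, ends),
                                   strand = rep(st, each = K),
                                   seqinfo = seqinfo(spans)))
    out <- S4Vectors::split(gr, rep(seq_len(n), each = K))
    names(out) <- names(spans)
    out
}

#' Per-transcript read-through profiles
#'
#' Computes, for every transcript in \code{ann}, the raw signal in the K
#' downstream windows and in the terminal window, and the
#' terminal-normalized window values. A profile is invalid (excluded from
#' aggregation, with a recorded reason) when the transcript span is shorter
#' than one window (\code{"short-span"}), when any window leaves the
#' chromosome — below position 1, or past the chromosome length when that is
#' known (\code{"out-of-bounds"}) — or when the terminal signal is below the
#' configured floor (\code{"terminal-floor"}). Transcripts whose terminal
#' exon is shorter than W are measured on the genomic span as usual but
#' flagged for audit.
#'
#' @param ann a \linkS4class{TranscriptAnnotation}, typically the retained
#'   subset after [filterTranscripts()].
#' @param cov a \linkS4class{StrandedCoverage}.
#' @param config a \linkS4class{PipelineConfig}.
#' @param condition,replicate provenance labels stored in the result.
#' @return a \linkS4class{TranscriptProfileSet}.
#' @export
transcriptProfiles <- function(ann, cov, config = pipelineConfig(),
                               condition = "", replicate = "") {
    stopifnot(length(ann) > 0L)
    W <- config@windowSize
    K <- config@nWindows
    ids <- transcriptIds(ann)
    n <- length(ids)
    spans <- transcriptRanges(ann)

    shortSpan <- BiocGenerics::width(spans) < W
    term <- placeWindows(ann, config, side = "terminal")
    down <- placeWindows(ann, config, side = "downstream")
    termFlat <- unlist(term, use.names = FALSE)
    downFlat <- unlist(down, use.names = FALSE)

    sl <- seqlengths(spans)
    oobOne <- function(gr) {
        lim <- sl[as.character(seqnames(gr))]
        BiocGenerics::start(gr) < 1L |
            (!is.na(lim) & BiocGenerics::end(gr) > lim)
    }
    oob <- matrix(oobOne(downFlat), nrow = n, ncol = K, byrow = TRUE)
    oobAny <- rowSums(oob) > 0L | oobOne(termFlat)

    terminalSignal <- intervalSum(cov, termFlat)
    windowSignals <- matrix(intervalSum(cov, downFlat),
                            nrow = n, ncol = K, byrow = TRUE,
                            dimnames = list(ids, NULL))

    reason <- character(n)
    reason[terminalSignal < config@terminalFloor] <- "terminal-floor"
    reason[oobAny] <- "out-of-bounds"
    reason[shortSpan] <- "short-span"
    valid <- !nzchar(reason)

    normalized <- windowSignals / terminalSignal
    normalized[!valid, ] <- NA_real_

    # audit flag: last exon in transcription direction shorter than W
    exw <- BiocGenerics::width(unlist(ann@exons, use.names = FALSE))
    lastIdx <- cumsum(lengths(ann@exons))
    firstIdx <- lastIdx - lengths(ann@exons) + 1L
    lastExonWidth <- ifelse(as.character(strand(spans)) == "+",
                            exw[lastIdx], exw[firstIdx])

    new("TranscriptProfileSet",
        transcriptId = ids,
        terminalSignal = unname(terminalSignal),
        windowSignals = windowSignals,
        normalized = normalized,
        valid = valid,
        reason = reason,
        terminalExonShort = unname(lastExonWidth < W),
        condition = as.character(condition),
        replicate = as.character(replicate),
        windowSize = W,
        nWindows = K,
        terminalFloor = config@terminalFloor)
}

setMethod("show", "TranscriptProfileSet", function(object) {
    cat(sprintf(paste0(
        "TranscriptProfileSet: %d transcript(s), %d valid; W=%d nt, K=%d",
        " [%s%s]\n"),
        length(object@transcriptId), sum(object@valid),
        object@windowSize, object@nWindows,
        if (nzchar(object@condition)) object@condition else "unlabelled",
        if (nzchar(object@replicate))
            paste0("/", object@replicate) else ""))
})

#' @describeIn transcriptProfiles number of transcript profiles.
#' @param x a \linkS4class{TranscriptProfileSet}.
#' @export
setMethod("length", "TranscriptProfileSet",
          function(x) length(x@transcriptId))

# concatenate profile sets (e.g. replicates of one condition); parameters
# must agree
.bindProfileSets <- function(sets) {
    if (is(sets, "TranscriptProfileSet"))
        return(sets)
    stopifnot(length(sets) >= 1L)
    p1 <- sets[[1L]]
    if (length(sets) == 1L)
        return(p1)
    for (p in sets[-1L])
        stopifnot(p@windowSize == p1@windowSize,
                  p@nWindows == p1@nWindows)
    new("TranscriptProfileSet",
        transcriptId = unlist(lapply(sets, slot, "transcriptId")),
        terminalSignal = unlist(lapply(sets, slot, "terminalSignal")),
        windowSignals = do.call(rbind, lapply(sets, slot, "windowSignals")),
        normalized = do.call(rbind, lapply(sets, slot, "normalized")),
        valid = unlist(lapply(sets, slot, "valid")),
        reason = unlist(lapply(sets, slot, "reason")),
        terminalExonShort = unlist(lapply(sets, slot, "terminalExonShort")),
        condition = paste(unique(vapply(sets, slot, character(1),
                                        "condition")), collapse = "+"),
        replicate = paste(vapply(sets, slot, character(1), "replicate"),
                          collapse = "+"),
        windowSize = p1@windowSize,
        nWindows = p1@nWindows,
        terminalFloor = p1@terminalFloor)
}

#' Aggregate transcript profiles into a meta-gene profile
#'
#' Two aggregation modes are provided. \code{mean_of_ratios} (default)
#' normalizes each transcript to its own terminal window and averages the
#' ratios across transcripts — each transcript contributes equally,
#' regardless of expression. \code{pooled_ratio} sums raw window signals
#' across transcripts and divides by the summed terminal signals — a
#' cumulative-signal reading in which highly expressed transcripts dominate.
#' Only valid profiles contribute, all-or-none across windows, so n is
#' constant along the profile.
#'
#' @param profiles a \linkS4class{TranscriptProfileSet}, or a list of them
#'   (concatenated, e.g. replicates).
#' @param config a \linkS4class{PipelineConfig}; its \code{aggregation} is
#'   the default mode.
#' @param mode override the aggregation mode.
#' @return a \linkS4class{MetaGeneProfile}.
#' @export
metageneProfile <- function(profiles, config = pipelineConfig(),
                            mode = config@aggregation) {
    p <- .bindProfileSets(profiles)
    mode <- match.arg(mode, c("mean_of_ratios", "pooled_ratio"))
    v <- p@valid
    if (!any(v))
        stop("no analyzable transcripts (all profiles invalid)")
    K <- p@nWindows
    W <- p@windowSize
    if (mode == "mean_of_ratios") {
        m <- p@normalized[v, , drop = FALSE]
        mu <- colMeans(m)
        sdev <- apply(m, 2L, stats::sd)
    } else {
        mu <- colSums(p@windowSignals[v, , drop = FALSE]) /
            sum(p@terminalSignal[v])
        sdev <- rep(NA_real_, K)
    }
    new("MetaGeneProfile",
        condition = p@condition,
        replicate = p@replicate,
        mode = mode,
        stats = data.frame(window = seq_len(K),
                           distance_nt = (seq_len(K) - 1L) * W,
                           mean = unname(mu),
                           sd = unname(sdev),
                           n = sum(v)))
}

setMethod("show", "MetaGeneProfile", function(object) {
    cat(sprintf("MetaGeneProfile [%s%s] mode=%s, n=%d transcript(s)\n",
                if (nzchar(object@condition)) object@condition else "unlabelled",
                if (nzchar(object@replicate))
                    paste0("/", object@replicate) else "",
                object@mode, object@stats$n[1L]))
    print(head(object@stats, 5L), row.names = FALSE)
    if (nrow(object@stats) > 5L) cat("  ...\n")
})

#' @describeIn metageneProfile the per-window statistics table.
#' @param x a \linkS4class{MetaGeneProfile}.
#' @export
metageneStats <- function(x) x@stats

#' Bootstrap contrast of two conditions
#'
#' Quantifies the read-through difference between two conditions per window:
#' the difference (B minus A) and ratio of mean-of-ratios means, with a 95%
#' percentile bootstrap confidence interval obtained by resampling
#' transcripts with replacement within each condition. Deterministic given
#' the seed in \code{config}.
#'
#' @param profilesA,profilesB \linkS4class{TranscriptProfileSet} objects (or
#'   lists of them, e.g. replicates), reference and contrast condition.
#' @param config a \linkS4class{PipelineConfig}.
#' @param nBoot number of bootstrap resamples.
#' @return data.frame with columns window, distance_nt, diff, ratio, ci_lo,
#'   ci_hi, n_boot, seed.
#' @export
compareConditions <- function(profilesA, profilesB,
                              config = pipelineConfig(), nBoot = 1000L) {
    a <- .bindProfileSets(profilesA)
    b <- .bindProfileSets(profilesB)
    stopifnot(a@nWindows == b@nWindows, a@windowSize == b@windowSize)
    ma <- a@normalized[a@valid, , drop = FALSE]
    mb <- b@normalized[b@valid, , drop = FALSE]
    if (nrow(ma) == 0L || nrow(mb) == 0L)
        stop("no analyzable transcripts in one of the conditions")
    K <- a@nWindows
    muA <- colMeans(ma)
    muB <- colMeans(mb)
    bootDiff <- matrix(NA_real_, nrow = nBoot, ncol = K)
    .withSeed(config@seed, {
        for (i in seq_len(nBoot)) {
            ia <- sample.int(nrow(ma), replace = TRUE)
            ib <- sample.int(nrow(mb), replace = TRUE)
            bootDiff[i, ] <- colMeans(mb[ib, , drop = FALSE]) -
                colMeans(ma[ia, , drop = FALSE])
        }
    })
    ci <- apply(bootDiff, 2L, stats::quantile, probs = c(0.025, 0.975))
    data.frame(window = seq_len(K),
               distance_nt = (seq_len(K) - 1L) * a@windowSize,
               diff = unname(muB - muA),
               ratio = unname(muB / muA),
               ci_lo = unname(ci[1L, ]),
               ci_hi = unname(ci[2L, ]),
               n_boot = as.integer(nBoot),
               seed = config@seed)
}

# evaluate expr under a fixed RNG state, restoring the caller's state
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has)
        old <- get(".Random.seed", envir = globalenv())
    set.seed(seed)
    on.exit({
        if (has)
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    eval.parent(substitute(expr))
}

#' Estimate the read-through fraction from a meta-gene profile
#'
#' Inverts the window-1 expectation of the exponential-decay read-through
#' model: with decay length lambda and window width W, the expected
#' terminal-normalized first-window value is
#' \code{alpha * (lambda/W) * (1 - exp(-W/lambda))}, so alpha is recovered
#' as the observed window-1 mean divided by that factor.
#'
#' @param metagene a \linkS4class{MetaGeneProfile}.
#' @param decayLength assumed decay length lambda in nt.
#' @return estimated read-through fraction alpha.
#' @seealso [expectedMetagene()]
#' @export
estimateReadthroughFraction <- function(metagene, decayLength) {
    st <- metageneStats(metagene)
    W <- st$distance_nt[2L] - st$distance_nt[1L]
    st$mean[1L] / ((decayLength / W) * (1 - exp(-W / decayLength)))
}
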