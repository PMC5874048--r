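#' Pipeline configuration constructor
#'
#' @param windowSize window width W in nt.
#' @param nWindows number of downstream windows K.
#' @param tpmThreshold retain transcripts with TPM strictly above this value.
#' @param requireSpliced retain only transcripts with >= 2 exons.
#' @param clearance required transcript-free distance downstream of the TES
#'   in nt; \code{NA} means \code{nWindows * windowSize} (no foreign signal
#'   inside any analysed window). Set to \code{0} to disable the check.
#' @param terminalFloor minimum terminal-window signal for a valid profile.
#' @param aggregation \code{"mean_of_ratios"} or \code{"pooled_ratio"}.
#' @param seed integer seed for the bootstrap.
#' @return a \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(windowSize = 250, nWindows = 20,
                           tpmThreshold = 10, requireSpliced = TRUE,
                           clearance = NA, terminalFloor = 1,
                           aggregation = c("mean_of_ratios", "pooled_ratio"),
                           seed = 1) {
    windowSize <- as.integer(windowSize)
    nWindows <- as.integer(nWindows)
    if (is.na(clearance))
        clearance <- windowSize * nWindows
    new("PipelineConfig",
        windowSize = windowSize,
        nWindows = nWindows,
        tpmThreshold = as.numeric(tpmThreshold),
        requireSpliced = isTRUE(requireSpliced),
        clearance = as.integer(clearance),
        terminalFloor = as.numeric(terminalFloor),
        aggregation = match.arg(aggregation),
        seed = as.integer(seed))
}

setMethod("show", "PipelineConfig", function(object) {
    cat(sprintf(paste0(
        "PipelineConfig: W=%d nt, K=%d windows, TPM > %g, spliced=%s,\n",
        "  clearance=%d nt, terminal floor=%g, aggregation=%s, seed=%d\n"),
        object@windowSize, object@nWindows, object@tpmThreshold,
        object@requireSpliced, object@clearance, object@terminalFloor,
        object@aggregation, object@seed))
})

#' Coverage-based TPM per transcript
#'
#' Expression is quantified directly from per-base exonic coverage: the
#' per-base rate of transcript t is its summed exonic signal divided by its
#' exonic length, and TPM_t rescales the rates to sum to one million. This
#' deliberately diverges from count-based TPM — coverage is the pipeline's
#' canonical input — but has the same normalization identity: TPM sums to
#' 1e6 whenever any transcript has signal (all-zero coverage yields all-zero
#' TPM).
#'
#' @param ann a \linkS4class{TranscriptAnnotation}.
#' @param cov a \linkS4class{StrandedCoverage}.
#' @param detail if TRUE return a data.frame with exonic_signal,
#'   exonic_length and tpm; otherwise a named TPM vector.
#' @return named numeric vector of TPM values (or a data.frame).
#' @export
computeTpm <- function(ann, cov, detail = FALSE) {
    stopifnot(length(ann) > 0L)
    ex <- unlist(ann@exons, use.names = FALSE)
    txOf <- rep(names(ann@exons), lengths(ann@exons))
    sig <- intervalSum(cov, ex)
    exonicSignal <- vapply(split(sig, factor(txOf, levels = names(ann@exons))),
                           sum, numeric(1))
    len <- exonicLengths(ann)
    rate <- exonicSignal / len
    total <- sum(rate)
    tpm <- if (total > 0) rate / total * 1e6 else rate * 0
    if (!detail)
        return(tpm)
    data.frame(transcript_id = names(tpm),
               exonic_length = as.integer(len),
               exonic_signal = unname(exonicSignal),
               tpm = unname(tpm),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Select analyzable transcripts
#'
#' Applies the transcript filter for the meta-gene analysis: expression
#' strictly above the TPM threshold, spliced structure (>= 2 exons) when
#' required, and a transcript-free downstream clearance region on the same
#' strand. Every transcript is accounted for: the returned table records,
#' for excluded transcripts, all rules they failed
#' (\code{expression}, \code{monoexonic}, \code{clearance}, semicolon-joined).
#'
#' @param ann a \linkS4class{TranscriptAnnotation}.
#' @param tpm named TPM vector covering all transcripts in \code{ann}
#'   (from [computeTpm()]).
#' @param config a \linkS4class{PipelineConfig}.
#' @return data.frame with columns transcript_id, gene_id, chrom, strand,
#'   exonic_length, tpm, retained, exclusion_reason.
#' @export
filterTranscripts <- function(ann, tpm, config = pipelineConfig()) {
    ids <- transcriptIds(ann)
    if (!all(ids %in% names(tpm)))
        stop("tpm must cover every transcript in the annotation")
    tpm <- tpm[ids]
    reasons <- vector("list", length(ids))
    failExpr <- !(tpm > config@tpmThreshold)
    failSplice <- config@requireSpliced & !isSpliced(ann)
    if (config@clearance > 0L) {
        failClear <- !downstreamClearance(ann, config@clearance)
    } else {
        failClear <- setNames(rep(FALSE, length(ids)), ids)
    }
    reason <- mapply(function(e, s, cl) {
        paste(c(if (e) "expression", if (s) "monoexonic",
                if (cl) "clearance"), collapse = ";")
    }, failExpr, failSplice, failClear)
    retained <- !nzchar(reason)
    spans <- transcriptRanges(ann)
    data.frame(transcript_id = ids,
               gene_id = unname(geneIds(ann)[ids]),
               chrom = as.character(seqnames(spans)),
               strand = as.character(strand(spans)),
               exonic_length = as.integer(exonicLengths(ann)[ids]),
               tpm = unname(tpm),
               retained = unname(retained),
               exclusion_reason = unname(reason),
               row.names = NULL, stringsAsFactors = FALSE)
}
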