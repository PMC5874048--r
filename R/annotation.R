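#' Construct a TranscriptAnnotation
#'
#' Builds the annotation container from a named \code{GRangesList} of exons.
#' Exons of each transcript are sorted by start; exons that overlap or abut
#' within one transcript are merged with a warning (tolerant of
#' assembler-produced GTFs).
#'
#' @param exons named \code{GRangesList}, one element per transcript.
#' @param geneId character vector of gene identifiers, parallel to
#'   \code{exons} (recycled if length 1).
#' @return a \linkS4class{TranscriptAnnotation}.
#' @export
TranscriptAnnotation <- function(exons, geneId) {
    if (length(exons) == 0L) {
        return(new("TranscriptAnnotation",
                   exons = GRangesList(),
                   geneId = character(0)))
    }
    if (length(geneId) == 1L)
        geneId <- rep(geneId, length(exons))
    ids <- names(exons)
    if (is.null(ids))
        stop("exons must be a named GRangesList (transcript identifiers)")
    names(geneId) <- ids
    flat <- unlist(exons, use.names = FALSE)
    mcols(flat) <- NULL
    grp <- rep(seq_along(exons), lengths(exons))
    o <- order(grp, BiocGenerics::start(flat))
    exons <- S4Vectors::split(flat[o], grp[o])
    names(exons) <- ids
    red <- IRanges::reduce(exons)
    if (!identical(unname(lengths(red)), unname(lengths(exons)))) {
        merged <- ids[lengths(red) != lengths(exons)]
        warning("merged overlapping exons within transcript(s): ",
                paste(head(merged, 5L), collapse = ", "),
                if (length(merged) > 5L) ", ...")
        exons <- red
    }
    new("TranscriptAnnotation", exons = exons, geneId = geneId)
}

#' Read a transcript annotation from GTF
#'
#' Parses exon features of a GTF file (1-based inclusive coordinates,
#' attributes must include \code{transcript_id} and \code{gene_id}) into a
#' \linkS4class{TranscriptAnnotation}. Non-exon features and comment lines
#' are ignored. Exons of one transcript must share chromosome and strand;
#' overlapping exons within a transcript are merged with a warning.
#'
#' @param path GTF file.
#' @param chromSizes optional two-column (chrom, length) tab-separated file;
#'   when given, chromosome lengths are attached and downstream windows that
#'   would leave a chromosome are flagged.
#' @return a \linkS4class{TranscriptAnnotation}.
#' @export
readGtf <- function(path, chromSizes = NULL) {
    if (!file.exists(path))
        stop("annotation file not found: ", path)
    gr <- tryCatch(
        suppressWarnings(rtracklayer::import(path, format = "gtf")),
        error = function(e) {
            # empty or comment-only files are a degenerate but legal input
            ln <- tryCatch(readLines(path, warn = FALSE),
                           error = function(e2) character(0))
            if (all(!nzchar(trimws(ln)) | startsWith(trimws(ln), "#")))
                return(GRanges())
            stop("failed to parse GTF '", path, "': ", conditionMessage(e))
        })
    ex <- gr[!is.na(S4Vectors::mcols(gr)$type) &
             as.character(S4Vectors::mcols(gr)$type) == "exon"]
    if (length(ex) == 0L) {
        warning("no exon features in '", path, "'; empty annotation")
        ann <- TranscriptAnnotation(GRangesList(), character(0))
        return(.attachChromSizes(ann, chromSizes))
    }
    tid <- S4Vectors::mcols(ex)$transcript_id
    gid <- S4Vectors::mcols(ex)$gene_id
    if (is.null(tid)) tid <- rep(NA_character_, length(ex))
    if (is.null(gid)) gid <- rep(NA_character_, length(ex))
    bad <- is.na(tid) | !nzchar(tid) | is.na(gid) | !nzchar(gid)
    if (any(bad)) {
        w <- which(bad)[1L]
        stop("exon feature missing transcript_id/gene_id attribute in '",
             path, "' (feature at ", seqnames(ex)[w], ":",
             BiocGenerics::start(ex)[w], "-", BiocGenerics::end(ex)[w], ")")
    }
    if (any(as.character(strand(ex)) == "*"))
        stop("exon features without strand in '", path, "'")
    byTx <- S4Vectors::split(granges(ex), tid)
    genePerTx <- vapply(S4Vectors::split(gid, tid),
                        function(g) unique(g)[1L], character(1))
    nGene <- vapply(S4Vectors::split(gid, tid),
                    function(g) length(unique(g)), integer(1))
    if (any(nGene > 1L))
        stop("transcript with multiple gene_id values: ",
             names(byTx)[nGene > 1L][1L])
    nC <- lengths(unique(seqnames(byTx)))
    nS <- lengths(unique(strand(byTx)))
    if (any(nC > 1L))
        stop("exons of transcript '", names(byTx)[nC > 1L][1L],
             "' lie on multiple chromosomes")
    if (any(nS > 1L))
        stop("exons of transcript '", names(byTx)[nS > 1L][1L],
             "' lie on mixed strands")
    ann <- TranscriptAnnotation(byTx, genePerTx[names(byTx)])
    .attachChromSizes(ann, chromSizes)
}

.attachChromSizes <- function(ann, chromSizes) {
    if (is.null(chromSizes))
        return(ann)
    cs <- data.table::fread(chromSizes, header = FALSE, sep = "\t",
                            col.names = c("chrom", "length"))
    if (length(ann) == 0L)
        return(ann)
    ex <- ann@exons
    sl <- setNames(cs$length, cs$chrom)
    keep <- intersect(seqlevels(ex), names(sl))
    seqlengths(ex)[keep] <- sl[keep]
    ann@exons <- ex
    ann
}

#' Write a TranscriptAnnotation as GTF
#'
#' Emits one exon line per exon (1-based inclusive coordinates) with
#' \code{transcript_id} and \code{gene_id} attributes; output is
#' deterministic (byte-identical for identical input).
#'
#' @param ann a \linkS4class{TranscriptAnnotation}.
#' @param path output file.
#' @param source value for the GTF source column.
#' @return \code{path}, invisibly.
#' @export
writeGtf <- function(ann, path, source = "txReadthrough") {
    ex <- unlist(ann@exons, use.names = FALSE)
    tid <- rep(names(ann@exons), lengths(ann@exons))
    gid <- ann@geneId[tid]
    lines <- sprintf(
        "%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
        as.character(seqnames(ex)), source,
        BiocGenerics::start(ex), BiocGenerics::end(ex),
        as.character(strand(ex)), gid, tid)
    writeLines(lines, path)
    invisible(path)
}

#' @describeIn TranscriptAnnotation-accessors number of transcripts.
#' @export
setMethod("length", "TranscriptAnnotation", function(x) length(x@exons))

#' Accessors for TranscriptAnnotation
#'
#' @param x a \linkS4class{TranscriptAnnotation}.
#' @param i transcript identifiers or indices.
#' @name TranscriptAnnotation-accessors
#' @aliases transcriptIds geneIds exonsByTranscript transcriptRanges
#'   isSpliced exonicLengths terminationSites
NULL

#' @rdname TranscriptAnnotation-accessors
#' @export
setMethod("transcriptIds", "TranscriptAnnotation",
          function(x) names(x@exons))

#' @rdname TranscriptAnnotation-accessors
#' @export
setMethod("geneIds", "TranscriptAnnotation", function(x) x@geneId)

#' @rdname TranscriptAnnotation-accessors
#' @export
setMethod("exonsByTranscript", "TranscriptAnnotation", function(x) x@exons)

#' @describeIn TranscriptAnnotation-accessors stranded genomic span
#'   (first exon start to last exon end) per transcript.
#' @export
setMethod("transcriptRanges", "TranscriptAnnotation", function(x) {
    sp <- unlist(range(x@exons), use.names = TRUE)
    sp
})

#' @describeIn TranscriptAnnotation-accessors TRUE for transcripts with at
#'   least two exons.
#' @export
setMethod("isSpliced", "TranscriptAnnotation",
          function(x) setNames(lengths(x@exons) >= 2L, names(x@exons)))

#' @describeIn TranscriptAnnotation-accessors summed exon widths in nt.
#' @export
setMethod("exonicLengths", "TranscriptAnnotation",
          function(x) setNames(sum(BiocGenerics::width(x@exons)),
                               names(x@exons)))

#' @describeIn TranscriptAnnotation-accessors width-1 GRanges at the last
#'   transcribed base (the TES) of each transcript.
#' @export
setMethod("terminationSites", "TranscriptAnnotation", function(x) {
    sp <- transcriptRanges(x)
    GenomicRanges::resize(sp, width = 1L, fix = "end")
})

#' @rdname TranscriptAnnotation-accessors
#' @export
setMethod("[", "TranscriptAnnotation", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) {
        missing <- setdiff(i, names(x@exons))
        if (length(missing))
            stop("transcript(s) not in annotation: ",
                 paste(head(missing, 5L), collapse = ", "))
    }
    new("TranscriptAnnotation",
        exons = x@exons[i],
        geneId = x@geneId[if (is.character(i)) i else names(x@exons)[i]])
})

setMethod("show", "TranscriptAnnotation", function(object) {
    n <- length(object)
    cat("TranscriptAnnotation with", n, "transcript(s)\n")
    if (n > 0L) {
        cat("  spliced:", sum(isSpliced(object)), " chromosomes:",
            paste(seqlevels(object@exons), collapse = ", "), "\n")
    }
})

#' Downstream clearance of transcript 3' ends
#'
#' For each transcript, reports whether the \code{distance} nucleotides
#' immediately downstream of its TES (increasing coordinates on \code{+},
#' decreasing on \code{-}) are free of any other same-strand transcript.
#' Transcripts of the same gene that share the identical TES are ignored, as
#' their read-through region is the same. Opposite-strand neighbours never
#' matter because the signal is strand-specific.
#'
#' @param ann a \linkS4class{TranscriptAnnotation}.
#' @param distance clearance distance in nt (>= 1).
#' @param transcripts transcript identifiers to test (default all).
#' @return named logical vector, TRUE = clear.
#' @export
downstreamClearance <- function(ann, distance,
                                transcripts = transcriptIds(ann)) {
    stopifnot(distance >= 1)
    missing <- setdiff(transcripts, transcriptIds(ann))
    if (length(missing))
        stop("transcript(s) not in annotation: ",
             paste(head(missing, 5L), collapse = ", "))
    spans <- transcriptRanges(ann)
    tes <- ifelse(as.character(strand(spans)) == "+",
                  BiocGenerics::end(spans), BiocGenerics::start(spans))
    down <- suppressWarnings(flank(spans[transcripts], width = as.integer(distance),
                                   start = FALSE))
    # clip windows that fall off the chromosome start; nothing can live there
    ns <- pmax(BiocGenerics::start(down), 1L)
    ne <- pmax(BiocGenerics::end(down), ns - 1L)
    IRanges::ranges(down) <- IRanges(ns, ne)
    hits <- GenomicRanges::findOverlaps(down, spans, ignore.strand = FALSE)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    qid <- transcripts[q]
    sid <- transcriptIds(ann)[s]
    sameSelf <- qid == sid
    sameGeneTes <- ann@geneId[qid] == ann@geneId[sid] &
        tes[match(qid, transcriptIds(ann))] == tes[s]
    blocked <- unique(q[!(sameSelf | sameGeneTes)])
    res <- rep(TRUE, length(transcripts))
    res[blocked] <- FALSE
    setNames(res, transcripts)
}
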