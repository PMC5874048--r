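#' @import methods
#' @import BiocGenerics
#' @importFrom S4Vectors mcols mcols<- Rle runValue runLength DataFrame
#' @importFrom IRanges IRanges Views viewSums RleList coverage
#' @importFrom GenomicRanges GRanges GRangesList strand strand<- seqnames
#'   granges flank
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqinfo
#' @importFrom data.table data.table fread fwrite rbindlist
#' @importFrom stats rlnorm rpois runif quantile setNames
#' @importFrom utils packageVersion head tail
NULL

#' Transcript annotation with exon structure
#'
#' Holds a set of stranded, exon-structured transcript models: for every
#' transcript, its exons as a \linkS4class{GRanges} (sorted, non-overlapping,
#' one chromosome, one strand) plus the identifier of the gene it belongs to.
#' The 3' end of each transcript (its transcription end site, TES) is the
#' reference point for all downstream read-through windows.
#'
#' @slot exons a named \linkS4class{GRangesList}, one element per transcript,
#'   names are transcript identifiers (unique).
#' @slot geneId named character vector, gene identifier per transcript,
#'   names parallel to \code{exons}.
#'
#' @seealso [readGtf()], [transcriptRanges()], [downstreamClearance()]
#' @export
setClass("TranscriptAnnotation",
    slots = c(
        exons = "CompressedGRangesList",
        geneId = "character"
    )
)

setValidity("TranscriptAnnotation", function(object) {
    ex <- object@exons
    ids <- names(ex)
    if (length(ex) != length(object@geneId))
        return("geneId must have one entry per transcript")
    if (length(ex) == 0L)
        return(TRUE)
    if (is.null(ids) || anyDuplicated(ids))
        return("transcript identifiers must be present and unique")
    if (!identical(ids, names(object@geneId)))
        return("names of geneId must match names of exons")
    st <- unlist(runValue(strand(ex)), use.names = FALSE)
    if (!all(st %in% c("+", "-")))
        return("every exon must be on strand '+' or '-'")
    nchrom <- lengths(runValue(seqnames(ex)))
    nstrand <- lengths(runValue(strand(ex)))
    if (any(nchrom != 1L) || any(nstrand != 1L))
        return("all exons of one transcript must share chromosome and strand")
    TRUE
})

#' Strand-specific per-base coverage
#'
#' Per-base, non-negative signal held separately for the two genomic strands
#' as run-length encoded vectors (one \code{Rle} per chromosome and strand).
#' Positions beyond the stored length, or on chromosomes with no data, have
#' value zero. Units are arbitrary (read-bases per position as produced by a
#' stranded RNA-seq protocol).
#'
#' @slot plus,minus \code{RleList}, one numeric \code{Rle} per chromosome.
#'
#' @seealso [readBedGraphPair()], [intervalSum()], [coverageFromBam()]
#' @export
setClass("StrandedCoverage",
    slots = c(plus = "SimpleRleList", minus = "SimpleRleList")
)

setValidity("StrandedCoverage", function(object) {
    for (sl in c("plus", "minus")) {
        rl <- slot(object, sl)
        if (length(rl)) {
            if (is.null(names(rl)) || anyDuplicated(names(rl)))
                return("coverage chromosomes must be uniquely named")
            vals <- unlist(lapply(rl, runValue), use.names = FALSE)
            if (any(is.na(vals)) || any(vals < 0))
                return("coverage values must be non-negative and non-missing")
        }
    }
    TRUE
})

#' Analysis parameters for the read-through pipeline
#'
#' @slot windowSize window width W in nucleotides (default 250).
#' @slot nWindows number K of downstream windows (default 20, i.e. 5 kb).
#' @slot tpmThreshold transcripts are retained when TPM is strictly greater
#'   than this value (default 10).
#' @slot requireSpliced keep only transcripts with at least two exons.
#' @slot clearance nucleotides downstream of the TES that must be free of
#'   other same-strand transcripts (default K*W).
#' @slot terminalFloor minimum signal in the terminal window for a transcript
#'   to enter the meta-gene (guards the normalization ratio; default 1).
#' @slot aggregation \code{"mean_of_ratios"} (per-transcript normalization,
#'   then averaging) or \code{"pooled_ratio"} (sum of window signals over sum
#'   of terminal signals).
#' @slot seed integer seed driving all randomness (bootstrap).
#'
#' @seealso [pipelineConfig()]
#' @export
setClass("PipelineConfig",
    slots = c(
        windowSize = "integer",
        nWindows = "integer",
        tpmThreshold = "numeric",
        requireSpliced = "logical",
        clearance = "integer",
        terminalFloor = "numeric",
        aggregation = "character",
        seed = "integer"
    )
)

setValidity("PipelineConfig", function(object) {
    if (object@windowSize < 1L) return("windowSize must be >= 1")
    if (object@nWindows < 1L) return("nWindows must be >= 1")
    if (object@tpmThreshold < 0) return("tpmThreshold must be >= 0")
    if (object@clearance < 0L) return("clearance must be >= 0")
    if (object@terminalFloor <= 0) return("terminalFloor must be > 0")
    if (!object@aggregation %in% c("mean_of_ratios", "pooled_ratio"))
        return("aggregation must be 'mean_of_ratios' or 'pooled_ratio'")
    TRUE
})

#' Per-transcript read-through profiles
#'
#' One row per transcript: the raw signal in each of K downstream windows,
#' the signal in the terminal window (last W nt of the gene body), and the
#' terminal-normalized window values. Transcripts whose terminal signal is
#' below the configured floor, whose span is shorter than one window, or
#' whose windows leave the chromosome are marked invalid with a reason and
#' excluded from aggregation.
#'
#' @slot transcriptId character, one per profile.
#' @slot terminalSignal numeric, signal in the terminal window.
#' @slot windowSignals numeric matrix (transcripts x K), raw window signal.
#' @slot normalized numeric matrix (transcripts x K), windowSignals divided
#'   by terminalSignal (NA rows for invalid profiles).
#' @slot valid logical, profile enters aggregation.
#' @slot reason character, empty or one of \code{"terminal-floor"},
#'   \code{"short-span"}, \code{"out-of-bounds"}.
#' @slot terminalExonShort logical, terminal exon shorter than W (measured
#'   genomically anyway; audit flag only).
#' @slot condition,replicate character scalars labelling provenance.
#' @slot windowSize,nWindows,terminalFloor the parameters used.
#'
#' @seealso [transcriptProfiles()], [metageneProfile()]
#' @export
setClass("TranscriptProfileSet",
    slots = c(
        transcriptId = "character",
        terminalSignal = "numeric",
        windowSignals = "matrix",
        normalized = "matrix",
        valid = "logical",
        reason = "character",
        terminalExonShort = "logical",
        condition = "character",
        replicate = "character",
        windowSize = "integer",
        nWindows = "integer",
        terminalFloor = "numeric"
    )
)

setValidity("TranscriptProfileSet", function(object) {
    n <- length(object@transcriptId)
    if (length(object@terminalSignal) != n || nrow(object@windowSignals) != n ||
        nrow(object@normalized) != n || length(object@valid) != n ||
        length(object@reason) != n || length(object@terminalExonShort) != n)
        return("all per-transcript slots must have the same length")
    if (ncol(object@windowSignals) != object@nWindows ||
        ncol(object@normalized) != object@nWindows)
        return("window matrices must have nWindows columns")
    ok <- object@normalized[object@valid, , drop = FALSE]
    if (length(ok) && any(is.na(ok) | ok < 0))
        return("normalized values of valid profiles must be >= 0")
    TRUE
})

#' Meta-gene read-through profile
#'
#' Cross-transcript aggregate of terminal-normalized downstream signal for
#' one condition/replicate: per window position, the mean, standard deviation
#' and the (constant) number of contributing transcripts, under one of two
#' aggregation modes.
#'
#' @slot condition,replicate character scalars.
#' @slot mode \code{"mean_of_ratios"} or \code{"pooled_ratio"}.
#' @slot stats data.frame with columns \code{window}, \code{distance_nt}
#'   (offset of the window start from the TES), \code{mean}, \code{sd},
#'   \code{n}.
#'
#' @seealso [metageneProfile()]
#' @export
setClass("MetaGeneProfile",
    slots = c(
        condition = "character",
        replicate = "character",
        mode = "character",
        stats = "data.frame"
    )
)

#' Parameters of the stranded-coverage simulator
#'
#' Describes a synthetic genome of non-overlapping transcripts on one
#' chromosome and a generative model for strand-specific coverage: uniform
#' expected per-base coverage \code{c_t} (log-normal across transcripts) on
#' exons, and downstream of each TES a read-through component
#' \code{alpha * c_t * exp(-d / decayLength)} truncated at
#' \code{readthroughExtent}, with optional uniform background and per-base
#' Poisson noise.
#'
#' @slot nTranscripts number of transcripts.
#' @slot chromLength chromosome length in nt; \code{NA} chooses the smallest
#'   feasible length for the packing.
#' @slot exonCountRange,exonLengthRange,intronLengthRange integer ranges
#'   (min, max) for exon structures.
#' @slot splicedFraction fraction of transcripts with >= 2 exons.
#' @slot expressionMeanlog,expressionSdlog log-normal parameters of c_t.
#' @slot decayLength read-through decay length scale lambda in nt.
#' @slot readthroughExtent maximal read-through distance D_max in nt.
#' @slot background uniform per-base background beta.
#' @slot intergenicMinGap minimal same-strand gap between transcripts in nt.
#' @slot replicates replicates per condition.
#' @slot seed integer seed.
#'
#' @seealso [simulationParams()], [simulateAnnotation()], [simulateCoverage()]
#' @export
setClass("SimulationParams",
    slots = c(
        nTranscripts = "integer",
        chromLength = "integer",
        exonCountRange = "integer",
        exonLengthRange = "integer",
        intronLengthRange = "integer",
        splicedFraction = "numeric",
        expressionMeanlog = "numeric",
        expressionSdlog = "numeric",
        decayLength = "numeric",
        readthroughExtent = "integer",
        background = "numeric",
        intergenicMinGap = "integer",
        replicates = "integer",
        seed = "integer"
    )
)

setValidity("SimulationParams", function(object) {
    if (object@nTranscripts < 1L) return("nTranscripts must be >= 1")
    if (object@splicedFraction < 0 || object@splicedFraction > 1)
        return("splicedFraction must be in [0, 1]")
    if (object@decayLength <= 0) return("decayLength must be > 0")
    if (object@readthroughExtent < 1L) return("readthroughExtent must be >= 1")
    if (object@background < 0) return("background must be >= 0")
    if (object@intergenicMinGap < 1L) return("intergenicMinGap must be >= 1")
    if (object@replicates < 1L) return("replicates must be >= 1")
    rngs <- list(object@exonCountRange, object@exonLengthRange,
                 object@intronLengthRange)
    for (r in rngs)
        if (length(r) != 2L || r[1] > r[2] || r[1] < 1L)
            return("ranges must be integer pairs (min, max), min >= 1")
    TRUE
})
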