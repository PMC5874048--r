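#' @rdname intervalSum
#' @export
setGeneric("intervalSum", function(x, regions, ...)
    standardGeneric("intervalSum"))

#' @rdname StrandedCoverage-accessors
#' @export
setGeneric("strandCoverage", function(x, strand)
    standardGeneric("strandCoverage"))

#' @rdname StrandedCoverage-accessors
#' @export
setGeneric("totalSignal", function(x) standardGeneric("totalSignal"))

#' @rdname StrandedCoverage-accessors
#' @export
setGeneric("scaleCoverage", function(x, factor)
    standardGeneric("scaleCoverage"))

#' @rdname TranscriptAnnotation-accessors
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))

#' @rdname TranscriptAnnotation-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname TranscriptAnnotation-accessors
#' @export
setGeneric("exonsByTranscript", function(x) standardGeneric("exonsByTranscript"))

#' @rdname TranscriptAnnotation-accessors
#' @export
setGeneric("transcriptRanges", function(x) standardGeneric("transcriptRanges"))

#' @rdname TranscriptAnnotation-accessors
#' @export
setGeneric("isSpliced", function(x) standardGeneric("isSpliced"))

#' @rdname TranscriptAnnotation-accessors
#' @export
setGeneric("exonicLengths", function(x) standardGeneric("exonicLengths"))

#' @rdname TranscriptAnnotation-accessors
#' @export
setGeneric("terminationSites", function(x) standardGeneric("terminationSites"))
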