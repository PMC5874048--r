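#' Strand-specific coverage from dUTP paired-end alignments
#'
#' Builds \linkS4class{StrandedCoverage} from a coordinate-sorted, indexed
#' BAM of paired-end reads from a dUTP stranded library. Each properly
#' paired fragment adds 1 to every base it covers — the union of the aligned
#' blocks of both mates, so intronic N-gaps receive nothing and a
#' mate-overlap region is counted once. Under the dUTP (reverse) convention
#' the fragment strand is the alignment strand of read 2, i.e. opposite to
#' read 1: the chemistry destroys the dUTP-marked second cDNA strand, so
#' read 2 carries the transcript strand. Secondary, supplementary and
#' duplicate-flagged alignments are ignored.
#'
#' @param path BAM file; \code{<path>.bai} index must exist.
#' @param library library chemistry; only \code{"dutp-reverse"} is supported.
#' @return a \linkS4class{StrandedCoverage}.
#' @export
coverageFromBam <- function(path, library = "dutp-reverse") {
    if (!requireNamespace("Rsamtools", quietly = TRUE) ||
        !requireNamespace("GenomicAlignments", quietly = TRUE))
        stop("coverageFromBam needs the Rsamtools and GenomicAlignments packages")
    if (!file.exists(path))
        stop("BAM file not found: ", path)
    if (!identical(library, "dutp-reverse"))
        stop("unknown library code '", library,
             "'; supported: 'dutp-reverse'")
    idx <- paste0(path, ".bai")
    if (!file.exists(idx) && !file.exists(sub("\\.bam$", ".bai", path)))
        stop("BAM index not found for '", path, "' (expected ", idx, ")")
    flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE,
                                   isDuplicate = FALSE,
                                   isProperPair = TRUE)
    param <- Rsamtools::ScanBamParam(flag = flag)
    # strandMode = 2: strand of the pair = strand of the last (second) mate
    ga <- GenomicAlignments::readGAlignmentPairs(path, param = param,
                                                 strandMode = 2)
    if (length(ga) == 0L) {
        sl <- seqlengths(ga)
        empty <- as(lapply(sl, function(n) Rle(0, n)), "SimpleRleList")
        return(new("StrandedCoverage", plus = empty, minus = empty))
    }
    frags <- IRanges::reduce(GenomicAlignments::grglist(ga))
    fragStrand <- as.character(strand(ga))
    flat <- unlist(frags, use.names = FALSE)
    blockStrand <- rep(fragStrand, lengths(frags))
    covFor <- function(s) {
        gr <- flat[blockStrand == s]
        as(coverage(gr), "SimpleRleList")
    }
    StrandedCoverage(plus = covFor("+"), minus = covFor("-"))
}
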