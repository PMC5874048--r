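#' Simulation parameter constructor
#'
#' Defaults describe the emulated study design: a few hundred well-separated
#' transcripts on one synthetic chromosome, mostly spliced, with log-normal
#' expression around ~20 read-bases per position, read-through decaying over
#' lambda = 1 kb and truncated at 5 kb, no background, and triplicate
#' libraries per condition.
#'
#' @param nTranscripts number of transcripts (default 200).
#' @param chromLength chromosome length in nt; \code{NA} (default) picks the
#'   smallest length that fits the packing.
#' @param exonCountRange,exonLengthRange,intronLengthRange integer
#'   (min, max) ranges for exon structures. The exon length minimum (300)
#'   stays above the 250-nt analysis window so the terminal reference window
#'   is always fully exonic, as the uniform-coverage model assumes.
#' @param splicedFraction fraction of transcripts with >= 2 exons
#'   (default 0.9).
#' @param expressionMeanlog,expressionSdlog log-normal parameters of the
#'   per-base expected coverage c_t (default meanlog 3, sdlog 1).
#' @param decayLength read-through decay length lambda in nt (default 1000).
#' @param readthroughExtent maximal read-through distance D_max in nt
#'   (default 5000).
#' @param background uniform per-base background (default 0).
#' @param intergenicMinGap minimal gap between transcripts in nt
#'   (default 6000, above the default 5 kb clearance).
#' @param replicates libraries per condition (default 3).
#' @param seed integer seed.
#' @return a \linkS4class{SimulationParams}.
#' @export
simulationParams <- function(nTranscripts = 200, chromLength = NA,
                             exonCountRange = c(1, 5),
                             exonLengthRange = c(300, 800),
                             intronLengthRange = c(100, 1000),
                             splicedFraction = 0.9,
                             expressionMeanlog = 3, expressionSdlog = 1,
                             decayLength = 1000, readthroughExtent = 5000,
                             background = 0, intergenicMinGap = 6000,
                             replicates = 3, seed = 1) {
    new("SimulationParams",
        nTranscripts = as.integer(nTranscripts),
        chromLength = as.integer(chromLength),
        exonCountRange = as.integer(exonCountRange),
        exonLengthRange = as.integer(exonLengthRange),
        intronLengthRange = as.integer(intronLengthRange),
        splicedFraction = as.numeric(splicedFraction),
        expressionMeanlog = as.numeric(expressionMeanlog),
        expressionSdlog = as.numeric(expressionSdlog),
        decayLength = as.numeric(decayLength),
        readthroughExtent = as.integer(readthroughExtent),
        background = as.numeric(background),
        intergenicMinGap = as.integer(intergenicMinGap),
        replicates = as.integer(replicates),
        seed = as.integer(seed))
}

setMethod("show", "SimulationParams", function(object) {
    cat(sprintf(paste0(
        "SimulationParams: %d transcripts, lambda=%g nt, D_max=%d nt,\n",
        "  spliced fraction %g, expression lognormal(%g, %g), gap %d nt,\n",
        "  %d replicate(s), seed %d\n"),
        object@nTranscripts, object@decayLength, object@readthroughExtent,
        object@splicedFraction, object@expressionMeanlog,
        object@expressionSdlog, object@intergenicMinGap,
        object@replicates, object@seed))
})

.simChrom <- "chrS"

#' Simulate a transcript annotation with known structure
#'
#' Places \code{nTranscripts} non-overlapping transcripts left to right on
#' one synthetic chromosome, every pair separated by at least
#' \code{max(intergenicMinGap, readthroughExtent)} so that no read-through
#' region touches a neighbouring transcript and the default clearance filter
#' passes by construction. Strands are assigned at random (seeded); exon
#' structures are drawn within the configured ranges. Deterministic:
#' identical parameters and seed give byte-identical GTF output via
#' [writeGtf()].
#'
#' @param params a \linkS4class{SimulationParams}.
#' @return list with elements \code{annotation}
#'   (\linkS4class{TranscriptAnnotation} with the chromosome length set) and
#'   \code{truth} (data.frame: transcript_id, gene_id, strand, tes, c_t,
#'   spliced), carrying the resolved parameters as attribute
#'   \code{"params"}.
#' @export
simulateAnnotation <- function(params = simulationParams()) {
    n <- params@nTranscripts
    gap <- max(params@intergenicMinGap, params@readthroughExtent)
    margin <- gap + 1L
    res <- .withSeed(params@seed, {
        spliced <- runif(n) < params@splicedFraction
        nEx <- ifelse(spliced,
                      .runifInt(n, max(2L, params@exonCountRange[1L]),
                                max(2L, params@exonCountRange[2L])),
                      1L)
        if (params@splicedFraction > 0 && params@exonCountRange[2L] < 2L)
            stop("exonCountRange maximum must be >= 2 when splicedFraction > 0")
        strands <- sample(c("+", "-"), n, replace = TRUE)
        cT <- rlnorm(n, params@expressionMeanlog, params@expressionSdlog)
        exonList <- vector("list", n)
        cur <- margin
        for (i in seq_len(n)) {
            ew <- .runifInt(nEx[i], params@exonLengthRange[1L],
                            params@exonLengthRange[2L])
            iw <- if (nEx[i] > 1L)
                .runifInt(nEx[i] - 1L, params@intronLengthRange[1L],
                          params@intronLengthRange[2L]) else integer(0)
            starts <- cur + cumsum(c(0L, head(ew, -1L) + iw))
            exonList[[i]] <- IRanges(starts, width = ew)
            cur <- max(starts + ew - 1L) + gap + 1L
        }
        list(spliced = spliced, strands = strands, cT = cT,
             exonList = exonList, lastEnd = cur - gap - 1L)
    })
    needed <- res$lastEnd + margin
    chromLength <- params@chromLength
    if (is.na(chromLength)) {
        chromLength <- as.integer(needed)
    } else if (chromLength < needed) {
        stop("chromLength too small for the requested packing; need at least ",
             needed, " nt")
    }
    ids <- sprintf("TX%04d", seq_len(n))
    nper <- lengths(res$exonList)
    flat <- GRanges(.simChrom,
                    unlist(as(res$exonList, "IRangesList"), use.names = FALSE),
                    strand = rep(res$strands, nper))
    exons <- S4Vectors::split(flat, factor(rep(ids, nper), levels = ids))
    ann <- TranscriptAnnotation(exons, setNames(sprintf("G%04d", seq_len(n)),
                                                ids))
    sl <- setNames(chromLength, .simChrom)
    ex <- ann@exons
    seqlengths(ex) <- sl
    ann@exons <- ex
    spans <- transcriptRanges(ann)
    tes <- ifelse(res$strands == "+", BiocGenerics::end(spans),
                  BiocGenerics::start(spans))
    truth <- data.frame(transcript_id = ids,
                        gene_id = sprintf("G%04d", seq_len(n)),
                        strand = res$strands,
                        tes = as.integer(tes),
                        c_t = res$cT,
                        spliced = lengths(ann@exons) >= 2L,
                        row.names = NULL, stringsAsFactors = FALSE)
    resolved <- params
    resolved@chromLength <- as.integer(chromLength)
    attr(truth, "params") <- resolved
    list(annotation = ann, truth = truth)
}

.runifInt <- function(n, lo, hi) {
    if (lo == hi) rep(as.integer(lo), n)
    else as.integer(sample(seq.int(lo, hi), n, replace = TRUE))
}

#' Simulate strand-specific coverage with known read-through
#'
#' Expected per-base coverage is \code{c_t} on the exons of transcript t (on
#' its strand), \code{alpha * c_t * exp(-d / lambda)} at distance d in
#' [0, D_max) downstream of its TES, and \code{background} elsewhere on both
#' strands. Realized values are drawn per base as Poisson of the expectation
#' (\code{noise = "poisson"}) or taken as the expectation itself
#' (\code{noise = "none"}, the analytic regime of [expectedMetagene()]).
#'
#' @param ann annotation from [simulateAnnotation()].
#' @param truth matching truth table.
#' @param alpha read-through fraction of this condition, in [0, 1].
#' @param params the \linkS4class{SimulationParams} used.
#' @param seed seed of this replicate.
#' @param noise \code{"poisson"} or \code{"none"}.
#' @return a \linkS4class{StrandedCoverage}.
#' @export
simulateCoverage <- function(ann, truth, alpha,
                             params = attr(truth, "params"),
                             seed = params@seed, noise = c("poisson", "none")) {
    noise <- match.arg(noise)
    stopifnot(alpha >= 0, alpha <= 1)
    L <- params@chromLength
    if (is.na(L))
        L <- seqlengths(ann@exons)[[.simChrom]]
    lam <- params@decayLength
    Dmax <- params@readthroughExtent
    expPlus <- rep(params@background, L)
    expMinus <- rep(params@background, L)
    spans <- transcriptRanges(ann)
    decay <- exp(-(seq_len(Dmax) - 1L) / lam)
    for (i in seq_along(spans)) {
        s <- truth$strand[i]
        cT <- truth$c_t[i]
        ex <- ann@exons[[i]]
        pos <- unlist(lapply(seq_along(ex), function(j)
            seq.int(BiocGenerics::start(ex)[j], BiocGenerics::end(ex)[j])),
            use.names = FALSE)
        if (s == "+") expPlus[pos] <- expPlus[pos] + cT
        else expMinus[pos] <- expMinus[pos] + cT
        if (alpha > 0) {
            if (s == "+") {
                from <- BiocGenerics::end(spans)[i] + 1L
                if (from <= L) {
                    dpos <- seq.int(from, min(from + Dmax - 1L, L))
                    expPlus[dpos] <- expPlus[dpos] +
                        alpha * cT * decay[seq_along(dpos)]
                }
            } else {
                from <- BiocGenerics::start(spans)[i] - 1L
                if (from >= 1L) {
                    dpos <- seq.int(from, max(from - Dmax + 1L, 1L))
                    expMinus[dpos] <- expMinus[dpos] +
                        alpha * cT * decay[seq_along(dpos)]
                }
            }
        }
    }
    realize <- function(v) {
        if (noise == "none")
            return(Rle(v))
        nz <- which(v > 0)
        out <- numeric(length(v))
        out[nz] <- rpois(length(nz), v[nz])
        Rle(out)
    }
    .withSeed(seed, {
        plus <- realize(expPlus)
        minus <- realize(expMinus)
        StrandedCoverage(
            plus = setNames(RleList(plus), .simChrom),
            minus = setNames(RleList(minus), .simChrom))
    })
}

#' Analytic meta-gene expectation of the simulator
#'
#' Closed-form noiseless terminal-normalized value of downstream window k
#' under the exponential-decay read-through model: the continuous
#' approximation of (window-k sum) / (terminal-window sum) on expected
#' coverage,
#' \deqn{alpha (lambda/W) e^{-(k-1)W/lambda} (1 - e^{-W/lambda}).}
#' The discrete per-base sum differs from this by less than 0.5% for
#' lambda >= 500 and W = 250.
#'
#' @param alpha read-through fraction.
#' @param decayLength decay length lambda in nt.
#' @param windowSize window width W in nt.
#' @param k window index (vectorized), 1-based.
#' @return expected normalized window value(s).
#' @export
expectedMetagene <- function(alpha, decayLength, windowSize, k) {
    stopifnot(decayLength > 0, windowSize >= 1, all(k >= 1))
    alpha * (decayLength / windowSize) *
        exp(-(k - 1) * windowSize / decayLength) *
        (1 - exp(-windowSize / decayLength))
}

#' Write a complete simulated fixture bundle
#'
#' Generates one annotation and, for every condition x replicate, a
#' strand-specific coverage pair, and writes \code{annotation.gtf},
#' \code{<condition>_rep<i>.plus/.minus.bedgraph}, \code{truth.tsv} and
#' \code{params.yaml} into \code{dir}. Replicate seeds are derived
#' deterministically from \code{params@seed}.
#'
#' @param params a \linkS4class{SimulationParams}.
#' @param dir output directory (created if needed).
#' @param conditions named numeric vector of read-through fractions per
#'   condition (default wildtype 0.05, mutant 0.6, the emulated contrast of
#'   active versus catalytically dead XRN2).
#' @param noise passed to [simulateCoverage()].
#' @return invisibly, a list with the annotation, truth and file paths.
#' @export
simulateBundle <- function(params = simulationParams(), dir,
                           conditions = c(wildtype = 0.05, mutant = 0.6),
                           noise = "poisson") {
    stopifnot(!is.null(names(conditions)), all(nzchar(names(conditions))))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    sim <- simulateAnnotation(params)
    resolved <- attr(sim$truth, "params")
    gtf <- file.path(dir, "annotation.gtf")
    writeGtf(sim$annotation, gtf)
    truthPath <- file.path(dir, "truth.tsv")
    data.table::fwrite(sim$truth, truthPath, sep = "\t")
    files <- list(annotation = gtf, truth = truthPath)
    covFiles <- list()
    for (ci in seq_along(conditions)) {
        cname <- names(conditions)[ci]
        for (r in seq_len(params@replicates)) {
            seed <- .replicateSeed(params@seed, ci, r)
            cov <- simulateCoverage(sim$annotation, sim$truth,
                                    alpha = conditions[[ci]],
                                    params = resolved, seed = seed,
                                    noise = noise)
            prefix <- file.path(dir, sprintf("%s_rep%d", cname, r))
            covFiles[[sprintf("%s_rep%d", cname, r)]] <-
                writeBedGraphPair(cov, prefix)
        }
    }
    cfg <- list(
        chrom = .simChrom,
        chrom_length = resolved@chromLength,
        n_transcripts = resolved@nTranscripts,
        spliced_fraction = resolved@splicedFraction,
        expression_meanlog = resolved@expressionMeanlog,
        expression_sdlog = resolved@expressionSdlog,
        decay_length = resolved@decayLength,
        readthrough_extent = resolved@readthroughExtent,
        background = resolved@background,
        intergenic_min_gap = resolved@intergenicMinGap,
        replicates = resolved@replicates,
        seed = resolved@seed,
        noise = noise,
        conditions = as.list(conditions))
    paramsPath <- file.path(dir, "params.yaml")
    yaml::write_yaml(cfg, paramsPath)
    files$params <- paramsPath
    files$coverage <- covFiles
    invisible(list(annotation = sim$annotation, truth = sim$truth,
                   files = files))
}

# deterministic per-replicate seed stream, kept within 32-bit range
.replicateSeed <- function(seed, conditionIndex, replicate) {
    as.integer((as.numeric(seed) + 104729 * conditionIndex +
                7919 * replicate) %% .Machine$integer.max)
}
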