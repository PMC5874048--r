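#' Construct a StrandedCoverage
#'
#' @param plus,minus named \code{RleList} (or named list of numeric vectors),
#'   one element per chromosome.
#' @return a \linkS4class{StrandedCoverage}.
#' @export
StrandedCoverage <- function(plus = RleList(), minus = RleList()) {
    new("StrandedCoverage",
        plus = .asNumericRleList(plus),
        minus = .asNumericRleList(minus))
}

.asNumericRleList <- function(x) {
    if (is(x, "RleList")) {
        x <- as(x, "SimpleRleList")
        for (i in seq_along(x))
            if (!is.numeric(runValue(x[[i]])))
                x[[i]] <- Rle(as.numeric(runValue(x[[i]])),
                              runLength(x[[i]]))
        return(x)
    }
    as(lapply(x, function(v) Rle(as.numeric(v))), "SimpleRleList")
}

.parseBedGraph <- function(path) {
    if (!file.exists(path))
        stop("coverage file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    tl <- trimws(lines)
    keep <- nzchar(tl) & !startsWith(tl, "#") &
        !startsWith(tl, "track") & !startsWith(tl, "browser")
    if (!any(keep))
        return(data.table::data.table(chrom = character(0),
                                      start = integer(0), end = integer(0),
                                      value = numeric(0)))
    lineNo <- which(keep)
    parts <- strsplit(tl[keep], "[\t ]+")
    nf <- lengths(parts)
    if (any(nf != 4L))
        stop("malformed bedGraph line (expected 4 fields) in '",
             path, "', line ", lineNo[which(nf != 4L)[1L]])
    m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
    start <- suppressWarnings(as.integer(m[, 2L]))
    end <- suppressWarnings(as.integer(m[, 3L]))
    value <- suppressWarnings(as.numeric(m[, 4L]))
    bad <- is.na(start) | is.na(end) | is.na(value)
    if (any(bad))
        stop("non-numeric coordinates or value in '", path, "', line ",
             lineNo[which(bad)[1L]])
    if (any(end <= start))
        stop("zero- or negative-length interval in '", path, "', line ",
             lineNo[which(end <= start)[1L]])
    if (any(value < 0))
        stop("negative coverage value in '", path, "', line ",
             lineNo[which(value < 0)[1L]])
    dt <- data.table::data.table(chrom = m[, 1L], start = start, end = end,
                                 value = value, line = lineNo)
    ord <- order(dt$chrom, dt$start, method = "radix")
    dts <- dt[ord]
    ovl <- dts$chrom[-1L] == dts$chrom[-nrow(dts)] &
        dts$start[-1L] < dts$end[-nrow(dts)]
    if (length(ovl) && any(ovl)) {
        i <- which(ovl)[1L]
        stop("overlapping intervals in '", path, "', lines ",
             dts$line[i], " and ", dts$line[i + 1L])
    }
    dt[, c("chrom", "start", "end", "value"), with = FALSE]
}

.rleListFromBedGraph <- function(dt) {
    if (nrow(dt) == 0L)
        return(as(list(), "SimpleRleList"))
    byChrom <- split(dt, dt$chrom)
    rl <- lapply(byChrom, function(d) {
        len <- max(d$end)
        coverage(IRanges(d$start + 1L, d$end), weight = as.numeric(d$value),
                 width = len)
    })
    as(rl, "SimpleRleList")
}

#' Read strand-specific coverage from a bedGraph pair
#'
#' Reads one bedGraph file per strand (0-based half-open intervals, four
#' tab-separated columns). Intervals within one file must not overlap;
#' values must be non-negative; track/browser/comment lines are skipped.
#' Violations raise an error naming the file and line.
#'
#' @param plusPath,minusPath bedGraph files for the + and - strand.
#' @return a \linkS4class{StrandedCoverage}.
#' @export
readBedGraphPair <- function(plusPath, minusPath) {
    new("StrandedCoverage",
        plus = .rleListFromBedGraph(.parseBedGraph(plusPath)),
        minus = .rleListFromBedGraph(.parseBedGraph(minusPath)))
}

#' Write strand-specific coverage as a bedGraph pair
#'
#' Emits sorted, non-overlapping runs of non-zero value, 0-based half-open,
#' to \code{<prefix>.plus.bedgraph} and \code{<prefix>.minus.bedgraph}.
#' Output is deterministic.
#'
#' @param cov a \linkS4class{StrandedCoverage}.
#' @param prefix output path prefix.
#' @return named character vector of the two paths, invisibly.
#' @export
writeBedGraphPair <- function(cov, prefix) {
    paths <- c(plus = paste0(prefix, ".plus.bedgraph"),
               minus = paste0(prefix, ".minus.bedgraph"))
    for (s in c("plus", "minus"))
        .writeBedGraph(slot(cov, s), paths[[s]])
    invisible(paths)
}

.writeBedGraph <- function(rl, path) {
    rows <- lapply(sort(names(rl)), function(chrom) {
        r <- rl[[chrom]]
        ends <- cumsum(runLength(r))
        starts <- ends - runLength(r)      # 0-based starts
        v <- runValue(r)
        nz <- v != 0
        if (!any(nz)) return(NULL)
        data.table::data.table(chrom = chrom, start = starts[nz],
                               end = ends[nz], value = v[nz])
    })
    dt <- data.table::rbindlist(rows)
    if (nrow(dt) == 0L) {
        file.create(path)
        return(invisible(path))
    }
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE,
                       scipen = 50L)
    invisible(path)
}

#' Sum coverage over genomic intervals
#'
#' Exact per-base sum of the stranded signal over each query interval;
#' positions outside the stored coverage (or whole chromosomes without data)
#' contribute zero. Queries must carry strand \code{+} or \code{-}.
#'
#' @param x a \linkS4class{StrandedCoverage}.
#' @param regions a stranded \code{GRanges}.
#' @return numeric vector parallel to \code{regions}.
#' @name intervalSum
#' @export
setMethod("intervalSum", c("StrandedCoverage", "GRanges"),
          function(x, regions, ...) {
    res <- numeric(length(regions))
    st <- as.character(strand(regions))
    if (any(st == "*"))
        stop("intervalSum requires stranded query intervals")
    ch <- as.character(seqnames(regions))
    for (s in c("+", "-")) {
        rl <- if (s == "+") x@plus else x@minus
        idx <- which(st == s)
        if (!length(idx)) next
        for (chrom in unique(ch[idx])) {
            ii <- idx[ch[idx] == chrom]
            r <- rl[[chrom]]
            if (is.null(r)) next
            len <- length(r)
            qs <- pmax(BiocGenerics::start(regions)[ii], 1L)
            qe <- pmin(BiocGenerics::end(regions)[ii], len)
            ok <- qs <= qe
            if (!any(ok)) next
            res[ii[ok]] <- viewSums(Views(r, qs[ok], qe[ok]))
        }
    }
    res
})

#' Accessors and arithmetic for StrandedCoverage
#'
#' \code{strandCoverage} returns the per-chromosome \code{RleList} of one
#' strand; \code{totalSignal} the grand sum of all per-base values;
#' \code{scaleCoverage} multiplies every value by a positive constant
#' (sequencing-depth rescaling; terminal-normalized profiles are invariant
#' under it).
#'
#' @param x a \linkS4class{StrandedCoverage}.
#' @param strand \code{"+"} or \code{"-"}.
#' @param factor positive scalar.
#' @name StrandedCoverage-accessors
NULL

#' @rdname StrandedCoverage-accessors
#' @export
setMethod("strandCoverage", "StrandedCoverage", function(x, strand) {
    switch(strand, "+" = x@plus, "-" = x@minus,
           stop("strand must be '+' or '-'"))
})

#' @rdname StrandedCoverage-accessors
#' @export
setMethod("totalSignal", "StrandedCoverage", function(x) {
    s <- 0
    for (sl in c("plus", "minus")) {
        rl <- slot(x, sl)
        if (length(rl))
            s <- s + sum(vapply(rl, function(r) sum(as.numeric(r)),
                                numeric(1)))
    }
    s
})

#' @rdname StrandedCoverage-accessors
#' @export
setMethod("scaleCoverage", "StrandedCoverage", function(x, factor) {
    stopifnot(is.numeric(factor), length(factor) == 1L, factor >= 0)
    new("StrandedCoverage",
        plus = as(lapply(x@plus, function(r) r * factor), "SimpleRleList"),
        minus = as(lapply(x@minus, function(r) r * factor), "SimpleRleList"))
})

setMethod("show", "StrandedCoverage", function(object) {
    cat("StrandedCoverage\n")
    for (s in c("plus", "minus")) {
        rl <- slot(object, s)
        cat(sprintf("  %s strand: %d chromosome(s), total signal %.6g\n",
                    s, length(rl),
                    sum(vapply(rl, function(r) sum(as.numeric(r)),
                               numeric(1)))))
    }
})

# elementwise sum of two coverage objects (replicate pooling)
.addCoverage <- function(a, b) {
    addRl <- function(x, y) {
        chroms <- union(names(x), names(y))
        out <- lapply(chroms, function(ch) {
            rx <- x[[ch]]
            ry <- y[[ch]]
            if (is.null(rx)) return(ry)
            if (is.null(ry)) return(rx)
            n <- max(length(rx), length(ry))
            pad <- function(r) if (length(r) < n)
                c(r, Rle(0, n - length(r))) else r
            pad(rx) + pad(ry)
        })
        names(out) <- chroms
        as(out, "SimpleRleList")
    }
    new("StrandedCoverage",
        plus = addRl(a@plus, b@plus),
        minus = addRl(a@minus, b@minus))
}

#' Pool coverage across replicates
#'
#' @param covs list of \linkS4class{StrandedCoverage} objects.
#' @return their per-base sum.
#' @export
poolCoverage <- function(covs) {
    stopifnot(length(covs) >= 1L)
    Reduce(.addCoverage, covs)
}
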