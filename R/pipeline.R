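#' Read and validate a pipeline configuration file
#'
#' The configuration is a single YAML file naming the annotation, one or
#' more conditions each with one or more replicates of stranded coverage
#' (either an explicit \code{plus}/\code{minus} file pair or a path prefix
#' to which \code{.plus.bedgraph}/\code{.minus.bedgraph} is appended),
#' optional parameter overrides under \code{params}, an optional
#' \code{compare: [reference, contrast]} pair, a \code{seed} and an
#' \code{output_dir}. Relative paths are resolved against the directory of
#' the configuration file.
#'
#' @param path YAML configuration file.
#' @return validated configuration list with resolved paths.
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path))
        stop("configuration file not found: ", path)
    cfg <- yaml::read_yaml(path)
    base <- dirname(normalizePath(path))
    resolve <- function(p) {
        ifelse(grepl("^/", p), p, file.path(base, p))
    }
    for (key in c("annotation", "conditions"))
        if (is.null(cfg[[key]]))
            stop("configuration is missing required key '", key, "'")
    cfg$annotation <- resolve(cfg$annotation)
    if (!is.null(cfg$chrom_sizes))
        cfg$chrom_sizes <- resolve(cfg$chrom_sizes)
    if (!is.list(cfg$conditions) || is.null(names(cfg$conditions)))
        stop("'conditions' must map condition names to replicate coverage files")
    cfg$conditions <- lapply(cfg$conditions, function(reps) {
        if (!is.list(reps) || is.null(names(reps)))
            stop("each condition must map replicate names to coverage inputs")
        lapply(reps, function(r) {
            if (is.character(r) && length(r) == 1L) {
                r <- list(plus = paste0(r, ".plus.bedgraph"),
                          minus = paste0(r, ".minus.bedgraph"))
            }
            if (is.null(r$plus) || is.null(r$minus))
                stop("replicate coverage must give 'plus' and 'minus' files ",
                     "or a path prefix")
            list(plus = resolve(r$plus), minus = resolve(r$minus))
        })
    })
    if (!is.null(cfg$compare)) {
        if (length(cfg$compare) != 2L ||
            !all(cfg$compare %in% names(cfg$conditions)))
            stop("'compare' must name two configured conditions")
    }
    if (is.null(cfg$output_dir))
        cfg$output_dir <- file.path(base, "readthrough_out")
    else
        cfg$output_dir <- resolve(cfg$output_dir)
    if (is.null(cfg$seed))
        cfg$seed <- 1L
    cfg
}

.configParams <- function(cfg) {
    p <- cfg$params
    get <- function(name, default) if (is.null(p[[name]])) default else p[[name]]
    pipelineConfig(
        windowSize = get("window_size", 250),
        nWindows = get("n_windows", 20),
        tpmThreshold = get("tpm_threshold", 10),
        requireSpliced = get("require_spliced", TRUE),
        clearance = get("clearance", NA),
        terminalFloor = get("terminal_floor", 1),
        aggregation = get("aggregation", "mean_of_ratios"),
        seed = cfg$seed)
}

.log <- function(outDir, ...) {
    msg <- paste0(...)
    message(msg)
    cat(msg, "\n", sep = "", file = file.path(outDir, "run.log"),
        append = TRUE)
}

.writeTsv <- function(x, path) {
    data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
    path
}

#' Quantification stage: transcript filter and per-transcript profiles
#'
#' Reads the annotation and all configured coverage files. For each
#' condition, expression is quantified on the coverage pooled across that
#' condition's replicates and the transcript filter (TPM, splicing,
#' clearance) applied; per-transcript window profiles are then computed per
#' replicate on the condition's retained transcripts. Writes
#' \code{transcripts.tsv} and \code{profiles.tsv} into the output directory.
#'
#' @param cfg configuration list from [readPipelineConfig()] (or a path).
#' @return invisibly, the output directory.
#' @export
runQuantify <- function(cfg) {
    if (is.character(cfg))
        cfg <- readPipelineConfig(cfg)
    outDir <- cfg$output_dir
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    config <- .configParams(cfg)
    .log(outDir, "quantify: reading annotation ", cfg$annotation)
    ann <- readGtf(cfg$annotation, chromSizes = cfg$chrom_sizes)
    if (length(ann) == 0L)
        stop("annotation '", cfg$annotation, "' contains no transcripts")
    txRows <- list()
    profRows <- list()
    for (cname in names(cfg$conditions)) {
        reps <- cfg$conditions[[cname]]
        covs <- lapply(reps, function(r) {
            if (is.character(r) && length(r) == 1L)
                r <- list(plus = paste0(r, ".plus.bedgraph"),
                          minus = paste0(r, ".minus.bedgraph"))
            for (f in c(r$plus, r$minus))
                if (!file.exists(f))
                    stop("coverage file not found: ", f)
            readBedGraphPair(r$plus, r$minus)
        })
        pooled <- poolCoverage(covs)
        tpm <- computeTpm(ann, pooled)
        detail <- computeTpm(ann, pooled, detail = TRUE)
        filt <- filterTranscripts(ann, tpm, config)
        filt$exonic_signal <- detail$exonic_signal[
            match(filt$transcript_id, detail$transcript_id)]
        filt <- filt[, c("transcript_id", "gene_id", "chrom", "strand",
                         "exonic_length", "exonic_signal", "tpm",
                         "retained", "exclusion_reason")]
        filt <- cbind(condition = cname, filt)
        txRows[[cname]] <- filt
        nRet <- sum(filt$retained)
        tally <- table(filt$exclusion_reason[!filt$retained])
        .log(outDir, sprintf(
            "quantify: condition '%s': %d/%d transcripts retained (%s)",
            cname, nRet, nrow(filt),
            if (length(tally)) paste(names(tally), tally, sep = "=",
                                     collapse = ", ") else "none excluded"))
        if (nRet == 0L)
            stop("no transcripts retained for condition '", cname,
                 "'; exclusions: ",
                 paste(names(tally), tally, sep = "=", collapse = ", "))
        keep <- ann[filt$transcript_id[filt$retained]]
        for (rname in names(reps)) {
            ps <- transcriptProfiles(keep, covs[[rname]], config,
                                     condition = cname, replicate = rname)
            profRows[[paste(cname, rname)]] <- .profilesToTable(ps)
        }
    }
    .writeTsv(data.table::rbindlist(txRows), file.path(outDir, "transcripts.tsv"))
    .writeTsv(data.table::rbindlist(profRows), file.path(outDir, "profiles.tsv"))
    invisible(outDir)
}

.profilesToTable <- function(ps) {
    K <- ps@nWindows
    raw <- as.data.frame(ps@windowSignals)
    names(raw) <- sprintf("window_%d", seq_len(K))
    nrm <- as.data.frame(ps@normalized)
    names(nrm) <- sprintf("norm_%d", seq_len(K))
    cbind(data.frame(condition = ps@condition, replicate = ps@replicate,
                     transcript_id = ps@transcriptId,
                     terminal_signal = ps@terminalSignal,
                     stringsAsFactors = FALSE),
          raw, nrm,
          data.frame(valid = ps@valid, reason = ps@reason,
                     terminal_exon_short = ps@terminalExonShort,
                     window_size = ps@windowSize,
                     stringsAsFactors = FALSE))
}

.profilesFromTable <- function(dt, config) {
    dt <- as.data.frame(dt)
    K <- sum(grepl("^window_[0-9]+$", names(dt)))
    split(dt, list(dt$condition, dt$replicate), drop = TRUE, sep = "\r") |>
        lapply(function(d) {
            new("TranscriptProfileSet",
                transcriptId = d$transcript_id,
                terminalSignal = d$terminal_signal,
                windowSignals = as.matrix(
                    d[sprintf("window_%d", seq_len(K))]),
                normalized = as.matrix(d[sprintf("norm_%d", seq_len(K))]),
                valid = d$valid,
                reason = ifelse(is.na(d$reason), "", d$reason),
                terminalExonShort = d$terminal_exon_short,
                condition = d$condition[1L],
                replicate = d$replicate[1L],
                windowSize = as.integer(d$window_size[1L]),
                nWindows = as.integer(K),
                terminalFloor = config@terminalFloor)
        })
}

#' Meta-gene stage: aggregate profiles per condition and replicate
#'
#' Reads \code{profiles.tsv} from the output directory and writes
#' \code{metagene.tsv}: one meta-gene per condition x replicate plus a
#' \code{combined} row set per condition aggregating all its replicate
#' profiles together.
#'
#' @param cfg configuration list from [readPipelineConfig()] (or a path).
#' @return invisibly, the output directory.
#' @export
runMetagene <- function(cfg) {
    if (is.character(cfg))
        cfg <- readPipelineConfig(cfg)
    outDir <- cfg$output_dir
    config <- .configParams(cfg)
    pf <- file.path(outDir, "profiles.tsv")
    if (!file.exists(pf))
        stop("profiles.tsv not found in '", outDir, "'; run the quantify ",
             "stage first")
    sets <- .profilesFromTable(data.table::fread(pf, sep = "\t"), config)
    rows <- list()
    conds <- unique(vapply(sets, slot, character(1), "condition"))
    for (cname in conds) {
        inCond <- Filter(function(s) s@condition == cname, sets)
        for (s in inCond) {
            mg <- metageneProfile(s, config)
            rows[[paste(cname, s@replicate)]] <-
                cbind(condition = cname, replicate = s@replicate,
                      metageneStats(mg), mode = mg@mode)
        }
        mgAll <- metageneProfile(inCond, config)
        rows[[paste(cname, "combined")]] <-
            cbind(condition = cname, replicate = "combined",
                  metageneStats(mgAll), mode = mgAll@mode)
    }
    .writeTsv(data.table::rbindlist(rows), file.path(outDir, "metagene.tsv"))
    .log(outDir, sprintf("metagene: wrote profiles for %d condition(s)",
                         length(conds)))
    invisible(outDir)
}

#' Comparison stage: bootstrap contrast between two conditions
#'
#' Reads \code{profiles.tsv} and, using the \code{compare} pair from the
#' configuration, writes \code{comparison.tsv} with the per-window
#' difference of mean terminal-normalized signal (contrast minus reference)
#' and its bootstrap confidence interval.
#'
#' @param cfg configuration list from [readPipelineConfig()] (or a path).
#' @param nBoot bootstrap resamples.
#' @return invisibly, the output directory.
#' @export
runCompare <- function(cfg, nBoot = 1000L) {
    if (is.character(cfg))
        cfg <- readPipelineConfig(cfg)
    outDir <- cfg$output_dir
    config <- .configParams(cfg)
    if (is.null(cfg$compare)) {
        .log(outDir, "compare: no 'compare' pair configured; skipping")
        return(invisible(outDir))
    }
    pf <- file.path(outDir, "profiles.tsv")
    if (!file.exists(pf))
        stop("profiles.tsv not found in '", outDir, "'; run the quantify ",
             "stage first")
    sets <- .profilesFromTable(data.table::fread(pf, sep = "\t"), config)
    pick <- function(cname) Filter(function(s) s@condition == cname, sets)
    cmp <- compareConditions(pick(cfg$compare[[1L]]),
                             pick(cfg$compare[[2L]]),
                             config, nBoot = nBoot)
    .writeTsv(cmp, file.path(outDir, "comparison.tsv"))
    .log(outDir, sprintf("compare: %s vs %s, %d window(s)",
                         cfg$compare[[2L]], cfg$compare[[1L]], nrow(cmp)))
    invisible(outDir)
}

#' Run the complete read-through pipeline
#'
#' Executes quantify, metagene and compare in sequence (each stage reads its
#' predecessor's TSV output, so running the stages individually produces
#' identical files) and writes a run manifest. Outputs are deterministic
#' given the configuration and seed: reruns yield byte-identical TSVs.
#'
#' @param cfg path to a YAML configuration file, or the list from
#'   [readPipelineConfig()].
#' @param outputDir optional override of the configured output directory.
#' @return invisibly, the output directory.
#' @export
runPipeline <- function(cfg, outputDir = NULL) {
    if (is.character(cfg))
        cfg <- readPipelineConfig(cfg)
    if (!is.null(outputDir))
        cfg$output_dir <- outputDir
    outDir <- cfg$output_dir
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    runQuantify(cfg)
    runMetagene(cfg)
    runCompare(cfg)
    .writeManifest(cfg)
    .log(outDir, "pipeline complete: ", outDir)
    invisible(outDir)
}

.writeManifest <- function(cfg) {
    outDir <- cfg$output_dir
    covFiles <- unlist(cfg$conditions)
    inputs <- c(annotation = cfg$annotation, covFiles)
    sums <- tools::md5sum(inputs)
    tx <- data.table::fread(file.path(outDir, "transcripts.tsv"), sep = "\t")
    lines <- c(
        paste0("tool_version: txReadthrough ",
               as.character(packageVersion("txReadthrough"))),
        paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
        paste0("seed: ", cfg$seed),
        paste0("output_dir: ", outDir),
        paste0("conditions: ", paste(names(cfg$conditions), collapse = ", ")),
        if (!is.null(cfg$compare))
            paste0("compare: ", paste(cfg$compare, collapse = " vs ")),
        paste0("input_md5: ", names(sums), " ", unname(sums)))
    for (cname in unique(tx$condition)) {
        d <- tx[tx$condition == cname, ]
        tally <- table(d$exclusion_reason[!d$retained])
        lines <- c(lines, sprintf(
            "transcripts[%s]: total=%d retained=%d%s", cname, nrow(d),
            sum(d$retained),
            if (length(tally)) paste0(" excluded{",
                paste(names(tally), tally, sep = "=", collapse = ", "), "}")
            else ""))
    }
    writeLines(lines, file.path(outDir, "manifest.txt"))
    invisible(file.path(outDir, "manifest.txt"))
}
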