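#' Read aligned small-RNA reads from a BED file
#'
#' Parses a BED3/BED6 file of aligned small-RNA read intervals, optionally
#' carrying the read sequence in a seventh column (needed for low-complexity
#' filtering). BED coordinates are 0-based half-open on disk; in memory all
#' intervals follow the GRanges convention (1-based, closed), and this reader
#' is one of the two places where the conversion happens (the other being
#' \code{\link{readAnnotations}}).
#'
#' @param path path to a tab-separated BED file.
#' @param sampleId sample identifier attached to every read.
#' @return a \code{data.table} of reads with columns \code{sample_id},
#'   \code{chrom}, \code{start}, \code{end} (1-based closed), \code{strand},
#'   \code{sequence} (\code{NA} when absent) and \code{weight}.
#' @export
readBedReads <- function(path, sampleId) {
    if (!file.exists(path)) .stopf("file not found: %s", path)
    if (file.size(path) == 0L) return(.emptyReads())
    dt <- tryCatch(
        data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1L)),
        error = function(e) .stopf("cannot parse '%s': %s",
                                   path, conditionMessage(e)))
    if (nrow(dt) == 0L) return(.emptyReads())
    if (ncol(dt) < 3L)
        .stopf("'%s': BED requires at least 3 tab-separated fields", path)
    start0 <- suppressWarnings(as.integer(dt[[2L]]))
    end0 <- suppressWarnings(as.integer(dt[[3L]]))
    bad <- which(is.na(start0) | is.na(end0))
    if (length(bad))
        .stopf("'%s': non-integer coordinates on line(s) %s", path,
               paste(head(bad, 5L), collapse = ", "))
    inv <- which(start0 >= end0)
    if (length(inv))
        .stopf("'%s': start >= end on line(s) %s", path,
               paste(head(inv, 5L), collapse = ", "))
    strand <- if (ncol(dt) >= 6L) as.character(dt[[6L]]) else "*"
    strand[!strand %in% c("+", "-")] <- "*"
    sequence <- if (ncol(dt) >= 7L) as.character(dt[[7L]]) else NA_character_
    hasSeq <- which(!is.na(sequence) & nzchar(sequence))
    if (length(hasSeq)) {
        lens <- nchar(sequence[hasSeq])
        mism <- hasSeq[lens != (end0[hasSeq] - start0[hasSeq])]
        if (length(mism))
            .stopf("'%s': sequence length != interval length on line(s) %s",
                   path, paste(head(mism, 5L), collapse = ", "))
    }
    out <- data.table::data.table(
        sample_id = sampleId, chrom = as.character(dt[[1L]]),
        start = start0 + 1L, end = end0, strand = strand,
        sequence = sequence, weight = 1L)
    out[]
}

.emptyReads <- function() {
    data.table::data.table(
        sample_id = character(0), chrom = character(0),
        start = integer(0), end = integer(0), strand = character(0),
        sequence = character(0), weight = integer(0))
}

#' Write reads to a BED6+1 file (sequence in column 7)
#'
#' @param reads a read table as returned by \code{\link{readBedReads}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeBedReads <- function(reads, path) {
    reads <- data.table::as.data.table(reads)
    out <- data.table::data.table(
        chrom = reads$chrom, start = reads$start - 1L, end = reads$end,
        name = if (nrow(reads)) paste0("read_", seq_len(nrow(reads)))
               else character(0),
        score = reads$weight, strand = reads$strand,
        sequence = ifelse(is.na(reads$sequence), ".", reads$sequence))
    data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
    invisible(path)
}

.ROLES <- c("tumor", "normal", "biofluid", "serum", "cfrna")

#' Read a sample manifest
#'
#' Tab-separated table with a header; required columns are \code{sample_id},
#' \code{role} and \code{tissue}. Optional columns (\code{subtype},
#' \code{timepoint}, \code{library_size}, \code{survival_time}, \code{event},
#' \code{patient_id}) become \code{NA} when empty, never zero.
#'
#' @param path path to the TSV manifest.
#' @return a \code{data.frame}, one row per sample.
#' @export
readSampleManifest <- function(path) {
    if (!file.exists(path)) .stopf("file not found: %s", path)
    dt <- data.table::fread(path, header = TRUE, sep = "\t",
                            na.strings = c("", "NA"))
    need <- c("sample_id", "role", "tissue")
    miss <- setdiff(need, colnames(dt))
    if (length(miss))
        .stopf("manifest lacks required column(s): %s",
               paste(miss, collapse = ", "))
    dup <- unique(dt$sample_id[duplicated(dt$sample_id)])
    if (length(dup))
        .stopf("duplicate sample_id in manifest: %s",
               paste(dup, collapse = ", "))
    badRole <- setdiff(unique(dt$role), .ROLES)
    if (length(badRole))
        .stopf("unknown role token(s): %s", paste(badRole, collapse = ", "))
    if (!is.null(dt$timepoint)) {
        badTp <- setdiff(unique(stats::na.omit(dt$timepoint)), c("T0", "T3"))
        if (length(badTp))
            .stopf("unknown timepoint token(s): %s",
                   paste(badTp, collapse = ", "))
    }
    if (!is.null(dt$library_size) &&
        any(!is.na(dt$library_size) & dt$library_size <= 0))
        .stopf("library_size must be positive where present")
    as.data.frame(dt)
}

#' Write a sample manifest
#' @param manifest a manifest data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSampleManifest <- function(manifest, path) {
    data.table::fwrite(data.table::as.data.table(manifest), path, sep = "\t",
                       na = "NA")
    invisible(path)
}

#' Read known small-RNA annotations (BED or GFF3)
#'
#' Dispatches on file extension: \code{.bed} is read as 0-based half-open and
#' converted, \code{.gff}/\code{.gff3}/\code{.gtf} as 1-based closed. Parsing
#' is delegated to \code{rtracklayer}. Output is sorted by (chrom, start)
#' ignoring strand.
#'
#' @param path annotation file path.
#' @return a sorted \code{GRanges} of annotation loci.
#' @export
readAnnotations <- function(path) {
    if (!file.exists(path)) .stopf("file not found: %s", path)
    ext <- tolower(tools::file_ext(path))
    gr <- switch(ext,
        bed = rtracklayer::import(path, format = "BED"),
        gff = ,
        gff3 = ,
        gtf = rtracklayer::import(path, format = ext),
        .stopf("unrecognized annotation format '.%s' (expect BED or GFF3)",
               ext))
    gr <- GenomeInfoDb::sortSeqlevels(gr)
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    if (is.null(names(gr)) || anyNA(names(gr)))
        names(gr) <- paste0("ann_", seq_along(gr))
    gr
}

## ------------------------------------------------------------------------
## Catalog serialization: BED-compatible TSV with provenance flags and
## per-tissue Fisher columns; round-trips through readCatalog().

#' Write an oncRNA catalog to a BED-compatible TSV
#'
#' One row per candidate locus (0-based half-open coordinates in the first
#' three columns, so the file doubles as a BED), cumulative stage flags, and
#' the per-tissue Fisher 2x2 tables with odds ratios, p- and q-values spread
#' into supplementary columns. Stage survivor counts and cascade parameters
#' are stored in commented header lines. \code{readCatalog()} reconstructs
#' the catalog losslessly.
#'
#' @param catalog an \code{\linkS4class{OncRNACatalog}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCatalog <- function(catalog, path) {
    stopifnot(is(catalog, "OncRNACatalog"))
    loci <- catalog@loci
    fl <- as.data.frame(catalog@stageFlags)
    enr <- as.data.frame(catalog@enrichment)
    base <- data.table::data.table(
        chrom = as.character(GenomicRanges::seqnames(loci)),
        start = GenomicRanges::start(loci) - 1L,
        end = GenomicRanges::end(loci),
        locus_id = names(loci),
        score = 0L,
        strand = as.character(GenomicRanges::strand(loci)))
    base$strand[base$strand == "*"] <- "."
    for (cn in colnames(fl)) base[[cn]] <- fl[[cn]]
    if (nrow(enr)) {
        for (ti in sort(unique(enr$tissue))) {
            sub <- enr[enr$tissue == ti, , drop = FALSE]
            idx <- match(base$locus_id, sub$locus_id)
            for (col in c("a", "b", "c", "d", "odds_ratio",
                          "p_value", "q_value"))
                base[[paste0(col, ".", ti)]] <- sub[[col]][idx]
        }
    }
    scalar <- vapply(catalog@params, function(p)
        is.atomic(p) && length(p) == 1L, logical(1L))
    writeLines(c(
        sprintf("# stage_counts: %s",
                paste(names(catalog@stageCounts), catalog@stageCounts,
                      sep = "=", collapse = ";")),
        sprintf("# param: %s=%s", names(catalog@params)[scalar],
                vapply(catalog@params[scalar], as.character,
                       character(1L)))),
        path)
    suppressWarnings(
        data.table::fwrite(base, path, sep = "\t", append = TRUE,
                           col.names = TRUE))
    invisible(path)
}

#' @rdname writeCatalog
#' @export
readCatalog <- function(path) {
    if (!file.exists(path)) .stopf("file not found: %s", path)
    hdr <- readLines(path, n = 30L)
    scLine <- grep("^# stage_counts:", hdr, value = TRUE)
    pLines <- grep("^# param: ", hdr, value = TRUE)
    dt <- data.table::fread(path, header = TRUE, sep = "\t", skip = "chrom")
    loci <- GenomicRanges::GRanges(
        dt$chrom,
        IRanges::IRanges(dt$start + 1L, dt$end),
        strand = ifelse(dt$strand == ".", "*", dt$strand))
    names(loci) <- dt$locus_id
    flagCols <- paste0("passed_", .STAGES)
    fl <- S4Vectors::DataFrame(as.data.frame(dt)[, flagCols, drop = FALSE])
    tisCols <- grep("^q_value\\.", colnames(dt), value = TRUE)
    tissues <- sub("^q_value\\.", "", tisCols)
    enr <- do.call(rbind, lapply(tissues, function(ti) {
        keep <- !is.na(dt[[paste0("p_value.", ti)]])
        if (!any(keep)) return(NULL)
        data.frame(
            locus_id = dt$locus_id[keep], tissue = ti,
            a = dt[[paste0("a.", ti)]][keep],
            b = dt[[paste0("b.", ti)]][keep],
            c = dt[[paste0("c.", ti)]][keep],
            d = dt[[paste0("d.", ti)]][keep],
            odds_ratio = dt[[paste0("odds_ratio.", ti)]][keep],
            p_value = dt[[paste0("p_value.", ti)]][keep],
            q_value = dt[[paste0("q_value.", ti)]][keep],
            stringsAsFactors = FALSE)
    }))
    if (is.null(enr))
        enr <- S4Vectors::DataFrame(locus_id = character(0),
                                    tissue = character(0))
    else {
        enr <- enr[order(enr$tissue, match(enr$locus_id, names(loci))), ]
        rownames(enr) <- NULL
        enr <- S4Vectors::DataFrame(enr)
    }
    sc <- integer(0)
    if (length(scLine)) {
        parts <- strsplit(sub("^# stage_counts: *", "", scLine[1L]), ";")[[1L]]
        kv <- strsplit(parts, "=")
        sc <- setNames(as.integer(vapply(kv, `[`, "", 2L)),
                       vapply(kv, `[`, "", 1L))
    }
    params <- list()
    for (ln in pLines) {
        kv <- strsplit(sub("^# param: ", "", ln), "=", fixed = TRUE)[[1L]]
        params[[kv[1L]]] <- utils::type.convert(kv[2L], as.is = TRUE)
    }
    new("OncRNACatalog", loci = loci, stageFlags = fl, enrichment = enr,
        stageCounts = sc, params = params)
}

#' Read a pipeline configuration file (YAML)
#'
#' Unknown keys are rejected to catch typos; missing keys take the defaults
#' of \code{pipelineDefaults()}.
#'
#' @param path YAML file path, or \code{NULL} for pure defaults.
#' @return a named list of cascade/discovery parameters.
#' @export
readPipelineConfig <- function(path = NULL) {
    defaults <- pipelineDefaults()
    if (is.null(path)) return(defaults)
    if (!file.exists(path)) .stopf("file not found: %s", path)
    cfg <- yaml::read_yaml(path)
    unknown <- setdiff(names(cfg), names(defaults))
    if (length(unknown))
        .stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
    utils::modifyList(defaults, cfg)
}

#' @rdname readPipelineConfig
#' @export
pipelineDefaults <- function() {
    list(
        dustThreshold = 3,
        peakHeight = 10,
        peakWidthMin = 15,
        peakWidthMax = 200,
        peakDistance = 20,
        keepUnsplitLongLoci = FALSE,
        strandAware = FALSE,
        biofluidThreshold = 0.0043,
        minNormals = 10L,
        maxNormalFrac = 0.10,
        minTumorFrac = 0.10,
        fdr = 0.1,
        serumMaxSamples = 1L)
}
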