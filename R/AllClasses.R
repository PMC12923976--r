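#' PresenceMatrix: locus-by-sample detection of small-RNA loci
#'
#' A \code{PresenceMatrix} extends
#' \linkS4class{RangedSummarizedExperiment} with two assays over the same
#' locus-by-sample grid: \code{"counts"} (total read weight of a sample
#' overlapping a locus) and \code{"presence"} (1 exactly when the count is
#' at least 1 -- a locus is considered present in a sample as soon as a
#' single read overlaps it). Loci live in \code{rowRanges}; the sample
#' manifest (role, tissue, subtype, timepoint, library size, survival) lives
#' in \code{colData}. Library sizes are the total retained reads per sample
#' and drive all counts-per-million scaling.
#'
#' @param counts integer matrix, loci in rows, samples in columns.
#' @param loci a \code{GRanges} of the loci, one per row of \code{counts};
#'   locus identifiers are taken from its names.
#' @param sampleData a \code{DataFrame}/\code{data.frame} of per-sample
#'   metadata, one row per column of \code{counts}, with at least a
#'   \code{library_size} column of positive integers.
#' @param x a \code{PresenceMatrix}.
#' @param ... unused.
#'
#' @return \code{PresenceMatrix()} returns a validated object.
#'   \code{presence(x)} returns the binary detection matrix;
#'   \code{librarySizes(x)} the named per-sample library sizes;
#'   \code{counts(x)} the raw count matrix.
#'
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 50), width = 20))
#' names(gr) <- c("locus_1", "locus_2")
#' cnt <- matrix(c(0L, 3L, 1L, 0L), nrow = 2,
#'               dimnames = list(names(gr), c("s1", "s2")))
#' pm <- PresenceMatrix(cnt, gr, S4Vectors::DataFrame(
#'     sample_id = c("s1", "s2"), role = "tumor", tissue = "breast",
#'     library_size = c(1e6L, 2e6L), row.names = c("s1", "s2")))
#' presence(pm)
#'
#' @aliases presence librarySizes
#' @import SummarizedExperiment
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @export
setClass("PresenceMatrix", contains = "RangedSummarizedExperiment")

#' @rdname PresenceMatrix-class
#' @export
PresenceMatrix <- function(counts, loci, sampleData) {
    if (!is.matrix(counts))
        .stopf("'counts' must be a matrix")
    if (!is(loci, "GRanges") || length(loci) != nrow(counts))
        .stopf("'loci' must be a GRanges with one range per row of 'counts'")
    if (is.null(names(loci)))
        names(loci) <- paste0("locus_", seq_along(loci))
    sampleData <- as(sampleData, "DataFrame")
    if (nrow(sampleData) != ncol(counts))
        .stopf("'sampleData' must have one row per column of 'counts'")
    if (is.null(sampleData$library_size))
        .stopf("'sampleData' must carry a 'library_size' column")
    storage.mode(counts) <- "integer"
    rownames(counts) <- names(loci)
    if (is.null(colnames(counts)))
        colnames(counts) <- if (!is.null(sampleData$sample_id))
            as.character(sampleData$sample_id) else rownames(sampleData)
    rownames(sampleData) <- colnames(counts)
    pres <- matrix(as.integer(counts >= 1L), nrow = nrow(counts),
                   dimnames = dimnames(counts))
    se <- SummarizedExperiment(
        assays = list(counts = counts, presence = pres),
        rowRanges = loci, colData = sampleData)
    new("PresenceMatrix", se)
}

setValidity("PresenceMatrix", function(object) {
    msg <- character(0)
    an <- assayNames(object)
    if (!all(c("counts", "presence") %in% an))
        return("assays 'counts' and 'presence' are required")
    cnt <- assay(object, "counts")
    prs <- assay(object, "presence")
    if (any(cnt < 0))
        msg <- c(msg, "counts must be nonnegative")
    if (!identical(dim(cnt), dim(prs)))
        msg <- c(msg, "'counts' and 'presence' dimensions differ")
    else if (!all((cnt >= 1L) == (prs == 1L)))
        msg <- c(msg, "presence[i,j] must be 1 exactly when counts[i,j] >= 1")
    ls <- colData(object)$library_size
    if (is.null(ls) || any(is.na(ls)) || any(ls <= 0))
        msg <- c(msg, "colData must carry positive 'library_size'")
    if (length(msg)) msg else TRUE
})

#' @rdname PresenceMatrix-class
#' @export
setMethod("presence", "PresenceMatrix", function(x, ...)
    assay(x, "presence"))

#' @rdname PresenceMatrix-class
#' @export
setMethod("librarySizes", "PresenceMatrix", function(x, ...)
    setNames(as.numeric(colData(x)$library_size), colnames(x)))

#' @rdname PresenceMatrix-class
#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "PresenceMatrix", function(object)
    assay(object, "counts"))

setMethod("show", "PresenceMatrix", function(object) {
    callNextMethod()
    det <- mean(assay(object, "presence"))
    cat(sprintf("overall detection rate: %.3f\n", det))
})

## ------------------------------------------------------------------------

#' OncRNACatalog: loci surviving the cancer-emergence cascade
#'
#' The result of \code{\link{runCascade}}: every candidate locus that entered
#' the cascade, cumulative per-stage survival flags (a flag is \code{TRUE}
#' when the locus survived that stage and all earlier ones, so survivor sets
#' are nested by construction), per-tissue Fisher enrichment results and the
#' per-stage survivor counts. The final oncRNA set is the subset whose last
#' flag is \code{TRUE}; it is returned by \code{finalLoci()}.
#'
#' @slot loci \code{GRanges} of all candidate loci that entered the cascade.
#' @slot stageFlags \code{DataFrame} of cumulative logical flags with columns
#'   \code{passed_biofluid}, \code{passed_normal}, \code{passed_prevalence},
#'   \code{passed_fisher}, \code{passed_annotation}, \code{passed_serum}.
#' @slot enrichment \code{DataFrame} of per-locus, per-tissue Fisher results
#'   (\code{locus_id}, \code{tissue}, the 2x2 table \code{a,b,c,d},
#'   \code{odds_ratio}, \code{p_value}, \code{q_value}).
#' @slot stageCounts named integer vector of survivor counts after each stage
#'   (first element is the input size).
#' @slot params list of the thresholds the cascade ran with.
#'
#' @param x an \code{OncRNACatalog}.
#' @param ... unused.
#'
#' @aliases stageFlags stageCounts enrichment finalLoci catalogParams
#' @export
setClass("OncRNACatalog",
    representation(loci = "GRanges", stageFlags = "DataFrame",
                   enrichment = "DataFrame", stageCounts = "integer",
                   params = "list"))

.STAGES <- c("biofluid", "normal", "prevalence", "fisher",
             "annotation", "serum")

setValidity("OncRNACatalog", function(object) {
    msg <- character(0)
    fl <- object@stageFlags
    if (nrow(fl) != length(object@loci))
        msg <- c(msg, "one flag row per locus required")
    want <- paste0("passed_", .STAGES)
    if (!all(want %in% colnames(fl)))
        msg <- c(msg, "stage flag columns incomplete")
    else {
        m <- as.matrix(as.data.frame(fl)[, want])
        if (nrow(m) && !all(apply(m, 1L, function(r) all(diff(r) <= 0))))
            msg <- c(msg, "stage flags must be cumulative (nested survivors)")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname OncRNACatalog-class
#' @export
setMethod("stageFlags", "OncRNACatalog", function(x, ...) x@stageFlags)

#' @rdname OncRNACatalog-class
#' @export
setMethod("stageCounts", "OncRNACatalog", function(x, ...) x@stageCounts)

#' @rdname OncRNACatalog-class
#' @export
setMethod("enrichment", "OncRNACatalog", function(x, ...) x@enrichment)

#' @rdname OncRNACatalog-class
#' @export
setMethod("catalogParams", "OncRNACatalog", function(x, ...) x@params)

#' @rdname OncRNACatalog-class
#' @export
setMethod("finalLoci", "OncRNACatalog", function(x, ...) {
    x@loci[x@stageFlags$passed_serum]
})

#' @rdname OncRNACatalog-class
#' @export
setMethod("length", "OncRNACatalog", function(x) sum(x@stageFlags$passed_serum))

setMethod("show", "OncRNACatalog", function(object) {
    cat(sprintf("OncRNACatalog: %d / %d loci retained\n",
                length(object), length(object@loci)))
    sc <- object@stageCounts
    cat("survivors per stage:\n")
    for (nm in names(sc)) cat(sprintf("  %-12s %d\n", nm, sc[[nm]]))
})
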