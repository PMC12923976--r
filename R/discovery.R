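#' DUST low-complexity score of nucleotide sequences
#'
#' The DUST statistic quantifies sequence repetitiveness from overlapping
#' triplets. For a sequence of length L with k = L - 2 overlapping triplets
#' and c_t occurrences of each distinct triplet t, the score is
#' sum_t c_t (c_t - 1) / 2, normalized by (k - 1). All-distinct triplets give
#' 0; a homopolymer of length L gives (L - 2) / 2, the maximum. Higher means
#' lower complexity. Triplets containing N are excluded from the counts; the
#' normalizer stays k - 1.
#'
#' @param sequences character vector of nucleotide sequences over
#'   \{A, C, G, T, N\} (case-insensitive), each of length >= 3.
#' @return numeric vector of scores, one per sequence.
#' @examples
#' dustScore(strrep("A", 30))           # (30-2)/2 = 14
#' dustScore(strrep("ACGT", 8))         # periodic, high
#' @export
dustScore <- function(sequences) {
    if (!is.character(sequences) || anyNA(sequences))
        .stopf("'sequences' must be a character vector without NA")
    L <- nchar(sequences)
    if (any(L < 3L))
        .stopf("all sequences must have length >= 3")
    sequences <- toupper(sequences)
    n <- length(sequences)
    if (n == 0L) return(numeric(0))
    k <- L - 2L
    id <- rep.int(seq_len(n), k)
    starts <- sequence(k)
    trips <- substring(rep.int(sequences, k), starts, starts + 2L)
    dt <- data.table::data.table(id = id, trip = trips)
    dt <- dt[!grepl("N", trip, fixed = TRUE)]
    cc <- dt[, .N, by = c("id", "trip")]
    ss <- cc[, list(S = sum(N * (N - 1) / 2)), by = "id"]
    out <- numeric(n)
    out[ss$id] <- ss$S
    out / (k - 1L)
}

#' Remove low-complexity reads by DUST score
#'
#' Reads whose DUST score exceeds \code{threshold} (default 3, the removal
#' regime used throughout the pipeline) are dropped; order is preserved and
#' per-sample removal counts are logged (see
#' \code{options(orphanRNA.verbose=)}).
#'
#' @param reads read table (see \code{\link{readBedReads}}); every read must
#'   carry a sequence.
#' @param threshold nonnegative removal threshold; reads with score strictly
#'   greater are removed. \code{Inf} disables filtering.
#' @return the filtered read table, with the number of removed reads in
#'   attribute \code{"removed"}.
#' @export
filterLowComplexity <- function(reads, threshold = 3) {
    reads <- data.table::as.data.table(reads)
    if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
        .stopf("'threshold' must be a single nonnegative number")
    if (nrow(reads) == 0L) {
        out <- reads
        data.table::setattr(out, "removed", 0L)
        return(out)
    }
    if (is.null(reads$sequence) || anyNA(reads$sequence))
        .stopf("low-complexity filtering requires a sequence on every read")
    if (is.infinite(threshold)) {
        out <- reads
        data.table::setattr(out, "removed", 0L)
        return(out)
    }
    ## chunked so the exploded triplet table stays small
    nr <- nrow(reads)
    chunk <- 200000L
    keep <- logical(nr)
    for (lo in seq(1L, nr, by = chunk)) {
        hi <- min(lo + chunk - 1L, nr)
        keep[lo:hi] <- dustScore(reads$sequence[lo:hi]) <= threshold
    }
    removedBySample <- reads[!keep, .N, by = "sample_id"]
    for (i in seq_len(nrow(removedBySample)))
        .logmsg("DUST filter: sample %s, %d read(s) removed",
                removedBySample$sample_id[i], removedBySample$N[i])
    out <- reads[keep]
    data.table::setattr(out, "removed", sum(!keep))
    out
}

.readsToGRanges <- function(reads, strandAware = FALSE) {
    GenomicRanges::GRanges(
        reads$chrom,
        IRanges::IRanges(reads$start, reads$end),
        strand = if (strandAware) reads$strand else "*")
}

#' Merge pooled read intervals into small-RNA loci
#'
#' Maximal sets of transitively overlapping or book-ended read intervals per
#' chromosome are collapsed into single loci (the interval-merge convention
#' with gap 0). Strand is ignored by default. Output loci are sorted and
#' pairwise disjoint; merging is idempotent.
#'
#' @param reads pooled read table from all discovery samples.
#' @param strandAware merge within strands separately (default FALSE).
#' @return a sorted, named \code{GRanges} of loci.
#' @export
mergeLoci <- function(reads, strandAware = FALSE) {
    reads <- data.table::as.data.table(reads)
    gr <- GenomeInfoDb::sortSeqlevels(.readsToGRanges(reads, strandAware))
    merged <- GenomicRanges::reduce(GenomicRanges::sort(gr),
                                    ignore.strand = !strandAware)
    merged <- GenomicRanges::sort(merged, ignore.strand = TRUE)
    names(merged) <- paste0("locus_", seq_along(merged))
    merged
}

#' Aggregate per-base read coverage over one locus
#'
#' Pooled per-base depth across the discovery cohort; reads are clipped to
#' the locus bounds and contribute their weight to every base they cover.
#'
#' @param locus a length-1 \code{GRanges}.
#' @param reads read table; reads not overlapping the locus are ignored.
#' @return a list with elements \code{locus} and \code{depth} (integer
#'   vector of length \code{width(locus)}), of class \code{CoverageProfile}.
#' @export
aggregateCoverage <- function(locus, reads) {
    stopifnot(is(locus, "GRanges"), length(locus) == 1L)
    reads <- data.table::as.data.table(reads)
    w <- GenomicRanges::width(locus)
    depth <- integer(w)
    if (nrow(reads)) {
        sel <- reads$chrom == as.character(GenomicRanges::seqnames(locus)) &
            reads$start <= GenomicRanges::end(locus) &
            reads$end >= GenomicRanges::start(locus)
        sub <- reads[sel]
        if (nrow(sub)) {
            s <- pmax(sub$start, GenomicRanges::start(locus)) -
                GenomicRanges::start(locus) + 1L
            e <- pmin(sub$end, GenomicRanges::end(locus)) -
                GenomicRanges::start(locus) + 1L
            cov <- IRanges::coverage(IRanges::IRanges(s, e),
                                     weight = as.numeric(sub$weight),
                                     width = w)
            depth <- as.integer(cov)
        }
    }
    structure(list(locus = locus, depth = depth), class = "CoverageProfile")
}

## ------------------------------------------------------------------------
## 1-D peak detection on a coverage profile. Semantics follow the common
## signal-processing peak caller: plateau-aware local maxima, a minimum
## height, greedy distance pruning from the highest peak down (ties ->
## leftmost), prominence by the lowest saddle toward the nearest higher
## point on each side, and peak width measured where the profile crosses
## height - 0.5 * prominence, with the crossings rounded outward.

#' Detect peaks in a 1-D coverage profile
#'
#' @param depth integer/numeric vector of per-base depth, or a
#'   \code{CoverageProfile}.
#' @param height minimum depth at the peak (default 10).
#' @param widthRange allowed peak width at half prominence, in bases
#'   (default \code{c(15, 200)}).
#' @param distance minimum separation between retained peaks, in bases
#'   (default 20); among closer peaks only the highest survives.
#' @return a \code{data.frame} with one row per peak: \code{position} (1-based
#'   index), \code{left}, \code{right} (outward-rounded half-prominence
#'   bounds), \code{height}, \code{prominence}, \code{width}.
#' @export
findCoveragePeaks <- function(depth, height = 10, widthRange = c(15, 200),
                              distance = 20) {
    if (inherits(depth, "CoverageProfile")) depth <- depth$depth
    if (length(widthRange) != 2L || widthRange[1L] > widthRange[2L])
        .stopf("'widthRange' must be an ordered pair")
    x <- as.numeric(depth)
    n <- length(x)
    empty <- data.frame(position = integer(0), left = integer(0),
                        right = integer(0), height = numeric(0),
                        prominence = numeric(0), width = numeric(0))
    if (n < 3L) return(empty)

    ## plateau-aware local maxima (position = left edge of the plateau,
    ## keeping ties deterministic and leftmost)
    r <- rle(x)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    nr <- length(r$values)
    isMax <- vapply(seq_len(nr), function(i) {
        lv <- if (i > 1L) r$values[i - 1L] else -Inf
        rv <- if (i < nr) r$values[i + 1L] else -Inf
        r$values[i] > lv && r$values[i] > rv
    }, logical(1L))
    pos <- starts[isMax]
    hts <- r$values[isMax]
    keepH <- hts >= height
    pos <- pos[keepH]; hts <- hts[keepH]
    if (!length(pos)) return(empty)

    ## distance pruning: highest first, ties leftmost
    ord <- order(-hts, pos)
    keep <- logical(length(pos))
    taken <- integer(0)
    for (i in ord) {
        if (!length(taken) || all(abs(pos[i] - pos[taken]) >= distance)) {
            keep[i] <- TRUE
            taken <- c(taken, i)
        }
    }
    pos <- pos[keep]; hts <- hts[keep]
    o <- order(pos); pos <- pos[o]; hts <- hts[o]

    ## prominence and half-prominence width per peak
    res <- lapply(seq_along(pos), function(i) {
        p <- pos[i]; h <- hts[i]
        ## walk left until a strictly higher point or the edge
        li <- p
        minL <- h
        j <- p - 1L
        while (j >= 1L && x[j] <= h) { minL <- min(minL, x[j]); j <- j - 1L }
        ## walk right likewise
        minR <- h
        j <- p + 1L
        while (j <= n && x[j] <= h) { minR <- min(minR, x[j]); j <- j + 1L }
        prom <- h - max(minL, minR)
        eval_h <- h - 0.5 * prom
        ## left crossing (linear interpolation, rounded outward)
        j <- p
        while (j > 1L && x[j - 1L] >= eval_h && x[j - 1L] <= h) j <- j - 1L
        lb <- if (j > 1L && x[j - 1L] < eval_h) {
            j - (eval_h - x[j - 1L]) / (x[j] - x[j - 1L])
        } else j
        j <- p
        while (j < n && x[j + 1L] >= eval_h && x[j + 1L] <= h) j <- j + 1L
        rb <- if (j < n && x[j + 1L] < eval_h) {
            j + (x[j] - eval_h) / (x[j] - x[j + 1L])
        } else j
        data.frame(position = p, left = as.integer(floor(lb)),
                   right = as.integer(ceiling(rb)), height = h,
                   prominence = prom, width = rb - lb)
    })
    out <- do.call(rbind, res)
    out <- out[out$width >= widthRange[1L] & out$width <= widthRange[2L], ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Split a long locus at its coverage peaks
#'
#' Loci no longer than \code{maxLength} bases pass through unchanged. Longer
#' loci are replaced by one sub-locus per qualifying coverage peak (see
#' \code{\link{findCoveragePeaks}}): sub-locus bounds are the outward-rounded
#' half-prominence crossings, clipped to the parent; adjacent sub-loci are
#' truncated at the midpoint between their peak positions so outputs are
#' pairwise disjoint; any sub-locus narrower than the minimum peak width
#' after truncation is dropped. A long locus with no qualifying peak yields
#' an empty result unless \code{keepUnsplit} is set.
#'
#' @param locus a length-1 \code{GRanges}.
#' @param profile a \code{CoverageProfile} over the locus (or a bare depth
#'   vector of matching length).
#' @param height,widthRange,distance peak-caller parameters.
#' @param maxLength loci at most this long are never split (default 200).
#' @param keepUnsplit keep peakless long loci whole instead of discarding
#'   them (default FALSE).
#' @return a \code{GRanges} of 0, 1 or more sub-loci.
#' @export
splitLocus <- function(locus, profile, height = 10, widthRange = c(15, 200),
                       distance = 20, maxLength = 200, keepUnsplit = FALSE) {
    stopifnot(is(locus, "GRanges"), length(locus) == 1L)
    if (GenomicRanges::width(locus) <= maxLength) return(locus)
    depth <- if (inherits(profile, "CoverageProfile")) profile$depth
             else as.numeric(profile)
    if (length(depth) != GenomicRanges::width(locus))
        .stopf("profile length does not match locus width")
    pk <- findCoveragePeaks(depth, height = height, widthRange = widthRange,
                            distance = distance)
    if (nrow(pk) == 0L) {
        if (keepUnsplit) return(locus)
        return(locus[0])
    }
    np <- nrow(pk)
    lo <- pk$left
    hi <- pk$right
    if (np > 1L) {
        mids <- floor((pk$position[-np] + pk$position[-1L]) / 2)
        hi[-np] <- pmin(hi[-np], mids)
        lo[-1L] <- pmax(lo[-1L], mids + 1L)
    }
    lo <- pmax(lo, 1L)
    hi <- pmin(hi, GenomicRanges::width(locus))
    keep <- (hi - lo + 1L) >= widthRange[1L]
    lo <- lo[keep]; hi <- hi[keep]
    if (!length(lo)) {
        if (keepUnsplit) return(locus)
        return(locus[0])
    }
    GenomicRanges::GRanges(
        GenomicRanges::seqnames(locus),
        IRanges::IRanges(GenomicRanges::start(locus) + lo - 1L,
                         GenomicRanges::start(locus) + hi - 1L),
        strand = GenomicRanges::strand(locus))
}

#' Split every long locus in a merged locus set
#'
#' Convenience wrapper applying \code{\link{aggregateCoverage}} and
#' \code{\link{splitLocus}} to every locus longer than \code{maxLength},
#' using the pooled reads of the discovery cohort as the coverage signal.
#' Names are reassigned \code{locus_1..n} over the final sorted set.
#'
#' @param loci merged loci (\code{GRanges}).
#' @param reads pooled discovery reads.
#' @inheritParams splitLocus
#' @return a sorted, named \code{GRanges}.
#' @export
splitLongLoci <- function(loci, reads, height = 10, widthRange = c(15, 200),
                          distance = 20, maxLength = 200,
                          keepUnsplit = FALSE) {
    reads <- data.table::as.data.table(reads)
    long <- GenomicRanges::width(loci) > maxLength
    if (!any(long)) return(loci)
    pieces <- lapply(which(long), function(i) {
        prof <- aggregateCoverage(loci[i], reads)
        splitLocus(loci[i], prof, height = height, widthRange = widthRange,
                   distance = distance, maxLength = maxLength,
                   keepUnsplit = keepUnsplit)
    })
    out <- c(loci[!long], do.call(c, unname(pieces)))
    out <- GenomicRanges::sort(out, ignore.strand = TRUE)
    names(out) <- paste0("locus_", seq_along(out))
    out
}

#' Build the locus-by-sample count and presence matrices
#'
#' A locus is counted for a sample whenever one of the sample's reads
#' overlaps it by at least one base; counts are total overlapping read
#' weight, and presence is the binarized count. A read spanning several
#' disjoint loci increments each of them. Library sizes come from the
#' manifest when present, otherwise they are the per-sample total read
#' weight.
#'
#' @param loci disjoint, sorted \code{GRanges} of loci (names become row
#'   names).
#' @param reads read table covering all samples (column \code{sample_id}).
#' @param manifest sample manifest; every sample in \code{reads} must appear.
#' @return a \code{\linkS4class{PresenceMatrix}} with one column per manifest
#'   sample (samples without reads get zero columns).
#' @export
buildPresenceMatrix <- function(loci, reads, manifest) {
    stopifnot(is(loci, "GRanges"))
    reads <- data.table::as.data.table(reads)
    manifest <- as.data.frame(manifest)
    if (is.null(names(loci)))
        names(loci) <- paste0("locus_", seq_along(loci))
    unknown <- setdiff(unique(reads$sample_id), manifest$sample_id)
    if (length(unknown))
        .stopf("sample(s) present in reads but not manifest: %s",
               paste(head(unknown, 5L), collapse = ", "))
    samples <- as.character(manifest$sample_id)
    cnt <- matrix(0L, nrow = length(loci), ncol = length(samples),
                  dimnames = list(names(loci), samples))
    if (nrow(reads)) {
        gr <- .readsToGRanges(reads)
        ov <- GenomicRanges::findOverlaps(loci, gr, ignore.strand = TRUE)
        if (length(ov)) {
            dt <- data.table::data.table(
                locus = S4Vectors::queryHits(ov),
                sample = reads$sample_id[S4Vectors::subjectHits(ov)],
                w = reads$weight[S4Vectors::subjectHits(ov)])
            agg <- dt[, list(n = sum(w)), by = c("locus", "sample")]
            cnt[cbind(agg$locus, match(agg$sample, samples))] <-
                as.integer(agg$n)
        }
    }
    sampleData <- S4Vectors::DataFrame(manifest, row.names = samples)
    if (is.null(sampleData$library_size) || anyNA(sampleData$library_size)) {
        tot <- reads[, list(n = sum(weight)), by = "sample_id"]
        computed <- tot$n[match(samples, tot$sample_id)]
        computed[is.na(computed)] <- 0L
        if (is.null(sampleData$library_size))
            sampleData$library_size <- computed
        else {
            miss <- is.na(sampleData$library_size)
            sampleData$library_size[miss] <- computed[miss]
        }
        if (any(sampleData$library_size <= 0))
            .stopf("cannot derive a positive library size for sample(s): %s",
                   paste(samples[sampleData$library_size <= 0], collapse = ", "))
    }
    PresenceMatrix(cnt, loci, sampleData)
}

#' Counts per million
#'
#' Library-size normalized counts: \code{counts[i, j] * 1e6 /
#' library_size[j]}.
#'
#' @param x a \code{\linkS4class{PresenceMatrix}}.
#' @return a numeric matrix with the dimensions of \code{counts(x)}.
#' @export
countsPerMillion <- function(x) {
    stopifnot(is(x, "PresenceMatrix"))
    ls <- librarySizes(x)
    if (any(ls <= 0)) .stopf("library sizes must be positive")
    sweep(assay(x, "counts"), 2L, ls, function(cnt, l) cnt * 1e6 / l)
}
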