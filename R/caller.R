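#' Elbow (knee) threshold of a prevalence curve
#'
#' Sorts the prevalences in decreasing order and returns the value at the
#' index maximizing the perpendicular distance to the chord joining the
#' first and last points of the curve (the Kneedle rule). Deterministic;
#' ties resolve to the smaller index. An all-equal vector has no elbow and
#' is returned as-is with a warning.
#'
#' @param prevalence numeric vector of per-locus prevalences in [0, 1].
#' @return the prevalence value at the knee.
#' @export
elbowThreshold <- function(prevalence) {
    if (!is.numeric(prevalence) || length(prevalence) == 0L)
        .stopf("'prevalence' must be a nonempty numeric vector")
    if (any(is.na(prevalence)) || any(prevalence < 0 | prevalence > 1))
        .stopf("prevalences must lie in [0, 1]")
    y <- sort(prevalence, decreasing = TRUE)
    n <- length(y)
    if (n == 1L || diff(range(y)) == 0) {
        .warnf("prevalence curve has no elbow; returning its value")
        return(y[1L])
    }
    x <- seq_len(n)
    ## perpendicular distance to the chord (x1,y1)-(xn,yn)
    dx <- n - 1
    dy <- y[n] - y[1L]
    d <- abs(dy * (x - 1) - dx * (y - y[1L])) / sqrt(dx^2 + dy^2)
    y[which.max(d)]
}

.roleMask <- function(pm, role) colData(pm)$role == role

.presFrac <- function(pm, mask) {
    if (!any(mask)) return(rep(0, nrow(pm)))
    rowMeans(assay(pm, "presence")[, mask, drop = FALSE])
}

#' Biofluid-atlas filter
#'
#' Removes loci observed in more than \code{threshold} (a fraction) of the
#' non-cancerous biofluid atlas samples (role \code{"biofluid"} in the
#' manifest); the default 0.43\% may be replaced by
#' \code{\link{elbowThreshold}} on the observed atlas prevalence curve via
#' \code{threshold = "elbow"}.
#'
#' @param pm a \code{\linkS4class{PresenceMatrix}} covering the atlas
#'   samples.
#' @param threshold maximum tolerated atlas prevalence (strictly-greater
#'   removal), or \code{"elbow"}.
#' @return named logical vector: \code{TRUE} for kept loci.
#' @export
biofluidFilter <- function(pm, threshold = 0.0043) {
    mask <- .roleMask(pm, "biofluid")
    if (!any(mask)) {
        .warnf("no biofluid atlas samples; all loci kept")
        return(setNames(rep(TRUE, nrow(pm)), rownames(pm)))
    }
    frac <- .presFrac(pm, mask)
    if (identical(threshold, "elbow"))
        threshold <- elbowThreshold(frac)
    .checkProb(threshold, "threshold")
    setNames(frac <= threshold, rownames(pm))
}

#' Tumor-adjacent-normal filter
#'
#' Loci observed in more than \code{maxFrac} of the normal samples of any
#' eligible tissue are removed; a tissue is eligible only when it has at
#' least \code{minNormals} normal samples.
#'
#' @param pm a \code{\linkS4class{PresenceMatrix}}.
#' @param minNormals minimum normal cohort size for a tissue to count
#'   (default 10).
#' @param maxFrac maximum tolerated normal-tissue prevalence (strictly
#'   greater removal; default 0.10).
#' @return named logical keep vector.
#' @export
normalFilter <- function(pm, minNormals = 10L, maxFrac = 0.10) {
    .checkProb(maxFrac, "maxFrac")
    cd <- colData(pm)
    normals <- cd$role == "normal"
    tissues <- unique(cd$tissue[normals])
    eligible <- tissues[vapply(tissues, function(t)
        sum(normals & cd$tissue == t) >= minNormals, logical(1L))]
    if (!length(eligible)) {
        .warnf("no tissue has >= %d normal samples; all loci kept",
               minNormals)
        return(setNames(rep(TRUE, nrow(pm)), rownames(pm)))
    }
    keep <- rep(TRUE, nrow(pm))
    for (t in eligible) {
        frac <- .presFrac(pm, normals & cd$tissue == t)
        keep <- keep & frac <= maxFrac
    }
    setNames(keep, rownames(pm))
}

#' Cancer prevalence filter
#'
#' Retains loci present in at least \code{minFrac} of the tumor samples for
#' at least one tumor tissue type (boundary inclusive).
#'
#' @param pm a \code{\linkS4class{PresenceMatrix}}.
#' @param minFrac minimum tumor prevalence (default 0.10).
#' @return named logical keep vector.
#' @export
prevalenceFilter <- function(pm, minFrac = 0.10) {
    .checkProb(minFrac, "minFrac")
    cd <- colData(pm)
    tumors <- cd$role == "tumor"
    tissues <- unique(cd$tissue[tumors])
    keep <- rep(FALSE, nrow(pm))
    for (t in tissues) {
        frac <- .presFrac(pm, tumors & cd$tissue == t)
        keep <- keep | frac >= minFrac
    }
    setNames(keep, rownames(pm))
}

#' One-sided Fisher exact test for tumor-enriched presence
#'
#' Tests whether presence is enriched in tumors, i.e. the "greater"
#' alternative on the 2x2 table (a = present in tumor, b = absent in tumor,
#' c = present in normal, d = absent in normal). The p-value is the
#' hypergeometric upper-tail probability P(X >= a), accumulated in log space
#' for numerical robustness; the odds ratio is the unconditional ad/bc, with
#' +Inf when bc = 0 and ad > 0 (reported for ranking only).
#'
#' @param a,b,c,d nonnegative integer vectors (recycled to common length).
#' @return a \code{data.frame} with columns \code{odds_ratio} and
#'   \code{p_value}.
#' @examples
#' fisherExactGreater(10, 0, 0, 100)   # p = 1 / choose(110, 10)
#' @export
fisherExactGreater <- function(a, b, c, d) {
    n <- max(length(a), length(b), length(c), length(d))
    a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
    c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
    if (any(is.na(c(a, b, c, d))) || any(c(a, b, c, d) < 0))
        .stopf("table entries must be nonnegative")
    if (any(a + b < 1) || any(c + d < 1))
        .stopf("both margins (a+b and c+d) must be at least 1")
    p <- vapply(seq_len(n), function(i) {
        m <- a[i] + c[i]          # total present
        nn <- b[i] + d[i]         # total absent
        k <- a[i] + b[i]          # tumor samples drawn
        hiX <- min(k, m)
        if (a[i] > hiX) return(0)
        xs <- a[i]:hiX
        exp(.logSumExp(dhyper(xs, m, nn, k, log = TRUE)))
    }, numeric(1L))
    p <- pmin(p, 1)
    or <- ifelse(b * c == 0,
                 ifelse(a * d > 0, Inf, 1),
                 (a * d) / (b * c))
    data.frame(odds_ratio = or, p_value = p)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Thin validating wrapper over \code{stats::p.adjust(method = "BH")}:
#' q_(i) = min over j >= i of p_(j) m / j, capped at 1 and mapped back to
#' the input order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values in input order.
#' @export
bhFDR <- function(p) {
    if (!is.numeric(p) || length(p) == 0L)
        .stopf("'p' must be a nonempty numeric vector")
    if (any(is.na(p)) || any(p <= 0 | p > 1))
        .stopf("p-values must lie in (0, 1]")
    p.adjust(p, method = "BH")
}

#' Per-tissue Fisher enrichment stage
#'
#' For each tumor tissue type and each candidate locus, builds the 2x2
#' presence table of that tissue's tumors against all normal samples pooled
#' across tissues, applies \code{\link{fisherExactGreater}}, and
#' BH-corrects within each tissue's family of tests. A locus is kept when
#' its q-value is at most \code{fdr} in at least one tissue.
#'
#' @param pm a \code{\linkS4class{PresenceMatrix}}.
#' @param fdr FDR cutoff (default 0.1).
#' @param loci logical/character subset of candidate loci to test (default
#'   all rows).
#' @return a list with \code{results} (a \code{DataFrame} of per-locus,
#'   per-tissue \code{EnrichmentResult} rows) and \code{keep} (named logical
#'   over \emph{all} rows of \code{pm}; untested loci are \code{FALSE}).
#' @export
fisherStage <- function(pm, fdr = 0.1, loci = NULL) {
    .checkProb(fdr, "fdr")
    cd <- colData(pm)
    if (is.null(loci)) loci <- rep(TRUE, nrow(pm))
    if (is.character(loci)) loci <- rownames(pm) %in% loci
    idx <- which(loci)
    prs <- assay(pm, "presence")
    tumors <- cd$role == "tumor"
    normals <- cd$role == "normal"
    nN <- sum(normals)
    cPres <- if (nN) rowSums(prs[idx, normals, drop = FALSE]) else
        rep(0, length(idx))
    tissues <- sort(unique(cd$tissue[tumors]))
    resList <- list()
    keep <- setNames(rep(FALSE, nrow(pm)), rownames(pm))
    for (t in tissues) {
        mask <- tumors & cd$tissue == t
        nT <- sum(mask)
        if (nT == 0L) { .warnf("tissue %s has no tumors; skipped", t); next }
        aPres <- rowSums(prs[idx, mask, drop = FALSE])
        ft <- fisherExactGreater(aPres, nT - aPres, cPres, nN - cPres)
        q <- bhFDR(ft$p_value)
        keep[idx[q <= fdr]] <- TRUE
        resList[[t]] <- data.frame(
            locus_id = rownames(pm)[idx], tissue = t,
            a = aPres, b = nT - aPres, c = cPres, d = nN - cPres,
            odds_ratio = ft$odds_ratio, p_value = ft$p_value, q_value = q,
            stringsAsFactors = FALSE)
    }
    results <- if (length(resList)) {
        out <- do.call(rbind, resList)
        rownames(out) <- NULL
        S4Vectors::DataFrame(out)
    } else S4Vectors::DataFrame(locus_id = character(0), tissue = character(0))
    list(results = results, keep = keep)
}

#' Known-annotation filter
#'
#' Removes loci that overlap any known small-RNA annotation by at least one
#' base (strand-agnostic by default).
#'
#' @param loci candidate loci (\code{GRanges}).
#' @param annotations annotation loci (\code{GRanges}); empty keeps
#'   everything.
#' @param strandAware require same-strand overlap (default FALSE).
#' @return named logical keep vector over \code{loci}.
#' @export
annotationFilter <- function(loci, annotations, strandAware = FALSE) {
    stopifnot(is(loci, "GRanges"))
    if (is.null(annotations) || length(annotations) == 0L)
        return(setNames(rep(TRUE, length(loci)), names(loci)))
    hit <- IRanges::overlapsAny(loci, annotations,
                                ignore.strand = !strandAware)
    setNames(!hit, names(loci))
}

#' Non-cancerous serum filter
#'
#' Keeps loci detected in at most \code{maxSamples} of the non-cancerous
#' serum samples (role \code{"serum"}).
#'
#' @param pm a \code{\linkS4class{PresenceMatrix}}.
#' @param maxSamples maximum tolerated detections (default 1;
#'   strictly-greater removal).
#' @return named logical keep vector.
#' @export
serumFilter <- function(pm, maxSamples = 1L) {
    maxSamples <- .checkCount(maxSamples, "maxSamples")
    mask <- .roleMask(pm, "serum")
    if (!any(mask))
        return(setNames(rep(TRUE, nrow(pm)), rownames(pm)))
    nDet <- rowSums(assay(pm, "presence")[, mask, drop = FALSE])
    setNames(nDet <= maxSamples, rownames(pm))
}

#' Run the full oncRNA annotation cascade
#'
#' Applies, in order, the biofluid-atlas filter, the tumor-adjacent-normal
#' filter, the cancer prevalence filter, the per-tissue Fisher enrichment
#' stage, the known-annotation filter and the non-cancerous serum filter.
#' Each stage only removes loci; cumulative per-stage flags and survivor
#' counts are recorded in the returned catalog. The three presence filters
#' (biofluid, normal, serum) are independent predicates, so permuting them
#' in \code{stageOrder} leaves the final set unchanged.
#'
#' @param pm a \code{\linkS4class{PresenceMatrix}} over all cohorts (tumor,
#'   normal, biofluid, serum samples identified by the manifest role in
#'   \code{colData}).
#' @param annotations known small-RNA annotation \code{GRanges} (may be
#'   empty).
#' @param params parameter list, see \code{\link{pipelineDefaults}}.
#' @param stageOrder order in which stages are applied (a permutation of
#'   the six canonical stage names).
#' @return an \code{\linkS4class{OncRNACatalog}}.
#' @export
runCascade <- function(pm, annotations = NULL,
                       params = pipelineDefaults(),
                       stageOrder = .STAGES) {
    stopifnot(is(pm, "PresenceMatrix"))
    params <- utils::modifyList(pipelineDefaults(), params)
    if (!setequal(stageOrder, .STAGES))
        .stopf("'stageOrder' must be a permutation of the six stages")
    if (!any(colData(pm)$role == "tumor"))
        .stopf("cascade requires at least one tumor sample")
    loci <- rowRanges(pm)
    n <- nrow(pm)
    surv <- setNames(rep(TRUE, n), rownames(pm))
    rawKeep <- list()
    enr <- NULL
    for (stage in stageOrder) {
        keep <- switch(stage,
            biofluid = biofluidFilter(pm, params$biofluidThreshold),
            normal = normalFilter(pm, params$minNormals,
                                  params$maxNormalFrac),
            prevalence = prevalenceFilter(pm, params$minTumorFrac),
            fisher = {
                fs <- fisherStage(pm, params$fdr, loci = surv)
                enr <- fs$results
                fs$keep
            },
            annotation = annotationFilter(loci, annotations,
                                          params$strandAware),
            serum = serumFilter(pm, params$serumMaxSamples))
        surv <- surv & keep
        rawKeep[[stage]] <- keep
        .logmsg("stage %-10s: %d survivors", stage, sum(surv))
    }
    ## flags and survivor counts are reported along the canonical stage
    ## order as cumulative conjunctions of the per-stage predicates, so
    ## that survivor sets are nested however the independent presence
    ## filters were permuted during application
    flags <- list()
    counts <- c(input = n)
    cum <- rep(TRUE, n)
    for (stage in .STAGES) {
        cum <- cum & rawKeep[[stage]]
        flags[[stage]] <- unname(cum)
        counts[stage] <- sum(cum)
    }
    fl <- S4Vectors::DataFrame(flags)
    colnames(fl) <- paste0("passed_", .STAGES)
    if (is.null(enr))
        enr <- S4Vectors::DataFrame(locus_id = character(0),
                                    tissue = character(0))
    new("OncRNACatalog", loci = loci, stageFlags = fl, enrichment = enr,
        stageCounts = counts, params = params)
}
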