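#' Extract oncRNA barcodes from a presence matrix
#'
#' An oncRNA barcode is the binary presence/absence vector of the catalog
#' loci for one sample -- the digital signature the cohort statistics work
#' on.
#'
#' @param pm a \code{\linkS4class{PresenceMatrix}}.
#' @param catalog an \code{\linkS4class{OncRNACatalog}} (its final loci
#'   define the barcode order), or \code{NULL} to use all loci of \code{pm}.
#' @param samples optional character/logical selection of samples.
#' @return a binary integer matrix, loci in rows, samples in columns.
#' @export
extractBarcodes <- function(pm, catalog = NULL, samples = NULL) {
    stopifnot(is(pm, "PresenceMatrix"))
    prs <- assay(pm, "presence")
    if (!is.null(catalog)) {
        ids <- names(finalLoci(catalog))
        miss <- setdiff(ids, rownames(prs))
        if (length(miss))
            .stopf("catalog loci absent from the presence matrix: %s",
                   paste(head(miss, 5L), collapse = ", "))
        prs <- prs[ids, , drop = FALSE]
    }
    if (!is.null(samples)) prs <- prs[, samples, drop = FALSE]
    prs
}

#' Jaccard similarity of two barcodes
#'
#' \code{|a AND b| / |a OR b|}, defined as 0 when both barcodes are
#' all-zero (an all-zero sample carries no identity signal).
#'
#' @param a,b binary vectors of equal length.
#' @return a similarity in [0, 1].
#' @export
jaccardSimilarity <- function(a, b) {
    if (length(a) != length(b))
        .stopf("barcodes differ in length (%d vs %d)", length(a), length(b))
    a <- a != 0; b <- b != 0
    un <- sum(a | b)
    if (un == 0L) return(0)
    sum(a & b) / un
}

## All pairwise Jaccard similarities of the columns of a binary matrix
.pairwiseJaccard <- function(m) {
    m <- (m != 0) * 1
    inter <- crossprod(m)
    sizes <- colSums(m)
    un <- outer(sizes, sizes, "+") - inter
    j <- ifelse(un == 0, 0, inter / un)
    diag(j) <- 1
    j
}

#' Within- versus between-group barcode similarity
#'
#' For each group (e.g. tissue of origin): the median pairwise Jaccard
#' similarity among its samples, the median similarity of its samples
#' against all samples of other groups, and a one-sided Wilcoxon rank-sum
#' p-value testing that within-group pairs are more similar.
#'
#' @param barcodes binary matrix, loci in rows, samples in columns.
#' @param groups group label per sample (column).
#' @return a \code{data.frame} with one row per group: \code{group},
#'   \code{n}, \code{median_within}, \code{median_between},
#'   \code{p_value}; singleton groups are skipped with a warning.
#' @export
barcodeSimilaritySummary <- function(barcodes, groups) {
    if (ncol(barcodes) != length(groups))
        .stopf("'groups' must label every barcode column")
    if (length(unique(groups)) < 2L)
        .stopf("at least two groups are required")
    jm <- .pairwiseJaccard(barcodes)
    out <- lapply(sort(unique(groups)), function(g) {
        inG <- which(groups == g)
        if (length(inG) < 2L) {
            .warnf("group %s has a single sample; skipped", g)
            return(NULL)
        }
        within <- jm[inG, inG][upper.tri(matrix(0, length(inG),
                                                length(inG)))]
        between <- as.vector(jm[inG, -inG, drop = FALSE])
        p <- mannWhitneyOneSided(within, between)$p_value
        data.frame(group = g, n = length(inG),
                   median_within = median(within),
                   median_between = median(between),
                   p_value = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Nearest-centroid barcode classification
#'
#' A deliberately simple tissue-of-origin baseline over oncRNA barcodes:
#' each class centroid is the mean bit vector of its training samples; a
#' test sample is assigned to the class maximizing the real-valued Jaccard
#' generalization sum(min(x, c)) / sum(max(x, c)). Ties (including the
#' all-zero barcode against all-zero centroids) resolve to the
#' lexicographically smallest label.
#'
#' @param train binary matrix of training barcodes (loci x samples).
#' @param trainLabels class label per training sample.
#' @param test binary matrix of test barcodes over the same loci.
#' @return character vector of predicted labels, one per test sample.
#' @export
centroidClassify <- function(train, trainLabels, test) {
    if (ncol(train) == 0L) .stopf("empty training set")
    if (ncol(train) != length(trainLabels))
        .stopf("one label per training sample required")
    if (nrow(train) != nrow(test))
        .stopf("train and test barcodes differ in locus dimension")
    labs <- sort(unique(as.character(trainLabels)))
    centroids <- vapply(labs, function(l)
        rowMeans(train[, trainLabels == l, drop = FALSE]),
        numeric(nrow(train)))
    apply(test, 2L, function(x) {
        scores <- vapply(seq_along(labs), function(j) {
            cj <- centroids[, j]
            den <- sum(pmax(x, cj))
            if (den == 0) 0 else sum(pmin(x, cj)) / den
        }, numeric(1L))
        labs[which.max(scores)]   # which.max takes the first = smallest label
    })
}

#' Per-locus one-way ANOVA across subtype groups
#'
#' Screens every locus for association between its expression and a subtype
#' label with the classic one-way F test, computed row-wise over the whole
#' matrix (the textbook between/within decomposition, vectorized).
#' Expression defaults to \code{log(cpm + 1)}; a binary presence mode is
#' available. Groups with fewer than 2 samples are excluded with a warning.
#' Loci with zero total variance are skipped; loci with zero within-group
#' but nonzero between-group variance are flagged degenerate rather than
#' given an infinite F. q-values are BH over all tested (non-degenerate)
#' loci.
#'
#' @param expr numeric matrix, loci in rows, samples in columns (e.g.
#'   \code{countsPerMillion(pm)}).
#' @param groups subtype label per sample.
#' @param transform \code{"log1p"} (natural log of value + 1, the default),
#'   \code{"binary"} (nonzero indicator) or \code{"identity"}.
#' @return a \code{data.frame}: \code{locus_id}, \code{statistic} (F),
#'   \code{df1}, \code{df2}, \code{p_value}, \code{q_value},
#'   \code{degenerate}, \code{tested}.
#' @export
subtypeAnova <- function(expr, groups, transform = c("log1p", "binary",
                                                     "identity")) {
    transform <- match.arg(transform)
    if (ncol(expr) != length(groups))
        .stopf("'groups' must label every sample column")
    groups <- as.character(groups)
    sizes <- table(groups)
    small <- names(sizes)[sizes < 2L]
    if (length(small)) {
        .warnf("group(s) with < 2 samples excluded: %s",
               paste(small, collapse = ", "))
        keep <- !groups %in% small
        expr <- expr[, keep, drop = FALSE]
        groups <- groups[keep]
    }
    labs <- unique(groups)
    if (length(labs) < 2L)
        .stopf("at least two groups with >= 2 samples are required")
    x <- switch(transform,
                log1p = log(expr + 1),
                binary = (expr != 0) * 1,
                identity = expr)
    N <- ncol(x)
    k <- length(labs)
    grand <- rowMeans(x)
    ssTot <- rowSums((x - grand)^2)
    ssB <- numeric(nrow(x))
    for (l in labs) {
        mask <- groups == l
        m <- rowMeans(x[, mask, drop = FALSE])
        ssB <- ssB + sum(mask) * (m - grand)^2
    }
    ssW <- pmax(ssTot - ssB, 0)
    df1 <- k - 1L
    df2 <- N - k
    eps <- 1e-12 * pmax(ssTot, 1)
    constant <- ssTot <= eps
    degenerate <- !constant & ssW <= eps
    Fstat <- rep(NA_real_, nrow(x))
    p <- rep(NA_real_, nrow(x))
    ok <- !constant & !degenerate
    Fstat[ok] <- (ssB[ok] / df1) / (ssW[ok] / df2)
    p[ok] <- pf(Fstat[ok], df1, df2, lower.tail = FALSE)
    ## all groups identical: F = 0, p = 1 by convention
    Fstat[constant] <- 0
    p[constant] <- 1
    q <- rep(NA_real_, nrow(x))
    tested <- ok | constant
    if (any(tested)) q[tested] <- bhFDR(p[tested])
    data.frame(locus_id = rownames(x) %||% as.character(seq_len(nrow(x))),
               statistic = Fstat, df1 = df1, df2 = df2,
               p_value = p, q_value = q,
               degenerate = degenerate, tested = tested,
               stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exclusive group-combination detection counts
#'
#' Assigns every locus to the exact set of groups in which at least one
#' sample detects it (UpSet-style exact-set semantics) and counts loci per
#' combination. Loci detected nowhere are counted under \code{"(none)"}.
#' Counts always partition the locus set.
#'
#' @param presence binary matrix, loci in rows, samples in columns.
#' @param groups group label per sample.
#' @return a \code{data.frame} with \code{combination} (labels joined by
#'   \code{"+"}), \code{count}.
#' @export
exclusiveCounts <- function(presence, groups) {
    if (ncol(presence) != length(groups))
        .stopf("'groups' must label every sample column")
    labs <- sort(unique(as.character(groups)))
    det <- vapply(labs, function(g)
        rowSums(presence[, groups == g, drop = FALSE]) > 0,
        logical(nrow(presence)))
    if (nrow(presence) == 1L) det <- matrix(det, nrow = 1L)
    combo <- apply(det, 1L, function(r)
        if (!any(r)) "(none)" else paste(labs[r], collapse = "+"))
    tab <- table(combo)
    data.frame(combination = names(tab), count = as.integer(tab),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' One-sided Mann-Whitney U test (x stochastically greater than y)
#'
#' The U statistic counts pairs with x_i > y_j (ties count one half). The
#' p-value is exact -- from the null distribution of U -- when
#' n + m <= \code{exactLimit} and there are no ties, and otherwise uses the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric vectors (both nonempty).
#' @param exactLimit switch point between the exact and approximate branch
#'   (default 12).
#' @return a list with \code{U} and \code{p_value}.
#' @export
mannWhitneyOneSided <- function(x, y, exactLimit = 12L) {
    if (!length(x) || !length(y))
        .stopf("both samples must be nonempty")
    n <- length(x); m <- length(y)
    r <- rank(c(x, y))
    U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    ties <- anyDuplicated(c(x, y)) > 0L
    if (!ties && (n + m) <= exactLimit) {
        ## exact upper tail P(U >= u) from the null distribution
        p <- pwilcox(U - 1, n, m, lower.tail = FALSE)
    } else {
        N <- n + m
        tieTab <- table(r)
        tieCorr <- sum(tieTab^3 - tieTab) / (N * (N - 1))
        sigma2 <- n * m / 12 * ((N + 1) - tieCorr)
        if (sigma2 <= 0) return(list(U = U, p_value = 1))
        z <- (U - n * m / 2 - 0.5) / sqrt(sigma2)
        p <- pnorm(z, lower.tail = FALSE)
    }
    list(U = U, p_value = min(max(p, .Machine$double.xmin), 1))
}

#' Presence-accessibility association per locus
#'
#' For every locus whose oncRNA is detected in at least \code{minPresent}
#' samples (and absent in at least one), tests whether chromatin
#' accessibility is higher in the samples where the oncRNA is present
#' (one-sided Mann-Whitney), with the effect size reported as
#' \code{log2((median_present + 1) / (median_absent + 1))} (unit
#' pseudocount for zero handling). q-values are BH over tested loci; the
#' significant set is \code{q <= fdr} and positive effect.
#'
#' @param presence binary matrix, loci in rows, samples in columns.
#' @param accessibility numeric score matrix over the same loci and samples
#'   (matching dimnames required).
#' @param minPresent minimum number of expressing samples for a locus to be
#'   tested (default 5).
#' @param fdr FDR level for the significant set (default 0.01).
#' @return a \code{data.frame}: \code{locus_id}, \code{n_present},
#'   \code{statistic} (U), \code{effect}, \code{p_value}, \code{q_value},
#'   \code{significant}; untested loci carry \code{NA}.
#' @export
atacAssociation <- function(presence, accessibility, minPresent = 5L,
                            fdr = 0.01) {
    if (!identical(dim(presence), dim(accessibility)))
        .stopf("presence and accessibility matrices must have equal dims")
    if (!is.null(colnames(presence)) && !is.null(colnames(accessibility)) &&
        !identical(colnames(presence), colnames(accessibility)))
        .stopf("sample columns differ between presence and accessibility")
    minPresent <- .checkCount(minPresent, "minPresent")
    .checkProb(fdr, "fdr")
    nP <- rowSums(presence != 0)
    nA <- ncol(presence) - nP
    testable <- nP >= minPresent & nA >= 1L
    stat <- eff <- p <- rep(NA_real_, nrow(presence))
    for (i in which(testable)) {
        pres <- presence[i, ] != 0
        xs <- accessibility[i, pres]
        ys <- accessibility[i, !pres]
        mw <- mannWhitneyOneSided(xs, ys)
        stat[i] <- mw$U
        p[i] <- mw$p_value
        eff[i] <- log2((median(xs) + 1) / (median(ys) + 1))
    }
    q <- rep(NA_real_, nrow(presence))
    if (any(testable)) q[testable] <- bhFDR(p[testable])
    data.frame(
        locus_id = rownames(presence) %||%
            as.character(seq_len(nrow(presence))),
        n_present = nP, statistic = stat, effect = eff,
        p_value = p, q_value = q,
        significant = !is.na(q) & q <= fdr & eff > 0,
        stringsAsFactors = FALSE)
}
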