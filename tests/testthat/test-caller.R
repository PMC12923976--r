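test_that("elbowThreshold finds the knee of a prevalence curve", {
    ## sharp knee: 100 points at 0.20 then 900 at 0.004
    v <- c(rep(0.20, 100), rep(0.004, 900))
    th <- elbowThreshold(v)
    ## the chord-distance maximum sits at the corner where the curve drops
    ## onto its low plateau; as a keep-if-at-most threshold this separates
    ## the rare loci from the prevalent ones
    expect_gte(th, 0.004)
    expect_lt(th, 0.20)
    ySorted <- sort(v, decreasing = TRUE)
    expect_equal(th, ySorted[oracleElbowIndex(ySorted)])
    ## linearly decreasing curve: matches the geometric oracle
    v2 <- seq(1, 0, length.out = 51)
    y2 <- sort(v2, decreasing = TRUE)
    expect_equal(elbowThreshold(v2), y2[oracleElbowIndex(y2)])
    ## constant vector: returned with a warning
    expect_warning(th3 <- elbowThreshold(rep(0.3, 10)), "elbow")
    expect_equal(th3, 0.3)
    expect_error(elbowThreshold(numeric(0)), "nonempty")
})

test_that("biofluid filter removes loci above the atlas prevalence cutoff", {
    ## 1000 atlas samples; loci present in 5 (0.5%), 4 (0.4%) and 0
    pres <- rbind(
        c(rep(1L, 5), rep(0L, 995)),
        c(rep(1L, 4), rep(0L, 996)),
        rep(0L, 1000))
    rownames(pres) <- c("over", "under", "zero")
    pm <- pmFromPresence(pres, roles = rep("biofluid", 1000))
    keep <- biofluidFilter(pm, threshold = 0.0043)
    expect_false(keep[["over"]])     # 0.5% > 0.43% -> removed
    expect_true(keep[["under"]])     # 0.4% kept
    expect_true(keep[["zero"]])
    ## empty atlas: all kept with a warning
    pm2 <- pmFromPresence(pres[, 1:4], roles = rep("tumor", 4))
    expect_warning(k2 <- biofluidFilter(pm2), "atlas")
    expect_true(all(k2))
})

test_that("normal filter honours the eligibility and prevalence rules", {
    ## tissue A: 12 normals (eligible), tissue B: 9 normals (ignored)
    roles <- rep("normal", 21)
    tissues <- c(rep("A", 12), rep("B", 9))
    pres <- rbind(
        c(rep(1L, 2), rep(0L, 10), rep(0L, 9)),   # 2/12 = 16.7% in A
        c(rep(1L, 1), rep(0L, 11), rep(0L, 9)),   # 1/12 = 8.3% in A
        c(rep(0L, 12), rep(1L, 3), rep(0L, 6)))   # 3/9 in ineligible B
    rownames(pres) <- c("hot", "cool", "bOnly")
    pm <- pmFromPresence(pres, roles, tissues)
    keep <- normalFilter(pm, minNormals = 10L, maxFrac = 0.10)
    expect_false(keep[["hot"]])
    expect_true(keep[["cool"]])
    expect_true(keep[["bOnly"]])     # only tissue ignored, no other evidence
    ## nothing eligible: warning, all kept
    pmB <- pmFromPresence(pres[, 13:21], roles = rep("normal", 9),
                          tissues = rep("B", 9))
    expect_warning(kB <- normalFilter(pmB), "normal")
    expect_true(all(kB))
})

test_that("prevalence filter keeps >= 10% in at least one tumor tissue", {
    roles <- rep("tumor", 80)
    tissues <- c(rep("X", 60), rep("Y", 20))
    pres <- rbind(
        c(rep(1L, 6), rep(0L, 54), rep(0L, 20)),    # 6/60 = 10.0% exactly
        c(rep(1L, 3), rep(0L, 57), rep(0L, 20)),    # 5% max
        c(rep(0L, 60), rep(1L, 20)))                # 100% in Y
    rownames(pres) <- c("edge", "rare", "yOnly")
    pm <- pmFromPresence(pres, roles, tissues)
    keep <- prevalenceFilter(pm, minFrac = 0.10)
    expect_true(keep[["edge"]])      # inclusive boundary
    expect_false(keep[["rare"]])
    expect_true(keep[["yOnly"]])
})

test_that("fisherExactGreater equals hypergeometric enumeration", {
    ## no presence anywhere: p = 1
    expect_equal(fisherExactGreater(0, 10, 0, 100)$p_value, 1.0)
    ## maximal enrichment: p = 1 / choose(110, 10)
    expect_equal(fisherExactGreater(10, 0, 0, 100)$p_value,
                 1 / choose(110, 10), tolerance = 1e-12)
    expect_equal(fisherExactGreater(10, 0, 0, 100)$odds_ratio, Inf)
    ## random tables vs the enumeration oracle and stats::fisher.test
    set.seed(77)
    for (i in 1:200) {
        a <- sample(0:15, 1); b <- sample(0:15, 1)
        c <- sample(0:15, 1); d <- sample(0:15, 1)
        if (a + b == 0) a <- 1
        if (c + d == 0) d <- 1
        p <- fisherExactGreater(a, b, c, d)$p_value
        expect_equal(p, oracleFisherGreater(a, b, c, d), tolerance = 1e-9)
        ft <- stats::fisher.test(matrix(c(a, c, b, d), 2),
                                 alternative = "greater")
        expect_equal(p, unname(ft$p.value), tolerance = 1e-9)
    }
    expect_error(fisherExactGreater(-1, 2, 3, 4), "nonnegative")
    expect_error(fisherExactGreater(0, 0, 3, 4), "margin")
})

test_that("bhFDR matches the step-up definition", {
    expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhFDR(0.2), 0.2)
    expect_equal(bhFDR(rep(0.07, 5)), rep(0.07, 5))
    set.seed(12)
    for (i in 1:20) {
        p <- runif(sample(1:100, 1))
        expect_equal(bhFDR(p), oracleBH(p), tolerance = 1e-12)
    }
    expect_error(bhFDR(c(0.5, 0)), "0, 1")
    expect_error(bhFDR(c(0.5, 1.2)), "0, 1")
})

test_that("fisherStage tests per tissue against pooled normals", {
    ## 60 tumors of tissue X, 20 of Y, 150 pooled normals
    roles <- c(rep("tumor", 80), rep("normal", 150))
    tissues <- c(rep("X", 60), rep("Y", 20), rep("N", 150))
    pres <- rbind(
        strong = c(rep(1L, 30), rep(0L, 30), rep(0L, 20), rep(0L, 150)),
        nowhere = rep(0L, 230))
    pm <- pmFromPresence(pres, roles, tissues)
    fs <- fisherStage(pm, fdr = 0.1)
    res <- as.data.frame(fs$results)
    strongX <- res[res$locus_id == "strong" & res$tissue == "X", ]
    expect_equal(strongX$a, 30)
    expect_equal(strongX$c, 0)
    expect_lt(strongX$q_value, 1e-6)
    expect_true(fs$keep[["strong"]])
    nowhereX <- res[res$locus_id == "nowhere" & res$tissue == "X", ]
    expect_equal(nowhereX$p_value, 1)
    expect_false(fs$keep[["nowhere"]])
    ## fdr = 0 keeps nothing
    fs0 <- fisherStage(pm, fdr = 0)
    expect_false(any(fs0$keep))
})

test_that("annotation and serum filters apply their boundary conventions", {
    loci <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(101, 101), c(130, 130)))
    names(loci) <- c("x", "y")
    ## 1-bp overlap removes; book-ended interval does not
    ann1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(130, 160))
    expect_equal(unname(annotationFilter(loci[1], ann1)), FALSE)
    ann2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(131, 160))
    expect_equal(unname(annotationFilter(loci[1], ann2)), TRUE)
    expect_true(all(annotationFilter(loci, GenomicRanges::GRanges())))

    ## serum: detected in 2 of 30 -> removed; 1 -> kept; 0 -> kept
    pres <- rbind(two = c(1L, 1L, rep(0L, 28)),
                  one = c(1L, rep(0L, 29)),
                  zero = rep(0L, 30))
    pm <- pmFromPresence(pres, roles = rep("serum", 30))
    keep <- serumFilter(pm, maxSamples = 1L)
    expect_equal(unname(keep), c(FALSE, TRUE, TRUE))
})

test_that("the cascade is monotone, order-stable and neutralizable", {
    sc <- smallCohort()
    catalog <- runCascade(sc$pm, sc$cohort$annotations)
    fl <- as.data.frame(stageFlags(catalog))
    ## monotone survivor sets
    m <- as.matrix(fl)
    expect_true(all(apply(m, 1, function(r) all(diff(r) <= 0))))
    expect_true(all(diff(stageCounts(catalog)) <= 0))
    ## final set = all six flags
    expect_equal(sum(rowSums(m) == 6L), length(catalog))

    ## permuting the three presence filters leaves the final set unchanged
    perms <- list(
        c("serum", "normal", "prevalence", "fisher", "annotation",
          "biofluid"),
        c("normal", "biofluid", "prevalence", "fisher", "annotation",
          "serum"))
    for (p in perms) {
        alt <- runCascade(sc$pm, sc$cohort$annotations, stageOrder = p)
        expect_identical(names(finalLoci(alt)), names(finalLoci(catalog)))
    }

    ## neutralized thresholds reduce to the prevalence-filtered
    ## Fisher-significant set
    lax <- runCascade(sc$pm, NULL, params = list(
        biofluidThreshold = 1, maxNormalFrac = 1, serumMaxSamples =
            ncol(sc$pm)))
    pf <- prevalenceFilter(sc$pm)
    ff <- fisherStage(sc$pm, 0.1, loci = pf)
    expect_setequal(names(finalLoci(lax)), names(which(pf & ff$keep)))

    ## a cohort without tumors is rejected
    sub <- sc$pm[, SummarizedExperiment::colData(sc$pm)$role != "tumor"]
    expect_error(runCascade(sub, NULL), "tumor")
})
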