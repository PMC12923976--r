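test_that("jaccardSimilarity follows the set formula and conventions", {
    expect_equal(jaccardSimilarity(c(1, 1, 0), c(1, 0, 0)), 0.5)
    expect_equal(jaccardSimilarity(c(1, 0, 1), c(1, 0, 1)), 1.0)
    expect_equal(jaccardSimilarity(c(1, 0, 0), c(0, 1, 1)), 0.0)
    ## two all-zero barcodes: defined 0, not NaN
    expect_equal(jaccardSimilarity(c(0, 0), c(0, 0)), 0)
    ## symmetry
    a <- c(1, 1, 0, 1, 0); b <- c(0, 1, 1, 1, 0)
    expect_equal(jaccardSimilarity(a, b), jaccardSimilarity(b, a))
    expect_error(jaccardSimilarity(c(1, 0), c(1, 0, 1)), "length")
})

test_that("within-tissue barcode similarity exceeds between-tissue", {
    sc <- smallCohort()
    cd <- as.data.frame(SummarizedExperiment::colData(sc$pm))
    tumors <- cd$sample_id[cd$role == "tumor"]
    catalog <- runCascade(sc$pm, sc$cohort$annotations)
    bc <- extractBarcodes(sc$pm, catalog, samples = tumors)
    groups <- cd$tissue[match(tumors, cd$sample_id)]
    summ <- barcodeSimilaritySummary(bc, groups)
    expect_true(all(summ$median_within > summ$median_between))
    expect_true(all(summ$p_value < 0.01))

    ## shuffling the labels removes the separation
    set.seed(8)
    shuf <- sample(groups)
    s2 <- barcodeSimilaritySummary(bc, shuf)
    expect_true(all(abs(s2$median_within - s2$median_between) < 0.05))

    ## two identical groups of identical barcodes: both medians 1
    ident <- matrix(1L, nrow = 5, ncol = 6)
    s3 <- barcodeSimilaritySummary(ident, rep(c("a", "b"), each = 3))
    expect_equal(s3$median_within, c(1, 1))
    expect_equal(s3$median_between, c(1, 1))
})

test_that("centroid classification recovers tissue of origin", {
    ## unanimous class pattern maps to its class
    train <- cbind(a1 = c(1, 1, 0, 0), a2 = c(1, 1, 0, 0),
                   b1 = c(0, 0, 1, 1), b2 = c(0, 0, 1, 1))
    labels <- c("A", "A", "B", "B")
    expect_equal(centroidClassify(train, labels,
                                  cbind(x = c(1, 1, 0, 0))), c(x = "A"))
    ## all-zero test barcode: documented tie to the smallest label
    expect_equal(unname(centroidClassify(train, labels,
                                         cbind(c(0, 0, 0, 0)))), "A")
    expect_error(centroidClassify(train[, 0], character(0), train), "empty")

    ## 80/20 split on the simulated cohort: high accuracy
    sc <- smallCohort()
    cd <- as.data.frame(SummarizedExperiment::colData(sc$pm))
    tumors <- cd$sample_id[cd$role == "tumor"]
    catalog <- runCascade(sc$pm, sc$cohort$annotations)
    bc <- extractBarcodes(sc$pm, catalog, samples = tumors)
    groups <- cd$tissue[match(tumors, cd$sample_id)]
    set.seed(21)
    test <- sample(length(tumors), round(0.2 * length(tumors)))
    pred <- centroidClassify(bc[, -test], groups[-test],
                             bc[, test, drop = FALSE])
    expect_gte(mean(pred == groups[test]), 0.9)
})

test_that("subtypeAnova matches the textbook F computation", {
    ## identical values in all groups: F = 0, p = 1 by convention
    x <- matrix(5, nrow = 1, ncol = 9)
    r <- subtypeAnova(x, rep(c("a", "b", "c"), each = 3),
                      transform = "identity")
    expect_equal(r$statistic, 0)
    expect_equal(r$p_value, 1)
    ## zero within-group variance with nonzero between: degenerate flag
    x2 <- matrix(rep(c(0, 5), c(3, 3)), nrow = 1)
    r2 <- subtypeAnova(x2, rep(c("a", "b"), each = 3),
                       transform = "identity")
    expect_true(r2$degenerate)
    expect_true(is.na(r2$p_value))
    ## random Gaussian data vs oneway.test on 100 instances
    set.seed(33)
    groups <- rep(c("g1", "g2", "g3"), times = c(5, 7, 6))
    xs <- matrix(rnorm(100 * length(groups)), nrow = 100)
    res <- subtypeAnova(xs, groups, transform = "identity")
    for (i in seq_len(100)) {
        o <- oracleAnovaRow(xs[i, ], groups)
        expect_equal(res$statistic[i], o$F, tolerance = 1e-8)
        expect_equal(res$p_value[i], o$p, tolerance = 1e-8)
    }
    ## q-values are BH over tested loci
    expect_equal(res$q_value, oracleBH(res$p_value), tolerance = 1e-12)
    ## groups of size < 2 are dropped with a warning
    expect_warning(
        subtypeAnova(xs[1:3, c(1:12, 13)], c(groups[1:12], "solo"),
                     transform = "identity"), "excluded")
})

test_that("exclusiveCounts partitions loci by exact group set", {
    pres <- rbind(
        onlyA = c(1L, 1L, 0L, 0L),
        both = c(1L, 0L, 1L, 0L),
        none = c(0L, 0L, 0L, 0L))
    groups <- c("A", "A", "B", "B")
    ec <- exclusiveCounts(pres, groups)
    expect_equal(ec$count[ec$combination == "A"], 1L)
    expect_equal(ec$count[ec$combination == "A+B"], 1L)
    expect_equal(ec$count[ec$combination == "(none)"], 1L)
    ## the combination counts always sum to the locus total
    sc <- smallCohort()
    cd <- as.data.frame(SummarizedExperiment::colData(sc$pm))
    tumors <- cd$role == "tumor"
    ec2 <- exclusiveCounts(presence(sc$pm)[, tumors],
                           cd$tissue[tumors])
    expect_equal(sum(ec2$count), nrow(sc$pm))
})

test_that("mannWhitneyOneSided agrees with enumeration and symmetry", {
    ## worked example: x fully above y, p = 1/C(5,2)
    r <- mannWhitneyOneSided(c(3, 4, 5), c(1, 2))
    expect_equal(r$U, 6)
    expect_equal(r$p_value, 0.1)
    ## exact branch vs enumeration for all sizes with n + m <= 12
    set.seed(55)
    for (n in 1:6) for (m in 1:6) {
        x <- sample(seq_len(100), n)
        y <- sample(setdiff(seq_len(100), x), m)
        expect_equal(mannWhitneyOneSided(x, y)$p_value, oracleMWU(x, y),
                     tolerance = 1e-12)
    }
    ## identical multisets in the approximate branch: p near 0.5
    x <- rep(1:10, 2)
    expect_equal(mannWhitneyOneSided(x, x)$p_value, 0.5, tolerance = 0.05)
    expect_error(mannWhitneyOneSided(numeric(0), 1), "nonempty")
})

test_that("atacAssociation tests, corrects and reports one-sidedly", {
    sc <- smallCohort()
    cd <- as.data.frame(SummarizedExperiment::colData(sc$pm))
    tumors <- cd$sample_id[cd$role == "tumor"]
    pm <- sc$pm[, tumors]
    prs <- presence(pm)

    ## strong planted effect: accessible loci with enough expressing
    ## samples are recovered with positive effects
    acc <- simulateAccessibility(pm, effect = 4, noiseSd = 0.5, seed = 3L)
    res <- atacAssociation(prs, acc$scores)
    testable <- res$n_present >= 5 & res$n_present < ncol(prs)
    planted <- acc$accessible & testable
    expect_gte(mean(res$significant[planted]), 0.8)
    expect_true(all(res$effect[res$significant] > 0))
    ## loci with < 5 expressing samples are never tested
    expect_true(all(is.na(res$p_value[res$n_present < 5])))

    ## no true effect: at most ~nominal FDR of tested loci significant
    acc0 <- simulateAccessibility(pm, effect = 0, noiseSd = 1, seed = 4L)
    res0 <- atacAssociation(prs, acc0$scores)
    nTested <- sum(!is.na(res0$q_value))
    se <- sqrt(0.01 * 0.99 / nTested)
    expect_lte(mean(res0$significant[!is.na(res0$q_value)]),
               0.01 + 3 * se)

    ## dimension mismatches are rejected
    expect_error(atacAssociation(prs[, -1], acc$scores), "dims")
})
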