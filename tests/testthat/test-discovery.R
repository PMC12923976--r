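test_that("dustScore matches its closed forms and the brute-force counter", {
    ## 30-nt homopolymer: k = 28, sum = 28*27/2 = 378, score = 378/27 = 14
    expect_equal(dustScore(strrep("A", 30)), 14.0)
    ## ACGT repeated to 30 nt: 4 distinct triplets x 7 each (+ partial),
    ## enumerated by the oracle
    tet <- substr(strrep("ACGT", 8), 1, 30)
    expect_equal(dustScore(tet), oracleDust(tet))
    expect_equal(oracleDust(tet), 84 / 27)
    ## all-distinct triplets score exactly 0
    s0 <- "GTTGCTAAAGCCCGGGAGTCGCATTATGAA"
    trips <- substring(s0, 1:28, 3:30)
    stopifnot(!anyDuplicated(trips))
    expect_equal(dustScore(s0), 0)
    ## N-containing triplets are excluded from the counts
    expect_equal(dustScore("AANAA"), 0)          # both triplets contain N
    ## validation
    expect_error(dustScore("AC"), "length")

    ## agreement with the independent brute-force counter on random input
    set.seed(404)
    seqs <- vapply(sample(15:40, 300, replace = TRUE), function(L)
        paste(sample(c("A", "C", "G", "T", "N"), L, replace = TRUE,
                     prob = c(.24, .24, .24, .24, .04)), collapse = ""),
        character(1))
    expect_equal(dustScore(seqs), vapply(seqs, oracleDust, numeric(1),
                                         USE.NAMES = FALSE))
})

test_that("filterLowComplexity removes above-threshold reads in order", {
    rd <- data.table::data.table(
        sample_id = "s1", chrom = "chr1",
        start = c(1L, 100L, 200L), end = c(30L, 129L, 229L),
        strand = "*",
        sequence = c(strrep("A", 30),                       # score 14
                     "GTTGCTAAAGCCCGGGAGTCGCATTATGAA",      # score 0
                     substr(strrep("GT", 16), 1, 30)),      # dinucleotide
        weight = 1L)
    out <- filterLowComplexity(rd, threshold = 3)
    expect_equal(out$start, 100L)
    expect_equal(attr(out, "removed"), 2L)
    ## infinite threshold is the identity
    all <- filterLowComplexity(rd, threshold = Inf)
    expect_equal(nrow(all), 3L)
    ## missing sequences are an error when filtering
    rd2 <- data.table::copy(rd)
    rd2$sequence[2] <- NA
    expect_error(filterLowComplexity(rd2), "sequence")
})

test_that("mergeLoci collapses overlapping and book-ended reads", {
    rd <- data.table::data.table(
        sample_id = "s", chrom = "chr1",
        start = c(101L, 121L, 301L), end = c(130L, 150L, 330L),
        strand = "*", sequence = NA_character_, weight = 1L)
    m <- mergeLoci(rd)
    expect_equal(GenomicRanges::start(m), c(101L, 301L))
    expect_equal(GenomicRanges::end(m), c(150L, 330L))
    ## book-ended (gap 0 in half-open terms): [100,120) + [120,140) merge
    rd2 <- data.table::data.table(
        sample_id = "s", chrom = "chr1",
        start = c(101L, 121L), end = c(120L, 140L),
        strand = "*", sequence = NA_character_, weight = 1L)
    m2 <- mergeLoci(rd2)
    expect_equal(length(m2), 1L)
    expect_equal(GenomicRanges::start(m2), 101L)
    expect_equal(GenomicRanges::end(m2), 140L)
    ## a single read merges to itself
    m3 <- mergeLoci(rd2[1])
    expect_equal(GenomicRanges::width(m3), 20L)

    ## idempotence on a simulated read pool (before splitting: split
    ## sub-loci are intentionally book-ended at peak midpoints)
    sc <- smallCohort()
    m4 <- sc$merged
    again <- GenomicRanges::reduce(m4)
    expect_equal(length(again), length(m4))
    expect_true(all(GenomicRanges::width(m4) ==
                        GenomicRanges::width(GenomicRanges::sort(again))))
    ## merged loci are pairwise disjoint
    expect_false(any(GenomicRanges::countOverlaps(m4, m4) > 1L))
})

test_that("aggregateCoverage clips reads and sums weights per base", {
    locus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 130))
    mk <- function(starts, ends, w = 1L) data.table::data.table(
        sample_id = "s", chrom = "chr1", start = starts, end = ends,
        strand = "*", sequence = NA_character_, weight = w)
    ## one read spanning the whole locus
    expect_equal(aggregateCoverage(locus, mk(101L, 130L))$depth, rep(1L, 30))
    ## no reads
    expect_equal(aggregateCoverage(locus, mk(integer(0), integer(0)))$depth,
                 rep(0L, 30))
    ## two identical reads
    expect_equal(aggregateCoverage(locus, mk(c(101L, 101L),
                                             c(130L, 130L)))$depth,
                 rep(2L, 30))
    ## weights count, partial overlap clipped
    prof <- aggregateCoverage(locus, mk(91L, 110L, w = 3L))
    expect_equal(prof$depth, c(rep(3L, 10), rep(0L, 20)))
})

test_that("findCoveragePeaks implements height, distance and width rules", {
    ## rectangular bump of height 20 over positions 51..80 in a 400-bp locus
    depth <- rep(0, 400); depth[51:80] <- 20
    pk <- findCoveragePeaks(depth)
    expect_equal(nrow(pk), 1L)
    expect_lte(pk$left, 51)
    expect_gte(pk$right, 80)
    expect_equal(pk$height, 20)
    ## flat sub-threshold profile: no peaks
    expect_equal(nrow(findCoveragePeaks(rep(5, 400))), 0L)
    ## two bumps 200 bp apart: two peaks
    d2 <- rep(0, 400); d2[51:80] <- 20; d2[251:280] <- 25
    expect_equal(nrow(findCoveragePeaks(d2)), 2L)
    ## distance pruning keeps the higher of two close maxima
    d3 <- rep(0, 100); d3[31:40] <- 12; d3[45:54] <- 18
    pk3 <- findCoveragePeaks(d3, widthRange = c(5, 200), distance = 20)
    expect_equal(nrow(pk3), 1L)
    expect_equal(pk3$height, 18)
    ## width window: a 5-bp spike is rejected at widthRange [15, 200]
    d4 <- rep(0, 100); d4[48:52] <- 30
    expect_equal(nrow(findCoveragePeaks(d4)), 0L)
    expect_error(findCoveragePeaks(d4, widthRange = c(200, 15)), "ordered")
})

test_that("splitLocus keeps short loci, splits long ones, discards peakless", {
    ## 150-bp locus passes through unchanged
    short <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 150))
    expect_identical(splitLocus(short, rep(50, 150)), short)
    ## 400-bp locus with two planted bumps -> exactly 2 disjoint sub-loci
    long <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1400))
    depth <- rep(0, 400); depth[51:80] <- 20; depth[251:280] <- 20
    sub <- splitLocus(long, depth)
    expect_equal(length(sub), 2L)
    expect_false(any(GenomicRanges::countOverlaps(sub, sub) > 1L))
    w <- GenomicRanges::width(sub)
    expect_true(all(w >= 15 & w <= 200))
    ## contained in the parent
    expect_true(all(GenomicRanges::start(sub) >= 1001 &
                        GenomicRanges::end(sub) <= 1400))
    ## long locus with max depth 5: discarded...
    expect_equal(length(splitLocus(long, rep(5, 400))), 0L)
    ## ...unless configured to keep unsplit long loci
    expect_identical(splitLocus(long, rep(5, 400), keepUnsplit = TRUE), long)
})

test_that("presence matrices binarize >= 1 bp overlaps per sample", {
    loci <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(101, 201), c(130, 230)))
    names(loci) <- c("L1", "L2")
    rd <- data.table::data.table(
        sample_id = c("s1", "s1", "s2"),
        chrom = "chr1",
        start = c(130L, 400L, 120L), end = c(159L, 429L, 210L),
        strand = "*", sequence = NA_character_, weight = c(1L, 1L, 2L))
    mf <- data.frame(sample_id = c("s1", "s2"), role = "tumor",
                     tissue = "t", library_size = c(10L, 20L))
    pm <- buildPresenceMatrix(loci, rd, mf)
    ## s1's first read overlaps L1 by exactly 1 bp -> present
    expect_equal(unname(counts(pm)["L1", "s1"]), 1L)
    expect_equal(unname(presence(pm)["L1", "s1"]), 1L)
    ## no overlap -> absent
    expect_equal(unname(presence(pm)["L2", "s1"]), 0L)
    ## s2's weighted read spans both loci -> counted once per locus
    expect_equal(unname(counts(pm)[, "s2"]), c(2L, 2L))
    ## presence <-> counts invariant over a simulated cohort
    big <- smallCohort()$pm
    expect_true(all((counts(big) >= 1L) == (presence(big) == 1L)))
    ## unknown sample is an error
    rd2 <- data.table::copy(rd); rd2$sample_id[1] <- "ghost"
    expect_error(buildPresenceMatrix(loci, rd2, mf), "ghost")
})

test_that("countsPerMillion applies the library-size scaling law", {
    loci <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 30))
    names(loci) <- "L1"
    cnt <- matrix(c(5L, 5L), 1, dimnames = list("L1", c("a", "b")))
    pm <- PresenceMatrix(cnt, loci, S4Vectors::DataFrame(
        sample_id = c("a", "b"), role = "tumor", tissue = "t",
        library_size = c(1e6L, 2e6L), row.names = c("a", "b")))
    cpm <- countsPerMillion(pm)
    expect_equal(unname(cpm["L1", "a"]), 5)
    ## doubling the library size halves the cpm
    expect_equal(unname(cpm["L1", "b"]), 2.5)
    expect_equal(unname(cpm["L1", "a"] * 0), 0)
})

test_that("decoy reads are fully removed and planted reads survive", {
    co <- smallCohort()$cohort
    filt <- smallCohort()$reads
    ## every homopolymer/dinucleotide decoy is gone at threshold 3
    expect_equal(sum(filt$chrom == "chrDecoy"), 0L)
    ## at least 99% of planted-locus reads survive
    planted <- co$reads[co$reads$chrom != "chrDecoy"]
    expect_gte(nrow(filt) / nrow(planted), 0.99)
})
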