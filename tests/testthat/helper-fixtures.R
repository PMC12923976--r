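## Shared fixtures, built once per test run and cached. The default cohort
## (the study conditions: 4 tissues x 60 tumors + 15 normals, 200 atlas
## samples, 30 sera, 300 planted oncRNAs at prevalence 0.30, 400 background
## loci at 0.90, 50 contaminants, 100 annotation-overlap loci) takes about a
## minute to generate and process, so the tests that need it share one copy.

.fixtures <- new.env(parent = emptyenv())

smallConfig <- function(seed = 11L) {
    simulationConfig(nTissues = 2L, tumorsPerTissue = 12L,
                     normalsPerTissue = 10L, nBiofluid = 30L,
                     nSerumNoncancer = 8L, nTrueOncPerTissue = 15L,
                     nBackgroundLoci = 30L, nContaminantLoci = 8L,
                     nAnnotatedLoci = 8L, seed = seed)
}

smallCohort <- function() {
    if (is.null(.fixtures$small)) {
        co <- simulateCohort(smallConfig())
        fr <- filterLowComplexity(co$reads)
        disc <- fr[fr$sample_id %in%
                       co$manifest$sample_id[co$manifest$role %in%
                                                 c("tumor", "normal")]]
        merged <- mergeLoci(disc)
        loci <- splitLongLoci(merged, disc)
        pm <- buildPresenceMatrix(loci, fr, co$manifest)
        .fixtures$small <- list(cohort = co, reads = fr, merged = merged,
                                loci = loci, pm = pm)
    }
    .fixtures$small
}

defaultCohort <- function() {
    if (is.null(.fixtures$default)) {
        co <- simulateCohort(simulationConfig())
        fr <- filterLowComplexity(co$reads)
        disc <- fr[fr$sample_id %in%
                       co$manifest$sample_id[co$manifest$role %in%
                                                 c("tumor", "normal")]]
        loci <- splitLongLoci(mergeLoci(disc), disc)
        pm <- buildPresenceMatrix(loci, fr, co$manifest)
        catalog <- runCascade(pm, co$annotations)
        .fixtures$default <- list(cohort = co, reads = fr, loci = loci,
                                  pm = pm, catalog = catalog)
    }
    .fixtures$default
}

truthGRanges <- function(cohort, label = "true_onc") {
    tr <- as.data.frame(cohort$truth)
    tr <- tr[tr$label == label, , drop = FALSE]
    gr <- GenomicRanges::GRanges(tr$chrom,
                                 IRanges::IRanges(tr$start, tr$end))
    names(gr) <- tr$locus_id
    gr
}

## Presence matrix assembled directly from a binary matrix (for filter and
## stage tests that do not need reads)
pmFromPresence <- function(pres, roles, tissues = NULL,
                           librarySize = 1e6L) {
    n <- ncol(pres)
    gr <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges((seq_len(nrow(pres)) - 1L) * 100L + 1L, width = 30L))
    names(gr) <- rownames(pres) <- rownames(pres) %||%
        paste0("locus_", seq_len(nrow(pres)))
    if (is.null(tissues)) tissues <- rep("tissueA", n)
    ids <- sprintf("s%03d", seq_len(n))
    colnames(pres) <- ids
    PresenceMatrix(pres, gr, S4Vectors::DataFrame(
        sample_id = ids, role = roles, tissue = tissues,
        library_size = rep(as.integer(librarySize), n), row.names = ids))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
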