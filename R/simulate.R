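#' @importFrom data.table data.table as.data.table rbindlist setattr :=
NULL

.TISSUE_NAMES <- c("breast", "lung", "colorectal", "prostate", "pancreas",
                   "kidney", "liver", "ovary")

#' Synthetic cohort configuration
#'
#' Bundles and validates the parameters of \code{\link{simulateCohort}}.
#' The defaults describe the study conditions the rest of the package is
#' exercised under: 4 tumor tissues with 60 tumors and 15 tumor-adjacent
#' normals each, a 200-sample non-cancerous biofluid atlas, 30 non-cancerous
#' sera, 75 planted tissue-specific oncRNA loci per tissue at within-tissue
#' prevalence 0.30, 400 ubiquitous background loci at prevalence 0.90 in
#' tumors and normals, 50 biofluid contaminant loci, 100 annotation-overlap
#' loci, 5\% low-complexity decoy reads, and negative-binomial read counts
#' (mean 10, dispersion 1) for present loci. A fraction of true loci are
#' embedded as narrow coverage peaks inside >200 bp parent spans so the
#' peak-splitting stage is exercised.
#'
#' @param nTissues number of tumor tissue types.
#' @param tumorsPerTissue,normalsPerTissue cohort sizes per tissue.
#' @param nBiofluid,nSerumNoncancer biofluid-atlas and non-cancer serum
#'   cohort sizes.
#' @param nTrueOncPerTissue planted tissue-specific oncRNA loci per tissue.
#' @param oncPrevalence within-cognate-tissue tumor prevalence of true loci.
#' @param nBackgroundLoci,backgroundPrevalence ubiquitous small-RNA loci
#'   present in tumors and normals alike.
#' @param nContaminantLoci,contaminantAtlasPrevalence biofluid contaminant
#'   loci and their prevalence in atlas (and serum) samples; such loci are
#'   also expressed across tumors (at \code{contaminantTumorPrevalence}),
#'   which is exactly why the atlas filter is needed to weed them out.
#' @param contaminantTumorPrevalence pan-tumor prevalence of contaminant
#'   loci.
#' @param nAnnotatedLoci,annotatedPrevalence tumor-expressed loci that
#'   coincide with the known-annotation track.
#' @param fracLowComplexityReads fraction of each sample's reads that are
#'   homopolymer/dinucleotide-repeat decoys placed outside all planted loci.
#' @param readsMean,readsDispersion negative-binomial law of reads per
#'   present locus (counts are floored at 1).
#' @param locusLengthRange planted locus lengths, in nt (small-RNA regime).
#' @param longLocusFraction fraction of true loci embedded as peaks inside
#'   long parent spans.
#' @param seed global integer seed; per-sample substreams are derived by a
#'   stable hash of the sample identifier, so resizing the cohort does not
#'   perturb the reads of retained samples.
#' @return a validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(nTissues = 4L, tumorsPerTissue = 60L,
                             normalsPerTissue = 15L, nBiofluid = 200L,
                             nSerumNoncancer = 30L, nTrueOncPerTissue = 75L,
                             oncPrevalence = 0.30, nBackgroundLoci = 400L,
                             backgroundPrevalence = 0.90,
                             nContaminantLoci = 50L,
                             contaminantAtlasPrevalence = 0.10,
                             contaminantTumorPrevalence = 0.30,
                             nAnnotatedLoci = 100L,
                             annotatedPrevalence = 0.30,
                             fracLowComplexityReads = 0.05,
                             readsMean = 10, readsDispersion = 1,
                             locusLengthRange = c(15L, 38L),
                             longLocusFraction = 0.20, seed = 1L) {
    cfg <- list(
        nTissues = .checkCount(nTissues, "nTissues", positive = TRUE),
        tumorsPerTissue = .checkCount(tumorsPerTissue, "tumorsPerTissue",
                                      positive = TRUE),
        normalsPerTissue = .checkCount(normalsPerTissue, "normalsPerTissue",
                                       positive = TRUE),
        nBiofluid = .checkCount(nBiofluid, "nBiofluid", positive = TRUE),
        nSerumNoncancer = .checkCount(nSerumNoncancer, "nSerumNoncancer",
                                      positive = TRUE),
        nTrueOncPerTissue = .checkCount(nTrueOncPerTissue,
                                        "nTrueOncPerTissue"),
        oncPrevalence = .checkProb(oncPrevalence, "oncPrevalence"),
        nBackgroundLoci = .checkCount(nBackgroundLoci, "nBackgroundLoci"),
        backgroundPrevalence = .checkProb(backgroundPrevalence,
                                          "backgroundPrevalence"),
        nContaminantLoci = .checkCount(nContaminantLoci, "nContaminantLoci"),
        contaminantAtlasPrevalence = .checkProb(contaminantAtlasPrevalence,
                                                "contaminantAtlasPrevalence"),
        contaminantTumorPrevalence = .checkProb(contaminantTumorPrevalence,
                                                "contaminantTumorPrevalence"),
        nAnnotatedLoci = .checkCount(nAnnotatedLoci, "nAnnotatedLoci"),
        annotatedPrevalence = .checkProb(annotatedPrevalence,
                                         "annotatedPrevalence"),
        fracLowComplexityReads = .checkProb(fracLowComplexityReads,
                                            "fracLowComplexityReads"),
        readsMean = readsMean, readsDispersion = readsDispersion,
        locusLengthRange = as.integer(locusLengthRange),
        longLocusFraction = .checkProb(longLocusFraction,
                                       "longLocusFraction"),
        seed = .checkCount(seed, "seed"))
    if (length(cfg$locusLengthRange) != 2L ||
        cfg$locusLengthRange[1L] < 3L ||
        cfg$locusLengthRange[1L] > cfg$locusLengthRange[2L])
        .stopf("'locusLengthRange' must be an ordered pair of lengths >= 3")
    if (readsMean <= 0 || readsDispersion <= 0)
        .stopf("'readsMean' and 'readsDispersion' must be positive")
    structure(cfg, class = "SimulationConfig")
}

.BASES <- c("A", "C", "G", "T")

## Random nucleotide sequences, grouped by length for vectorized paste
.randSeqs <- function(lens) {
    out <- character(length(lens))
    for (L in unique(lens)) {
        idx <- which(lens == L)
        m <- matrix(sample(.BASES, length(idx) * L, replace = TRUE),
                    ncol = L)
        out[idx] <- do.call(paste0, as.data.frame(m))
    }
    out
}

## Low-complexity decoy sequences: half homopolymers, half dinucleotide
## repeats (both far above the DUST removal threshold at small-RNA lengths)
.decoySeqs <- function(lens) {
    n <- length(lens)
    homo <- seq_len(n) %% 2L == 1L
    out <- character(n)
    b1 <- sample(.BASES, n, replace = TRUE)
    off <- sample(3L, n, replace = TRUE)
    b2 <- .BASES[(match(b1, .BASES) + off - 1L) %% 4L + 1L]
    out[homo] <- strrep(b1[homo], lens[homo])
    di <- !homo
    out[di] <- substr(strrep(paste0(b1[di], b2[di]),
                             ceiling(lens[di] / 2) + 1L), 1L, lens[di])
    out
}

## Deterministic locus layout: every planted locus gets its own 1-kb slot
## on a synthetic chromosome; long-embedded true loci sit as peaks inside a
## 400-bp parent span within the slot.
.layoutLoci <- function(cfg) {
    tissues <- if (cfg$nTissues <= length(.TISSUE_NAMES))
        .TISSUE_NAMES[seq_len(cfg$nTissues)]
    else paste0("tissue", seq_len(cfg$nTissues))
    ids <- c(
        if (cfg$nTrueOncPerTissue > 0)
            paste0("onc_", rep(tissues, each = cfg$nTrueOncPerTissue), "_",
                   seq_len(cfg$nTrueOncPerTissue)),
        if (cfg$nBackgroundLoci > 0)
            paste0("bg_", seq_len(cfg$nBackgroundLoci)),
        if (cfg$nContaminantLoci > 0)
            paste0("cont_", seq_len(cfg$nContaminantLoci)),
        if (cfg$nAnnotatedLoci > 0)
            paste0("ann_", seq_len(cfg$nAnnotatedLoci)))
    labels <- c(
        rep("true_onc", cfg$nTissues * cfg$nTrueOncPerTissue),
        rep("background", cfg$nBackgroundLoci),
        rep("contaminant", cfg$nContaminantLoci),
        rep("annotation_overlap", cfg$nAnnotatedLoci))
    tissue <- c(rep(tissues, each = cfg$nTrueOncPerTissue),
                rep(NA_character_,
                    cfg$nBackgroundLoci + cfg$nContaminantLoci +
                        cfg$nAnnotatedLoci))
    n <- length(ids)
    lens <- sample(seq(cfg$locusLengthRange[1L], cfg$locusLengthRange[2L]),
                   n, replace = TRUE)
    slotStart <- (seq_len(n) - 1L) * 1000L + 1L
    nTrue <- cfg$nTissues * cfg$nTrueOncPerTissue
    embedded <- rep(FALSE, n)
    if (nTrue > 0 && cfg$longLocusFraction > 0) {
        nEmb <- round(cfg$longLocusFraction * nTrue)
        embedded[seq_len(nTrue)] <- seq_len(nTrue) %in%
            sample(nTrue, nEmb)
    }
    parentStart <- ifelse(embedded, slotStart + 200L, NA_integer_)
    parentEnd <- ifelse(embedded, slotStart + 599L, NA_integer_)
    start <- ifelse(embedded,
                    slotStart + 400L - lens %/% 2L,  # peak near parent center
                    slotStart + 400L)
    dt <- data.table(
        locus_id = ids, label = labels, tissue = tissue,
        chrom = "chrS", start = as.integer(start),
        end = as.integer(start + lens - 1L), length = lens,
        embedded = embedded,
        parent_start = as.integer(parentStart),
        parent_end = as.integer(parentEnd))
    dt
}

## Planted per-cohort prevalence of a locus table for one sample role/tissue
.plantedPrev <- function(layout, cfg, role, tissue) {
    prev <- numeric(nrow(layout))
    if (role == "tumor") {
        prev[layout$label == "true_onc" &
                 layout$tissue == tissue] <- cfg$oncPrevalence
        prev[layout$label == "background"] <- cfg$backgroundPrevalence
        prev[layout$label == "annotation_overlap"] <- cfg$annotatedPrevalence
        prev[layout$label == "contaminant"] <- cfg$contaminantTumorPrevalence
    } else if (role == "normal") {
        prev[layout$label == "background"] <- cfg$backgroundPrevalence
    } else if (role %in% c("biofluid", "serum")) {
        prev[layout$label == "contaminant"] <- cfg$contaminantAtlasPrevalence
    }
    prev
}

## Emit the reads of one sample (called inside its own RNG substream).
## smearIdx: indices (within the tissue's tumor cohort) of the tiling reads
## this sample contributes to long parent spans.
.sampleReads <- function(sampleId, layout, prev, cfg, smear = NULL) {
    present <- which(runif(nrow(layout)) < prev)
    parts <- list()
    if (length(present)) {
        nReads <- pmax(1L, rnbinom(length(present), mu = cfg$readsMean,
                                   size = cfg$readsDispersion))
        li <- rep.int(present, nReads)
        jit <- sample(-2:2, length(li), replace = TRUE)
        st <- pmax(1L, layout$start[li] + jit)
        parts$main <- data.table(
            chrom = layout$chrom[li], start = as.integer(st),
            end = as.integer(st + layout$length[li] - 1L))
    }
    if (!is.null(smear) && nrow(smear)) {
        parts$smear <- data.table(chrom = smear$chrom, start = smear$start,
                                  end = smear$end)
    }
    reads <- rbindlist(parts)
    nReal <- nrow(reads)
    if (nReal) {
        reads[, sequence := .randSeqs(end - start + 1L)]
    } else {
        reads <- data.table(chrom = character(0), start = integer(0),
                            end = integer(0), sequence = character(0))
    }
    f <- cfg$fracLowComplexityReads
    if (f > 0 && nReal > 0) {
        nDecoy <- round(nReal * f / (1 - f))
        if (nDecoy > 0) {
            ## a dinucleotide repeat shorter than 18 nt can sit at or below
            ## the DUST removal threshold; decoys are meant to exceed it
            dl <- sample(seq(max(18L, cfg$locusLengthRange[1L]),
                             max(18L, cfg$locusLengthRange[2L])),
                         nDecoy, replace = TRUE)
            ds <- sample.int(1000000L, nDecoy, replace = TRUE)
            reads <- rbindlist(list(reads, data.table(
                chrom = "chrDecoy", start = ds,
                end = as.integer(ds + dl - 1L),
                sequence = .decoySeqs(dl))))
        }
    }
    if (nrow(reads) == 0L) return(.emptyReads())
    data.table(sample_id = sampleId, chrom = reads$chrom,
               start = reads$start, end = reads$end, strand = "*",
               sequence = reads$sequence, weight = 1L)
}

## Tiling reads across each long parent span, assigned cyclically to the
## tumor samples of the cognate tissue so the merged locus spans the parent
## while pooled smear depth stays far below the peak-calling height.
.smearTable <- function(layout) {
    emb <- layout[layout$embedded == TRUE]
    if (nrow(emb) == 0L) return(NULL)
    parts <- lapply(seq_len(nrow(emb)), function(i) {
        starts <- seq(emb$parent_start[i], emb$parent_end[i] - 39L, by = 30L)
        data.table(tissue = emb$tissue[i], chrom = emb$chrom[i],
                   start = as.integer(starts),
                   end = as.integer(starts + 39L))
    })
    rbindlist(parts)
}

#' Simulate a seeded synthetic discovery cohort with planted ground truth
#'
#' Generates aligned small-RNA reads, a sample manifest, a known-annotation
#' track and a planted-truth table for a multi-tissue tumor/normal cohort
#' plus a biofluid atlas and non-cancerous sera. Presence of each planted
#' locus in each sample is drawn independently at the cohort-specific
#' prevalence; present loci emit at least one read within (a +/-2 nt jitter
#' of) the locus span; a fraction of true loci are embedded as narrow
#' coverage peaks inside >200 bp parent spans that low-depth tiling reads
#' hold together; decoy reads are homopolymer/dinucleotide repeats placed
#' on a separate decoy chromosome. The same seed reproduces the cohort
#' exactly.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return a list of class \code{SyntheticCohort} with elements
#'   \code{reads} (pooled read table), \code{manifest} (data.frame),
#'   \code{annotations} (\code{GRanges} of known-annotation spans),
#'   \code{truth} (per-locus \code{data.table}: \code{locus_id},
#'   \code{label}, \code{tissue}, coordinates, embedding) and \code{config}.
#' @export
simulateCohort <- function(config = simulationConfig()) {
    stopifnot(inherits(config, "SimulationConfig"))
    cfg <- config
    layout <- .withSeed(cfg$seed, .layoutLoci(cfg))
    tissues <- unique(stats::na.omit(layout$tissue))
    if (!length(tissues))
        tissues <- if (cfg$nTissues <= length(.TISSUE_NAMES))
            .TISSUE_NAMES[seq_len(cfg$nTissues)]
        else paste0("tissue", seq_len(cfg$nTissues))
    smear <- .smearTable(layout)

    manifest <- list()
    readParts <- list()
    subtypes <- c("subA", "subB", "subC")
    for (t in tissues) {
        for (i in seq_len(cfg$tumorsPerTissue)) {
            sid <- sprintf("tumor_%s_%03d", t, i)
            sm <- NULL
            if (!is.null(smear)) {
                rows <- which(smear$tissue == t)
                sm <- smear[rows[(rows %% cfg$tumorsPerTissue) + 1L == i]]
            }
            prev <- .plantedPrev(layout, cfg, "tumor", t)
            rd <- .withSeed(.sampleSeed(cfg$seed, sid), {
                sub <- sample(subtypes, 1L)
                r <- .sampleReads(sid, layout, prev, cfg, smear = sm)
                list(reads = r, subtype = sub)
            })
            readParts[[sid]] <- rd$reads
            manifest[[sid]] <- data.frame(
                sample_id = sid, role = "tumor", tissue = t,
                subtype = rd$subtype, timepoint = NA_character_,
                library_size = nrow(rd$reads),
                survival_time = NA_real_, event = NA_integer_)
        }
        for (i in seq_len(cfg$normalsPerTissue)) {
            sid <- sprintf("normal_%s_%03d", t, i)
            prev <- .plantedPrev(layout, cfg, "normal", t)
            rd <- .withSeed(.sampleSeed(cfg$seed, sid),
                            .sampleReads(sid, layout, prev, cfg))
            readParts[[sid]] <- rd
            manifest[[sid]] <- data.frame(
                sample_id = sid, role = "normal", tissue = t,
                subtype = NA_character_, timepoint = NA_character_,
                library_size = nrow(rd),
                survival_time = NA_real_, event = NA_integer_)
        }
    }
    for (i in seq_len(cfg$nBiofluid)) {
        sid <- sprintf("atlas_%03d", i)
        prev <- .plantedPrev(layout, cfg, "biofluid", NA)
        rd <- .withSeed(.sampleSeed(cfg$seed, sid),
                        .sampleReads(sid, layout, prev, cfg))
        readParts[[sid]] <- rd
        manifest[[sid]] <- data.frame(
            sample_id = sid, role = "biofluid", tissue = "biofluid",
            subtype = NA_character_, timepoint = NA_character_,
            library_size = nrow(rd),
            survival_time = NA_real_, event = NA_integer_)
    }
    for (i in seq_len(cfg$nSerumNoncancer)) {
        sid <- sprintf("serum_%03d", i)
        prev <- .plantedPrev(layout, cfg, "serum", NA)
        rd <- .withSeed(.sampleSeed(cfg$seed, sid),
                        .sampleReads(sid, layout, prev, cfg))
        readParts[[sid]] <- rd
        manifest[[sid]] <- data.frame(
            sample_id = sid, role = "serum", tissue = "serum",
            subtype = NA_character_, timepoint = NA_character_,
            library_size = nrow(rd),
            survival_time = NA_real_, event = NA_integer_)
    }
    reads <- rbindlist(readParts)
    manifest <- do.call(rbind, manifest)
    rownames(manifest) <- NULL
    ## a present locus always emits >= 1 read, but a sample could in
    ## principle emit none at all; library sizes must stay positive
    manifest$library_size <- pmax(manifest$library_size, 1L)

    annRows <- layout[layout$label == "annotation_overlap"]
    annotations <- GenomicRanges::GRanges(
        annRows$chrom, IRanges::IRanges(annRows$start, annRows$end))
    names(annotations) <- annRows$locus_id

    structure(list(reads = reads, manifest = manifest,
                   annotations = annotations, truth = layout,
                   config = cfg),
              class = "SyntheticCohort")
}

#' @export
print.SyntheticCohort <- function(x, ...) {
    cat(sprintf(
        "SyntheticCohort: %d reads, %d samples, %d planted loci\n",
        nrow(x$reads), nrow(x$manifest), nrow(x$truth)))
    print(table(x$truth$label))
    invisible(x)
}

#' Write a synthetic cohort to disk in the pipeline's file formats
#'
#' One BED6+sequence file per sample under \code{dir/reads/}, a TSV
#' manifest, a BED annotation track and a TSV truth table.
#'
#' @param cohort a \code{SyntheticCohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    stopifnot(inherits(cohort, "SyntheticCohort"))
    readsDir <- file.path(dir, "reads")
    dir.create(readsDir, recursive = TRUE, showWarnings = FALSE)
    for (sid in unique(cohort$reads$sample_id)) {
        writeBedReads(cohort$reads[cohort$reads$sample_id == sid],
                      file.path(readsDir, paste0(sid, ".bed")))
    }
    writeSampleManifest(cohort$manifest, file.path(dir, "manifest.tsv"))
    ann <- cohort$annotations
    data.table::fwrite(data.table(
        chrom = as.character(GenomicRanges::seqnames(ann)),
        start = GenomicRanges::start(ann) - 1L,
        end = GenomicRanges::end(ann),
        name = names(ann), score = 0L, strand = "."),
        file.path(dir, "annotations.bed"), sep = "\t", col.names = FALSE)
    data.table::fwrite(cohort$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", na = "NA")
    invisible(dir)
}

#' Simulate a locus-by-sample chromatin accessibility matrix
#'
#' For a chosen fraction of "accessible" loci the accessibility score is
#' \code{baseline + effect * presence + N(0, noiseSd)}; for the remaining
#' null loci it is \code{baseline + N(0, noiseSd)} regardless of presence.
#' Scores are floored at 0.
#'
#' @param pm a \code{\linkS4class{PresenceMatrix}} giving the presence
#'   pattern (typically restricted to catalog loci and tumor samples).
#' @param effect additive accessibility shift in present samples of
#'   accessible loci (score units).
#' @param noiseSd Gaussian noise standard deviation (must be nonnegative).
#' @param accessibleFraction fraction of loci planted as accessible.
#' @param baseline baseline accessibility score.
#' @param seed integer seed.
#' @return a list with \code{scores} (numeric matrix, dimnames of
#'   \code{presence(pm)}) and \code{accessible} (named logical).
#' @export
simulateAccessibility <- function(pm, effect, noiseSd,
                                  accessibleFraction = 0.5, baseline = 5,
                                  seed = 1L) {
    stopifnot(is(pm, "PresenceMatrix"))
    if (!is.numeric(noiseSd) || length(noiseSd) != 1L || noiseSd < 0)
        .stopf("'noiseSd' must be a single nonnegative number")
    .checkProb(accessibleFraction, "accessibleFraction")
    prs <- assay(pm, "presence")
    .withSeed(seed, {
        nAcc <- round(accessibleFraction * nrow(prs))
        accessible <- setNames(rep(FALSE, nrow(prs)), rownames(prs))
        if (nAcc > 0)
            accessible[sample(nrow(prs), nAcc)] <- TRUE
        scores <- baseline +
            effect * prs * accessible +
            matrix(stats::rnorm(length(prs), sd = noiseSd), nrow(prs))
        scores <- pmax(scores, 0)
        dimnames(scores) <- dimnames(prs)
        list(scores = scores, accessible = accessible)
    })
}

#' Simulate paired serum timepoints with outcome-linked species burden
#'
#' Each patient contributes serum samples at T0 (pretreatment) and T3
#' (post-treatment): responders lose an exact fraction
#' \code{speciesLoss} of their detected oncRNA species at T3, non-responders
#' retain all of theirs and gain at least one. Survival times follow
#' exponential laws whose rate differs by \code{hazardRatio} between the
#' planted high-residual-burden (non-responder) and low-residual-burden
#' groups, with administrative censoring at \code{horizon}. Library sizes
#' are fixed so species counts and per-million burdens order identically.
#'
#' @param nPatients number of patients.
#' @param responderFraction fraction of patients planted as responders.
#' @param speciesLoss fraction of T0 species a responder loses at T3.
#' @param hazardRatio hazard ratio of the high-burden group (must be > 0).
#' @param nLoci size of the oncRNA catalog being assayed.
#' @param baselinePrevalence per-locus detection probability at T0.
#' @param gainRate per-absent-locus gain probability for non-responders.
#' @param baselineHazard exponential event rate (per year) of the low
#'   group.
#' @param horizon administrative censoring horizon (years).
#' @param librarySize fixed serum library size (reads).
#' @param seed integer seed.
#' @return a list of class \code{SerumCohort}: \code{reads},
#'   \code{manifest} (two rows per patient, with \code{patient_id},
#'   \code{timepoint}, \code{survival_time}, \code{event}), \code{loci}
#'   (\code{GRanges} of the assayed catalog) and \code{truth}
#'   (per-patient \code{data.table} with planted responder status, species
#'   counts and stratum).
#' @export
simulateSerumPairs <- function(nPatients, responderFraction = 0.5,
                               speciesLoss = 0.8, hazardRatio = 3,
                               nLoci = 300L, baselinePrevalence = 0.3,
                               gainRate = 0.05, baselineHazard = 0.15,
                               horizon = 8, librarySize = 1e6, seed = 1L) {
    nPatients <- .checkCount(nPatients, "nPatients", positive = TRUE)
    .checkProb(responderFraction, "responderFraction")
    .checkProb(speciesLoss, "speciesLoss")
    .checkProb(baselinePrevalence, "baselinePrevalence")
    .checkProb(gainRate, "gainRate")
    if (!is.numeric(hazardRatio) || length(hazardRatio) != 1L ||
        hazardRatio <= 0)
        .stopf("'hazardRatio' must be a single positive number")
    nLoci <- .checkCount(nLoci, "nLoci", positive = TRUE)

    .withSeed(seed, {
        lens <- sample(15:38, nLoci, replace = TRUE)
        starts <- (seq_len(nLoci) - 1L) * 500L + 101L
        loci <- GenomicRanges::GRanges(
            "chrSerum", IRanges::IRanges(starts, starts + lens - 1L))
        names(loci) <- paste0("locus_", seq_len(nLoci))
        nResp <- round(responderFraction * nPatients)
        responder <- seq_len(nPatients) %in% sample(nPatients, nResp)

        readParts <- list()
        manifest <- list()
        truth <- list()
        for (i in seq_len(nPatients)) {
            pid <- sprintf("patient_%03d", i)
            t0 <- which(runif(nLoci) < baselinePrevalence)
            if (!length(t0)) t0 <- sample(nLoci, 1L)
            if (responder[i]) {
                nKeep <- round((1 - speciesLoss) * length(t0))
                t3 <- if (nKeep > 0) sort(sample(t0, nKeep)) else integer(0)
            } else {
                absent <- setdiff(seq_len(nLoci), t0)
                nGain <- max(1L, rbinom(1L, length(absent), gainRate))
                nGain <- min(nGain, length(absent))
                t3 <- sort(c(t0, sample(absent, nGain)))
            }
            delta <- length(t3) - length(t0)
            stratum <- if (delta > 0) "high" else "low"
            rate <- baselineHazard * if (stratum == "high") hazardRatio else 1
            tt <- rexp(1L, rate = rate)
            ev <- as.integer(tt <= horizon)
            tt <- min(tt, horizon)
            for (tp in c("T0", "T3")) {
                sel <- if (tp == "T0") t0 else t3
                sid <- paste0(pid, "_", tp)
                if (length(sel)) {
                    readParts[[sid]] <- data.table(
                        sample_id = sid,
                        chrom = "chrSerum",
                        start = as.integer(starts[sel]),
                        end = as.integer(starts[sel] + lens[sel] - 1L),
                        strand = "*",
                        sequence = .randSeqs(lens[sel]),
                        weight = 1L)
                }
                manifest[[sid]] <- data.frame(
                    sample_id = sid, role = "serum", tissue = "breast",
                    subtype = NA_character_, timepoint = tp,
                    patient_id = pid,
                    library_size = librarySize,
                    survival_time = tt, event = ev)
            }
            truth[[pid]] <- data.table(
                patient_id = pid, responder = responder[i],
                n_t0 = length(t0), n_t3 = length(t3), delta = delta,
                stratum = stratum, time = tt, event = ev)
        }
        reads <- rbindlist(readParts)
        manifest <- do.call(rbind, manifest)
        rownames(manifest) <- NULL
        structure(list(reads = reads, manifest = manifest, loci = loci,
                       truth = rbindlist(truth)),
                  class = "SerumCohort")
    })
}

#' Simulate two survival arms with a planted hazard ratio
#'
#' The survival-time generator behind \code{\link{simulateSerumPairs}},
#' exposed directly for power and type-I-error calibration of the log-rank
#' test: exponential event times with rate \code{baselineHazard} in arm B
#' and \code{baselineHazard * hazardRatio} in arm A, administratively
#' censored at \code{horizon}.
#'
#' @param nA,nB arm sizes.
#' @param hazardRatio hazard ratio of arm A relative to arm B.
#' @param baselineHazard event rate (per year) of arm B.
#' @param horizon administrative censoring horizon (years).
#' @param seed integer seed.
#' @return a \code{data.frame} with \code{time}, \code{event},
#'   \code{group}.
#' @export
simulateSurvivalArms <- function(nA, nB, hazardRatio, baselineHazard = 0.15,
                                 horizon = 8, seed = 1L) {
    nA <- .checkCount(nA, "nA", positive = TRUE)
    nB <- .checkCount(nB, "nB", positive = TRUE)
    if (hazardRatio <= 0) .stopf("'hazardRatio' must be positive")
    .withSeed(seed, {
        tA <- rexp(nA, baselineHazard * hazardRatio)
        tB <- rexp(nB, baselineHazard)
        tt <- c(tA, tB)
        data.frame(time = pmin(tt, horizon),
                   event = as.integer(tt <= horizon),
                   group = rep(c("A", "B"), c(nA, nB)))
    })
}
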