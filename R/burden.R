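#' Circulating oncRNA burden of a sample
#'
#' The number of distinct oncRNA species detected in the sample (presence
#' over the catalog loci), normalized per million sequenced reads:
#' \code{species * 1e6 / librarySize}. A read-count mode (total oncRNA read
#' CPM rather than species CPM) is available.
#'
#' @param presence binary presence vector over the catalog loci for one
#'   sample, or a presence matrix (loci x samples).
#' @param librarySize positive library size(s); recycled across samples
#'   for a matrix input.
#' @param counts optional raw count vector/matrix; required for
#'   \code{mode = "reads"}.
#' @param mode \code{"species"} (default, distinct detected loci) or
#'   \code{"reads"} (total read counts).
#' @return nonnegative burden value(s), one per sample.
#' @examples
#' oncRNABurden(c(1, 1, 0, 1), librarySize = 1e6)  # 3 species per million
#' @export
oncRNABurden <- function(presence, librarySize, counts = NULL,
                         mode = c("species", "reads")) {
    mode <- match.arg(mode)
    if (any(librarySize <= 0) || anyNA(librarySize))
        .stopf("'librarySize' must be positive")
    num <- if (mode == "species") {
        if (is.matrix(presence)) colSums(presence != 0) else
            sum(presence != 0)
    } else {
        if (is.null(counts))
            .stopf("read-count mode requires 'counts'")
        if (is.matrix(counts)) colSums(counts) else sum(counts)
    }
    num * 1e6 / librarySize
}

#' Residual oncRNA burden across two serum timepoints
#'
#' \code{delta = N_T3 - N_T0}: the change in circulating oncRNA burden over
#' the bracketing timepoints (negative under treatment response).
#'
#' @param nT0,nT3 burden at pretreatment (T0) and post-treatment (T3).
#' @return \code{nT3 - nT0}.
#' @export
deltaBurden <- function(nT0, nT3) {
    if (anyNA(nT0) || anyNA(nT3))
        .stopf("both timepoints must be defined")
    nT3 - nT0
}

#' Stratify patients by residual burden
#'
#' \code{stratum = "high"} when \code{delta > tau}, else \code{"low"}
#' (default threshold 0).
#'
#' @param delta residual burden value(s).
#' @param tau stratification threshold (default 0).
#' @return character vector of strata.
#' @export
stratifyBurden <- function(delta, tau = 0) {
    ifelse(delta > tau, "high", "low")
}

#' Per-patient burden records from a serum presence matrix
#'
#' Pairs the T0 and T3 columns of each patient (via the \code{patient_id}
#' and \code{timepoint} columns of the matrix's sample data), computes the
#' species burden at both timepoints, the residual burden and the stratum.
#'
#' @param pm a \code{\linkS4class{PresenceMatrix}} over serum samples whose
#'   \code{colData} carries \code{patient_id} and \code{timepoint}
#'   (\code{"T0"}/\code{"T3"}).
#' @param tau stratification threshold on the residual burden.
#' @return a \code{data.frame}: \code{patient_id}, \code{n_t0},
#'   \code{n_t3}, \code{delta}, \code{stratum}, plus \code{survival_time}
#'   and \code{event} when present in the sample data.
#' @export
burdenTable <- function(pm, tau = 0) {
    stopifnot(is(pm, "PresenceMatrix"))
    cd <- as.data.frame(colData(pm))
    if (is.null(cd$patient_id) || is.null(cd$timepoint))
        .stopf("colData must carry 'patient_id' and 'timepoint'")
    burdens <- oncRNABurden(assay(pm, "presence"), librarySizes(pm))
    pats <- unique(cd$patient_id)
    rows <- lapply(pats, function(p) {
        i0 <- which(cd$patient_id == p & cd$timepoint == "T0")
        i3 <- which(cd$patient_id == p & cd$timepoint == "T3")
        if (length(i0) != 1L || length(i3) != 1L)
            .stopf("patient %s lacks a unique T0/T3 pair", p)
        d <- deltaBurden(burdens[i0], burdens[i3])
        out <- data.frame(patient_id = p, n_t0 = burdens[i0],
                          n_t3 = burdens[i3], delta = d,
                          stratum = stratifyBurden(d, tau),
                          stringsAsFactors = FALSE)
        if (!is.null(cd$survival_time)) {
            out$survival_time <- cd$survival_time[i0]
            out$event <- cd$event[i0]
        }
        out
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Kaplan-Meier product-limit estimate
#'
#' Product-limit survival curve(s), computed with the survival package:
#' S(0) = 1, non-increasing, right-continuous; censored times reduce the
#' risk set without creating steps.
#'
#' @param time positive follow-up times.
#' @param event event indicator (1 = event, 0 = censored).
#' @param group optional stratum label per record.
#' @return a \code{data.frame} of the step function: \code{time},
#'   \code{n_risk}, \code{n_event}, \code{survival} and (when grouped)
#'   \code{group}.
#' @export
kmEstimate <- function(time, event, group = NULL) {
    if (!length(time)) .stopf("at least one record is required")
    if (any(is.na(time)) || any(time <= 0))
        .stopf("survival times must be positive")
    if (length(event) != length(time) || !all(event %in% c(0, 1)))
        .stopf("'event' must be 0/1, one per record")
    if (is.null(group)) {
        fit <- survival::survfit(survival::Surv(time, event) ~ 1)
        data.frame(time = fit$time, n_risk = fit$n.risk,
                   n_event = fit$n.event, survival = fit$surv)
    } else {
        fit <- survival::survfit(survival::Surv(time, event) ~ group)
        strata <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
        data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
                   n_event = fit$n.event, survival = fit$surv)
    }
}

#' Two-group log-rank test
#'
#' Compares the survival curves of two groups via the standard log-rank
#' statistic: at each distinct event time, observed minus expected events
#' in group A under hypergeometric sampling from the pooled risk set;
#' chi-square on 1 df. Computed with \code{survival::survdiff}.
#'
#' @param timeA,eventA follow-up and event indicator of group A.
#' @param timeB,eventB follow-up and event indicator of group B.
#' @return a list with \code{chi_square}, \code{p_value}, \code{n}.
#' @export
logrankTest <- function(timeA, eventA, timeB, eventB) {
    if (any(c(timeA, timeB) <= 0) || anyNA(c(timeA, timeB)))
        .stopf("survival times must be positive")
    if (sum(eventA) + sum(eventB) == 0)
        .stopf("log-rank test is undefined without any event")
    time <- c(timeA, timeB)
    event <- c(eventA, eventB)
    group <- rep(c("A", "B"), c(length(timeA), length(timeB)))
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    chisq <- unname(sd$chisq)
    list(chi_square = chisq,
         p_value = pchisq(chisq, df = 1L, lower.tail = FALSE),
         n = length(time))
}

#' Sensitivity of burden stratification to the threshold
#'
#' Re-runs the high/low split and the log-rank test over a grid of
#' thresholds, mirroring the robustness check one performs before fixing
#' tau.
#'
#' @param records a \code{data.frame} with \code{delta},
#'   \code{survival_time}, \code{event} (as from \code{\link{burdenTable}}).
#' @param taus thresholds to sweep.
#' @return a \code{data.frame}: \code{tau}, \code{n_high}, \code{n_low},
#'   \code{chi_square}, \code{p_value} (\code{NA} where a stratum is empty
#'   or eventless data make the test undefined).
#' @export
tauSweep <- function(records, taus = seq(-5, 5, by = 1)) {
    stopifnot(all(c("delta", "survival_time", "event") %in%
                      colnames(records)))
    rows <- lapply(taus, function(tau) {
        hi <- records$delta > tau
        if (!any(hi) || all(hi) ||
            sum(records$event) == 0)
            return(data.frame(tau = tau, n_high = sum(hi),
                              n_low = sum(!hi), chi_square = NA_real_,
                              p_value = NA_real_))
        lr <- logrankTest(records$survival_time[hi], records$event[hi],
                          records$survival_time[!hi], records$event[!hi])
        data.frame(tau = tau, n_high = sum(hi), n_low = sum(!hi),
                   chi_square = lr$chi_square, p_value = lr$p_value)
    })
    do.call(rbind, rows)
}
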