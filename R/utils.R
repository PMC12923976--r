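#' @importFrom methods is new validObject setValidity show slot
#' @importFrom stats median p.adjust pchisq pf phyper dhyper pnorm pwilcox
#'   rbinom rexp rnbinom runif setNames
#' @importFrom utils head tail
#' @importFrom GenomeInfoDb sortSeqlevels
NULL

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Lightweight stage logging, silenced unless options(orphanRNA.verbose = TRUE)
.logmsg <- function(fmt, ...) {
    if (isTRUE(getOption("orphanRNA.verbose", FALSE)))
        message(sprintf(paste0("[orphanRNA] ", fmt), ...))
    invisible(NULL)
}

## Evaluate `expr` under a private RNG state seeded with `seed`, restoring the
## caller's RNG afterwards. All simulator randomness is scoped through this.
.withSeed <- function(seed, expr) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        runif(1L)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

## Stable 31-bit string hash (polynomial rolling hash). Used to fan a global
## seed out to per-sample substreams so that adding or removing samples does
## not perturb the reads generated for the others.
.hashString <- function(x) {
    vapply(x, function(s) {
        h <- 0
        for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
        as.integer(h)
    }, integer(1L), USE.NAMES = FALSE)
}

.sampleSeed <- function(seed, sampleId) {
    as.integer((as.numeric(seed) * 7919 + .hashString(sampleId)) %% 2147483647)
}

## Numerically stable log(sum(exp(x)))
.logSumExp <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
}

.checkProb <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
        .stopf("'%s' must be a single probability in [0, 1]", name)
    invisible(x)
}

.checkCount <- function(x, name, positive = FALSE) {
    ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
        x == as.integer(x) && x >= if (positive) 1 else 0
    if (!ok)
        .stopf("'%s' must be a single %s integer", name,
               if (positive) "positive" else "nonnegative")
    invisible(as.integer(x))
}
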