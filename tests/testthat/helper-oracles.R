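## Independent oracles used to check the package implementations. These are
## deliberately naive (loops, full enumeration, closed forms) and share no
## code with the implementations they verify.

## DUST score via an explicit double loop over triplet positions
oracleDust <- function(seq) {
    seq <- toupper(seq)
    L <- nchar(seq)
    k <- L - 2L
    trips <- character(0)
    for (i in seq_len(k)) {
        t <- substr(seq, i, i + 2L)
        if (!grepl("N", t, fixed = TRUE)) trips <- c(trips, t)
    }
    total <- 0
    for (t in unique(trips)) {
        ct <- sum(trips == t)
        total <- total + ct * (ct - 1) / 2
    }
    total / (k - 1)
}

## One-sided (greater) Fisher p as an explicit hypergeometric enumeration
## from binomial coefficients
oracleFisherGreater <- function(a, b, c, d) {
    m <- a + c; n <- b + d; k <- a + b
    denom <- choose(m + n, k)
    xs <- a:min(k, m)
    sum(choose(m, xs) * choose(n, k - xs)) / denom
}

## BH step-up by its definition
oracleBH <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- ps * m / seq_len(m)
    for (i in rev(seq_len(m - 1))) q[i] <- min(q[i], q[i + 1])
    q <- pmin(q, 1)
    out <- numeric(m)
    out[o] <- q
    out
}

## Exact one-sided Mann-Whitney p by enumerating every assignment of the
## pooled ranks to the x-sample
oracleMWU <- function(x, y) {
    n <- length(x); m <- length(y)
    r <- rank(c(x, y))
    uObs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    combos <- utils::combn(n + m, n)
    us <- apply(combos, 2L, function(idx) sum(idx) - n * (n + 1) / 2)
    mean(us >= uObs)
}

## Textbook two-group log-rank chi-square
oracleLogrank <- function(time, event, group) {
    g <- unique(group)
    stopifnot(length(g) == 2L)
    evTimes <- sort(unique(time[event == 1]))
    O <- E <- V <- 0
    for (t in evTimes) {
        atRisk <- time >= t
        n1 <- sum(atRisk & group == g[1L])
        ntot <- sum(atRisk)
        d <- sum(time == t & event == 1)
        d1 <- sum(time == t & event == 1 & group == g[1L])
        O <- O + d1
        E <- E + d * n1 / ntot
        if (ntot > 1)
            V <- V + d * (n1 / ntot) * (1 - n1 / ntot) *
                (ntot - d) / (ntot - 1)
    }
    (O - E)^2 / V
}

## Per-row one-way ANOVA through stats::oneway.test (equal variances)
oracleAnovaRow <- function(values, groups) {
    ft <- stats::oneway.test(values ~ factor(groups), var.equal = TRUE)
    list(F = unname(ft$statistic), p = unname(ft$p.value))
}

## Kneedle: perpendicular distance to the chord, computed geometrically
oracleElbowIndex <- function(ySorted) {
    n <- length(ySorted)
    p1 <- c(1, ySorted[1]); p2 <- c(n, ySorted[n])
    v <- p2 - p1
    d <- vapply(seq_len(n), function(i) {
        w <- c(i, ySorted[i]) - p1
        abs(v[1] * w[2] - v[2] * w[1]) / sqrt(sum(v^2))
    }, numeric(1))
    which.max(d)
}
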