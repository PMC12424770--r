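## Independent brute-force oracles used across the suite. These never call
## the implementation paths they check.

## O(n*m) all-pairs edge-gap distance between 1-based closed intervals;
## overlap and bookended = 0; NA when no target shares the chromosome.
bruteClosest <- function(qchr, qs, qe, tchr, ts, te) {
    vapply(seq_along(qs), function(i) {
        j <- which(tchr == qchr[i])
        if (!length(j)) return(NA_real_)
        g <- pmax(ts[j] - qe[i] - 1, qs[i] - te[j] - 1, 0)
        min(g)
    }, 0)
}

## O(n*m) count of queries overlapping >= 1 target by >= 1 base
bruteGenicCount <- function(qchr, qs, qe, tchr, ts, te) {
    sum(vapply(seq_along(qs), function(i) {
        j <- which(tchr == qchr[i])
        any(ts[j] <= qe[i] & te[j] >= qs[i])
    }, TRUE))
}

## random interval instance on a handful of chromosomes
randomIntervals <- function(n, chroms = c("c1", "c2", "c3"),
                            max_pos = 10000, max_len = 300) {
    chr <- sample(chroms, n, replace = TRUE)
    s <- sample.int(max_pos, n, replace = TRUE)
    l <- sample.int(max_len, n, replace = TRUE)
    data.frame(chrom = chr, start = s, end = s + l - 1L)
}

## direct GLS solve against an explicit covariance (dense inverse)
bruteGls <- function(y, X, V) {
    Vi <- solve(V)
    solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
}

## Grubbs critical value recomputed from first principles
bruteGrubbsCritical <- function(n, alpha = 0.05) {
    t2 <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)^2
    (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

## BH step-up adjustment written out longhand
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    prev <- 1
    for (i in m:1) {
        prev <- min(prev, p[o[i]] * m / i)
        adj[o[i]] <- prev
    }
    adj
}

## temporary study directory, removed on exit of the calling test
localStudy <- function(..., envir = parent.frame()) {
    d <- tempfile("study")
    withr::defer(unlink(d, recursive = TRUE), envir = envir)
    simulateStudy(d, ...)
}
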