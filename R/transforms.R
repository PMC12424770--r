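## Trait transformations: Tukey ladder of powers, min-max normalization,
## and Grubbs outlier screening.

#' Tukey ladder-of-powers transformation
#'
#' Searches a grid of power exponents for the transform that makes the
#' vector most nearly normal, judged by the Shapiro-Wilk W statistic. The
#' transform rule keeps every candidate monotone increasing: \code{x^p} for
#' p > 0, \code{log(x)} for p = 0, and \code{-(x^p)} for p < 0 (the sign
#' flip undoes the order reversal of negative powers). Candidates with
#' p <= 0 require strictly positive data and are skipped otherwise --
#' count predictors with zeros are therefore only ever raised to positive
#' powers unless an \code{offset} is supplied.
#'
#' @param x numeric vector, length >= 3, non-constant
#' @param grid candidate powers (default \code{seq(-2, 2, by = 0.025)})
#' @param offset constant added to \code{x} before the search (default 0)
#' @return a list: \code{power} (selected exponent), \code{transformed}
#'   (transformed vector), \code{w} (its Shapiro-Wilk W), \code{w_raw}
#'   (W of the input)
#' @export
tukeyTransform <- function(x, grid = seq(-2, 2, by = 0.025), offset = 0) {
    if (length(x) < 3) stop("need at least 3 values", call. = FALSE)
    x <- x + offset
    if (max(x) == min(x)) stop("constant vector", call. = FALSE)
    if (length(x) > 5000)
        stop("Shapiro-Wilk objective limited to 5000 values", call. = FALSE)
    if (min(x) <= 0) grid <- grid[grid > 0]
    if (!length(grid))
        stop("no valid candidate powers (non-positive data exclude p <= 0; ",
             "consider an offset)", call. = FALSE)
    best <- NULL
    for (p in grid) {
        tx <- if (p > 0) x^p else if (p == 0) log(x) else -(x^p)
        if (any(!is.finite(tx)) || max(tx) == min(tx)) next
        w <- suppressWarnings(tryCatch(stats::shapiro.test(tx)$statistic,
                                       error = function(e) NA_real_))
        if (is.na(w)) next
        if (is.null(best) || w > best$w)
            best <- list(power = p, transformed = tx, w = unname(w))
    }
    if (is.null(best))
        stop("all candidate powers produced degenerate transforms",
             call. = FALSE)
    best$w_raw <- unname(suppressWarnings(
        tryCatch(stats::shapiro.test(x)$statistic,
                 error = function(e) NA_real_)))
    best
}

#' Min-max normalization to [0, 1]
#'
#' @param x numeric vector, non-constant (\code{NA}s are preserved)
#' @return \code{(x - min) / (max - min)}
#' @export
minmaxNormalize <- function(x) {
    lo <- min(x, na.rm = TRUE)
    hi <- max(x, na.rm = TRUE)
    if (hi == lo) stop("constant vector", call. = FALSE)
    (x - lo) / (hi - lo)
}

#' Grubbs test for a single outlier
#'
#' Two-sided Grubbs statistic G = max |x - mean| / sd (sample sd, n - 1
#' denominator) against the critical value
#' \deqn{G_{crit} = \frac{n-1}{\sqrt{n}}
#'   \sqrt{\frac{t^2}{n - 2 + t^2}}}
#' with \eqn{t} the upper \eqn{\alpha/(2n)} quantile of the t-distribution
#' on n - 2 degrees of freedom. The maximal-deviation point is flagged iff
#' G exceeds the critical value. Flagged points are reported only -- this
#' package never removes them (long-lived outlier species are biology, not
#' error).
#'
#' @param x numeric vector, length >= 3, non-constant
#' @param alpha significance level (default 0.05)
#' @return a list: \code{statistic} (G), \code{critical},
#'   \code{outlier_index} (index of the flagged value, or \code{NA}),
#'   \code{outlier_value}, \code{alpha}
#' @export
grubbsTest <- function(x, alpha = 0.05) {
    n <- length(x)
    if (n < 3) stop("need at least 3 values", call. = FALSE)
    s <- stats::sd(x)
    if (s == 0) stop("zero standard deviation", call. = FALSE)
    dev <- abs(x - mean(x))
    i <- which.max(dev)
    G <- dev[i] / s
    tq <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
    crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
    flagged <- G > crit
    list(statistic = unname(G), critical = crit,
         outlier_index = if (flagged) i else NA_integer_,
         outlier_value = if (flagged) x[i] else NA_real_,
         alpha = alpha)
}
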