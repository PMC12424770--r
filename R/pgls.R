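## Weighted phylogenetic generalized least squares with jointly estimated
## Pagel's lambda and per-species sampling error.
##
## Model: y ~ N(X beta, sigma2 * C(lambda) + tau2 * diag(w^2)) where C is
## the Brownian-motion variance-covariance matrix of the phylogeny, lambda
## scales its off-diagonal entries, and w is the per-species sampling-error
## scale (1/sqrt of the necropsy count). beta is profiled out by GLS at
## each variance-parameter value; the variance parameters maximise the
## exact multivariate-normal log-likelihood.

#' Phylogenetic variance-covariance matrix
#'
#' C[i, j] is the sum of branch lengths shared by the root-to-tip paths of
#' tips i and j (the root-to-MRCA depth); the diagonal holds root-to-tip
#' depths. The tree is pruned to the requested species first.
#'
#' @param tree an \code{ape} \code{phylo} object with branch lengths
#' @param species optional character vector of tip labels defining the
#'   subset and the row/column order of the result (default: all tips in
#'   tree order)
#' @return a symmetric positive semi-definite matrix with dimnames set to
#'   the species labels
#' @export
vcvFromTree <- function(tree, species = NULL) {
    stopifnot(inherits(tree, "phylo"))
    if (is.null(species)) species <- tree$tip.label
    unknown <- setdiff(species, tree$tip.label)
    if (length(unknown))
        stop("species not in tree: ", paste(unknown, collapse = ", "),
             call. = FALSE)
    if (length(species) < length(tree$tip.label))
        tree <- ape::keep.tip(tree, species)
    C <- ape::vcv(tree)
    C[species, species, drop = FALSE]
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries by \code{lambda}, leaving tip
#' variances unchanged: lambda = 1 is Brownian motion, lambda = 0 removes
#' all phylogenetic covariance (a star phylogeny).
#'
#' @param C phylogenetic variance-covariance matrix
#' @param lambda scalar in [0, 1]
#' @return the rescaled matrix
#' @export
lambdaTransform <- function(C, lambda) {
    if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
        lambda < 0 || lambda > 1)
        stop("lambda must be a single value in [0, 1]", call. = FALSE)
    Cl <- C * lambda
    diag(Cl) <- diag(C)
    Cl
}

#' Akaike information criterion from a log-likelihood
#'
#' @param loglik maximised log-likelihood
#' @param k number of estimated parameters
#' @return \code{-2 * loglik + 2 * k}
#' @export
aicScore <- function(loglik, k) {
    if (k < 1) stop("k must be >= 1", call. = FALSE)
    -2 * loglik + 2 * k
}

## GLS with beta profiled out against covariance W (up to a scale).
## Returns the profiled-sigma2 ML (or REML) log-likelihood and fit pieces.
.glsProfiled <- function(y, X, W, reml = FALSE) {
    n <- length(y)
    p <- ncol(X)
    U <- tryCatch(chol(W), error = function(e) NULL)
    if (is.null(U)) return(NULL)
    ty <- backsolve(U, y, transpose = TRUE)
    tX <- backsolve(U, X, transpose = TRUE)
    qrX <- qr(tX)
    beta <- qr.coef(qrX, ty)
    rt <- ty - tX %*% beta
    q <- sum(rt^2)
    logdetW <- 2 * sum(log(diag(U)))
    if (reml) {
        s2 <- max(q / (n - p), 1e-300)
        ll <- -0.5 * ((n - p) * (log(2 * pi) + log(s2) + 1) + logdetW +
                      determinant(crossprod(tX), logarithm = TRUE)$modulus)
    } else {
        s2 <- max(q / n, 1e-300)
        ll <- -0.5 * (n * (log(2 * pi) + log(s2) + 1) + logdetW)
    }
    list(beta = drop(beta), sigma2 = s2, loglik = as.numeric(ll),
         U = U, tX = tX, ty = drop(ty), rt = drop(rt), profiled = TRUE)
}

## GLS against a fully specified covariance V (no free scale).
.glsFixedScale <- function(y, X, V, reml = FALSE) {
    n <- length(y)
    U <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(U)) return(NULL)
    ty <- backsolve(U, y, transpose = TRUE)
    tX <- backsolve(U, X, transpose = TRUE)
    qrX <- qr(tX)
    beta <- qr.coef(qrX, ty)
    rt <- ty - tX %*% beta
    q <- sum(rt^2)
    logdetV <- 2 * sum(log(diag(U)))
    ll <- -0.5 * (n * log(2 * pi) + logdetV + q)
    if (reml)
        ll <- ll + 0.5 * ncol(X) * log(2 * pi) -
            0.5 * determinant(crossprod(tX), logarithm = TRUE)$modulus
    list(beta = drop(beta), sigma2 = NA_real_, loglik = as.numeric(ll),
         U = U, tX = tX, ty = drop(ty), rt = drop(rt), profiled = FALSE)
}

## 1-D maximisation on an interval: coarse grid, then local refinement in
## the bracketing subinterval, then explicit boundary comparison. Robust to
## the mild multimodality of lambda profiles without derivatives.
.gridOptimize <- function(f, lower, upper, n_grid = 11, tol = 1e-6) {
    grid <- seq(lower, upper, length.out = n_grid)
    vals <- vapply(grid, f, 0)
    i <- which.max(vals)
    lo <- grid[max(i - 1L, 1L)]
    hi <- grid[min(i + 1L, n_grid)]
    opt <- stats::optimize(f, interval = c(lo, hi), maximum = TRUE,
                           tol = tol)
    cand_x <- c(opt$maximum, grid[i], lower, upper)
    cand_v <- c(opt$objective, vals[i], vals[1], vals[n_grid])
    j <- which.max(cand_v)
    list(maximum = cand_x[j], objective = cand_v[j])
}

#' Fit a weighted phylogenetic GLS regression with Pagel's lambda
#'
#' Fits \eqn{y \sim N(X\beta, V)} with
#' \eqn{V = \sigma^2 C(\lambda) + \tau^2 \mathrm{diag}(w^2)}: phylogenetic
#' residual covariance scaled by Pagel's \eqn{\lambda} plus an additive
#' diagonal sampling-error term driven by the per-species weights
#' \eqn{w = 1/\sqrt{n}}. \eqn{\beta} is profiled out by GLS at each
#' variance-parameter value; \eqn{\lambda} (unless fixed) and the variance
#' components maximise the exact log-likelihood, with \eqn{\lambda}
#' restricted to [0, 1] and located by a grid-plus-refinement search that
#' always compares the interior optimum against both boundaries.
#'
#' By default the sampling-error scale \eqn{\tau^2} is estimated, which
#' makes the fit invariant to the unknown scale of the weights after trait
#' transformation; \code{tau = "fixed"} pins \eqn{\tau^2 = 1} so the
#' weights enter on their raw scale. When all weights are zero the
#' sampling-error term vanishes and is not counted as a parameter.
#'
#' Coefficient tests are t-tests on n - p degrees of freedom. R-squared is
#' GLS-weighted: \eqn{1 - e'V^{-1}e / y_c'V^{-1}y_c} with \eqn{y_c} the
#' response centred at its GLS (intercept-only, same V) mean. Diagnostics
#' are computed on the normalized residuals \eqn{V^{-1/2} e}: Shapiro-Wilk
#' normality, a Breusch-Pagan-type score test of their squared values on
#' the fitted values, and variance inflation factors for multiple
#' regressions.
#'
#' @param formula model formula; variables are looked up in \code{data}
#' @param data data.frame whose rownames are species labels matching
#'   \code{C}
#' @param C phylogenetic variance-covariance matrix covering (at least) the
#'   species in \code{data}
#' @param weights named per-species sampling-error scale (the 1/sqrt(n)
#'   vector); \code{NULL} means no sampling error
#' @param lambda \code{"ML"} (default) to estimate Pagel's lambda, or a
#'   fixed value in [0, 1]
#' @param tau \code{"estimate"} (default) or \code{"fixed"} (tau2 = 1)
#' @param reml use REML instead of ML for the variance parameters
#' @return a \code{\linkS4class{PglsFit}}
#' @examples
#' tr <- simulateTree(30, seed = 1)
#' C <- vcvFromTree(tr)
#' df <- data.frame(x = rnorm(30), row.names = tr$tip.label)
#' df$y <- 2 * df$x + as.vector(simulateTraits(C, lambda = 0.5,
#'     sigma2 = 0.5, seed = 2))
#' fitPgls(y ~ x, df, C)
#' @export
fitPgls <- function(formula, data, C, weights = NULL, lambda = "ML",
                    tau = c("estimate", "fixed"), reml = FALSE) {
    tau <- match.arg(tau)
    mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
    y <- stats::model.response(mf)
    X <- stats::model.matrix(formula, mf)
    n <- length(y)
    p <- ncol(X)
    if (qr(X)$rank < p)
        stop("design matrix is rank deficient", call. = FALSE)
    if (n <= p)
        stop("need more species than coefficients", call. = FALSE)
    sp <- rownames(mf)
    missingC <- setdiff(sp, rownames(C))
    if (length(missingC))
        stop("species missing from C: ", paste(missingC, collapse = ", "),
             call. = FALSE)
    C <- C[sp, sp, drop = FALSE]
    if (is.null(weights)) {
        w <- numeric(n)
    } else {
        w <- if (!is.null(names(weights))) unname(weights[sp])
             else rep_len(weights, n)
        if (anyNA(w) || any(w < 0))
            stop("invalid sampling weights", call. = FALSE)
    }
    d <- w^2
    zeroW <- all(d == 0)
    estLambda <- identical(lambda, "ML") || identical(lambda, "estimate")
    if (!estLambda) {
        if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
            stop("fixed lambda must lie in [0, 1]", call. = FALSE)
    }

    ## inner fit at a given lambda, maximising over the remaining variance
    ## parameter; returns loglik plus the pieces needed downstream.
    ## A tiny ridge is added to the diagonal only if the covariance is not
    ## numerically positive definite (e.g. duplicated zero-length tips).
    ridge <- 1e-8 * mean(diag(C))
    profiledFit <- function(W) {
        ft <- .glsProfiled(y, X, W, reml)
        if (is.null(ft))
            ft <- .glsProfiled(y, X, W + diag(ridge, n), reml)
        ft
    }
    fixedScaleFit <- function(V) {
        ft <- .glsFixedScale(y, X, V, reml)
        if (is.null(ft))
            ft <- .glsFixedScale(y, X, V + diag(ridge, n), reml)
        ft
    }
    innerFit <- function(lam) {
        Cl <- lambdaTransform(C, lam)
        if (tau == "estimate" || zeroW) {
            if (zeroW) {
                fit <- profiledFit(Cl)
                if (is.null(fit)) return(NULL)
                fit$tau2 <- 0
                return(fit)
            }
            ## V = sigma2 (C(lam) + g D); profile sigma2, optimize log g
            D <- d
            f <- function(logg) {
                ft <- profiledFit(Cl + exp(logg) * diag(D, n))
                if (is.null(ft)) -Inf else ft$loglik
            }
            opt <- .gridOptimize(f, -12, 12, n_grid = 9, tol = 1e-5)
            g <- exp(opt$maximum)
            fit <- profiledFit(Cl + g * diag(D, n))
            if (is.null(fit)) return(NULL)
            fit$tau2 <- g * fit$sigma2
            fit
        } else {
            ## strict mode: V = sigma2 C(lam) + D, tau2 = 1
            ls2_ols <- log(max(stats::var(stats::lm.fit(X, y)$residuals),
                               1e-12))
            f <- function(ls2) {
                ft <- fixedScaleFit(exp(ls2) * Cl + diag(d, n))
                if (is.null(ft)) -Inf else ft$loglik
            }
            opt <- .gridOptimize(f, ls2_ols - 15, ls2_ols + 10,
                                 n_grid = 11, tol = 1e-6)
            s2 <- exp(opt$maximum)
            fit <- fixedScaleFit(s2 * Cl + diag(d, n))
            if (is.null(fit)) return(NULL)
            fit$sigma2 <- s2
            fit$tau2 <- 1
            fit
        }
    }

    if (estLambda) {
        prof <- function(lam) {
            ft <- innerFit(lam)
            if (is.null(ft)) -Inf else ft$loglik
        }
        opt <- .gridOptimize(prof, 0, 1, n_grid = 11, tol = 1e-6)
        lambda_hat <- opt$maximum
    } else {
        lambda_hat <- as.numeric(lambda)
    }
    fit <- innerFit(lambda_hat)
    if (is.null(fit))
        stop("covariance not positive definite at the optimum; ",
             "optimization failed", call. = FALSE)

    beta <- fit$beta
    names(beta) <- colnames(X)
    ## cov(beta) = (X' V^-1 X)^-1; with the profiled parameterisation the
    ## whitening used sigma2-free W, so the estimated scale multiplies back
    XtXinv <- chol2inv(qr.R(qr(fit$tX)))
    covb <- if (fit$profiled) fit$sigma2 * XtXinv else XtXinv
    se <- sqrt(diag(covb))
    names(se) <- colnames(X)
    tstat <- beta / se
    pv <- 2 * stats::pt(-abs(tstat), df = n - p)
    resid_raw <- drop(y - X %*% beta)
    normres <- if (fit$profiled) fit$rt / sqrt(fit$sigma2) else fit$rt
    ## GLS-weighted R2 against the intercept-only GLS mean under the same V
    t1 <- backsolve(fit$U, rep(1, n), transpose = TRUE)
    mu <- sum(t1 * fit$ty) / sum(t1^2)
    den <- sum((fit$ty - t1 * mu)^2)
    r2 <- if (den > 0) 1 - sum(fit$rt^2) / den else NA_real_
    adjr2 <- if (!is.na(r2)) 1 - (1 - r2) * (n - 1) / (n - p) else NA_real_

    tau2Est <- tau == "estimate" && !zeroW
    k <- p + 1L + as.integer(estLambda) + as.integer(tau2Est)

    diag_list <- list(shapiro_p = NA_real_, bp_p = NA_real_, vif = NULL)
    if (n >= 3 && n <= 5000 && stats::sd(normres) > 0) {
        diag_list$shapiro_p <- suppressWarnings(
            tryCatch(stats::shapiro.test(normres)$p.value,
                     error = function(e) NA_real_))
        fitvals <- drop(X %*% beta)
        if (stats::sd(fitvals) > 0) {
            aux <- stats::lm(I(normres^2) ~ fitvals)
            r2aux <- summary(aux)$r.squared
            diag_list$bp_p <- stats::pchisq(n * r2aux, df = 1,
                                            lower.tail = FALSE)
        }
    }
    pred_cols <- setdiff(colnames(X), "(Intercept)")
    if (length(pred_cols) >= 2)
        diag_list$vif <- vifScores(X[, pred_cols, drop = FALSE])

    new("PglsFit",
        beta = beta, se = se, tstat = tstat, pvalue = pv,
        lambda = lambda_hat, lambdaEstimated = estLambda,
        sigma2 = fit$sigma2, tau2 = fit$tau2, tau2Estimated = tau2Est,
        loglik = fit$loglik, k = k, aic = aicScore(fit$loglik, k),
        r2 = r2, adjR2 = adjr2,
        residuals = resid_raw, normalizedResiduals = drop(normres),
        fitted = drop(X %*% beta), nobs = as.integer(n), p = as.integer(p),
        diagnostics = diag_list,
        model = list(response = as.character(formula[[2]]),
                     predictors = pred_cols, weights = w, species = sp,
                     tau_mode = tau, reml = reml))
}

#' Compare fixed- and estimated-lambda fits by AIC
#'
#' Refits the model with Pagel's lambda fixed at 0 (no phylogenetic
#' signal), estimated by ML, and fixed at 1 (Brownian motion), and tabulates
#' log-likelihoods and AICs. The estimated-lambda model carries one more
#' parameter than the fixed-lambda models.
#'
#' @inheritParams fitPgls
#' @return a list: \code{table} (data.frame with columns \code{model},
#'   \code{lambda}, \code{loglik}, \code{k}, \code{aic}) and \code{fits}
#'   (the three \code{\linkS4class{PglsFit}} objects)
#' @export
compareLambdaModels <- function(formula, data, C, weights = NULL,
                                tau = c("estimate", "fixed"), reml = FALSE) {
    tau <- match.arg(tau)
    fits <- list(
        lambda0 = fitPgls(formula, data, C, weights, lambda = 0,
                          tau = tau, reml = reml),
        lambdaML = fitPgls(formula, data, C, weights, lambda = "ML",
                           tau = tau, reml = reml),
        lambda1 = fitPgls(formula, data, C, weights, lambda = 1,
                          tau = tau, reml = reml))
    tab <- data.frame(
        model = names(fits),
        lambda = vapply(fits, lambdaHat, 0),
        loglik = vapply(fits, function(f) f@loglik, 0),
        k = vapply(fits, function(f) as.numeric(f@k), 0),
        aic = vapply(fits, aicValue, 0),
        stringsAsFactors = FALSE)
    rownames(tab) <- NULL
    list(table = tab, fits = fits)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjusted p-values with rejection flags at FDR level \code{q}.
#'
#' @param p_values numeric vector of p-values in [0, 1]
#' @param q target false discovery rate (default 0.05)
#' @return a data.frame: \code{p}, \code{p_adjusted}, \code{reject}
#' @export
bhFdr <- function(p_values, q = 0.05) {
    if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
        stop("p-values must lie in [0, 1]", call. = FALSE)
    adj <- stats::p.adjust(p_values, method = "BH")
    data.frame(p = p_values, p_adjusted = adj, reject = adj <= q)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R2_j) where R2_j is from regressing predictor j on all
#' the others (with intercept). Values above 5 indicate substantial
#' collinearity; a perfectly collinear predictor yields \code{Inf}.
#'
#' @param X numeric matrix or data.frame of predictors (no intercept
#'   column), at least two columns and more rows than columns
#' @return named numeric vector of VIFs
#' @export
vifScores <- function(X) {
    X <- as.matrix(X)
    if (ncol(X) < 2) stop("need at least two predictors", call. = FALSE)
    if (nrow(X) <= ncol(X))
        stop("need more observations than predictors", call. = FALSE)
    if (is.null(colnames(X)))
        colnames(X) <- paste0("x", seq_len(ncol(X)))
    v <- vapply(seq_len(ncol(X)), function(j) {
        ## perfect-fit warnings are the expected path to an infinite VIF
        r2 <- suppressWarnings(summary(
            stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared)
        if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, 0)
    names(v) <- colnames(X)
    v
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3, non-constant
#' @return correlation coefficient in [-1, 1]
#' @export
pearsonR <- function(x, y) {
    if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
    if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("constant input", call. = FALSE)
    stats::cor(x, y)
}
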