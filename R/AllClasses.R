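#' @import methods
#' @importFrom stats coef logLik residuals fitted
NULL

#' Per-species necropsy cohort
#'
#' An S4 container for the per-species cancer cohort table: necropsy totals,
#' neoplasia and malignancy tallies, prevalences, optional longevity, and the
#' 1/sqrt(n) sampling weight used by the weighted phylogenetic regressions.
#' Validity enforces the count nesting 0 <= malignant <= neoplasia <=
#' necropsies, the exact prevalence identities, and the weight definition.
#'
#' @slot records a \code{data.frame} with columns \code{species_id},
#'   \code{n_necropsies}, \code{n_neoplasia}, \code{n_malignant},
#'   \code{longevity} (months, may be \code{NA}),
#'   \code{neoplasia_prevalence}, \code{malignancy_prevalence},
#'   \code{weight}.
#'
#' @exportClass SpeciesCohort
setClass("SpeciesCohort", representation(records = "data.frame"))

setValidity("SpeciesCohort", function(object) {
    df <- object@records
    need <- c("species_id", "n_necropsies", "n_neoplasia", "n_malignant",
              "longevity", "neoplasia_prevalence", "malignancy_prevalence",
              "weight")
    miss <- setdiff(need, names(df))
    if (length(miss))
        return(paste("missing columns:", paste(miss, collapse = ", ")))
    if (anyDuplicated(df$species_id))
        return("duplicated species_id")
    if (any(df$n_necropsies < 0) || any(df$n_neoplasia < 0) ||
        any(df$n_malignant < 0))
        return("negative counts")
    bad <- df$n_malignant > df$n_neoplasia | df$n_neoplasia > df$n_necropsies
    if (any(bad))
        return(paste("count nesting violated for:",
                     paste(df$species_id[bad], collapse = ", ")))
    pos <- df$n_necropsies > 0
    if (any(abs(df$neoplasia_prevalence[pos] -
                df$n_neoplasia[pos] / df$n_necropsies[pos]) > 0))
        return("neoplasia_prevalence != n_neoplasia / n_necropsies")
    if (any(abs(df$malignancy_prevalence[pos] -
                df$n_malignant[pos] / df$n_necropsies[pos]) > 0))
        return("malignancy_prevalence != n_malignant / n_necropsies")
    wref <- ifelse(df$n_necropsies >= 1, 1 / sqrt(df$n_necropsies), NA_real_)
    if (any(pos & abs(df$weight - wref) > 1e-12, na.rm = TRUE))
        return("weight != 1/sqrt(n_necropsies)")
    TRUE
})

#' Trimmed proximity summary of closest-feature distances
#'
#' Quartiles, Tukey fences, and the interquartile-range (IQR) mean of a set
#' of element-to-gene distances. The IQR mean is the plain mean of the
#' distances inside [Q1 - 1.5 IQR, Q3 + 1.5 IQR]; points outside the fences
#' are counted in \code{nExcluded} and dropped from the mean only (never
#' from the data).
#'
#' @slot n number of distances summarised
#' @slot median,q1,q3 quartiles (linear-interpolation convention)
#' @slot iqr \code{q3 - q1}
#' @slot lower,upper the Tukey fences \code{q1 - 1.5 iqr}, \code{q3 + 1.5 iqr}
#' @slot iqrMean mean of the within-fence distances
#' @slot nExcluded number of distances outside the fences
#'
#' @exportClass ProximityStats
setClass("ProximityStats", representation(
    n = "integer", median = "numeric", q1 = "numeric", q3 = "numeric",
    iqr = "numeric", lower = "numeric", upper = "numeric",
    iqrMean = "numeric", nExcluded = "integer"))

setValidity("ProximityStats", function(object) {
    if (object@n < 1L) return("n must be >= 1")
    if (abs(object@iqr - (object@q3 - object@q1)) > 1e-9)
        return("iqr != q3 - q1")
    if (abs(object@lower - (object@q1 - 1.5 * object@iqr)) > 1e-9 ||
        abs(object@upper - (object@q3 + 1.5 * object@iqr)) > 1e-9)
        return("fences inconsistent with quartiles")
    if (object@q1 > object@median || object@median > object@q3)
        return("quartile ordering violated")
    TRUE
})

#' Fitted weighted phylogenetic GLS regression
#'
#' Result of \code{\link{fitPgls}}: the model is
#' \deqn{y \sim N(X\beta,\; \sigma^2 C(\lambda) + \tau^2 \mathrm{diag}(w^2))}
#' where \eqn{C(\lambda)} is the Pagel-lambda-scaled phylogenetic
#' variance-covariance matrix and \eqn{w} the per-species sampling-error
#' scale (1/sqrt of the necropsy count). \eqn{\beta} is profiled out by GLS;
#' the variance parameters (and \eqn{\lambda} when estimated) maximise the
#' exact multivariate-normal likelihood.
#'
#' @slot beta,se,tstat,pvalue named coefficient vectors
#' @slot lambda estimated (or fixed) Pagel's lambda in [0,1]
#' @slot lambdaEstimated whether lambda was optimised
#' @slot sigma2 Brownian-rate variance component
#' @slot tau2 sampling-error variance scale (1 in strict mode; 0 when all
#'   weights are zero)
#' @slot tau2Estimated whether tau2 was optimised
#' @slot loglik maximised log-likelihood
#' @slot k parameter count used for AIC
#' @slot aic -2 loglik + 2 k
#' @slot r2,adjR2 GLS-weighted coefficient of determination (and its
#'   adjusted form)
#' @slot residuals raw response residuals
#' @slot normalizedResiduals residuals whitened by the fitted covariance
#' @slot fitted fitted values X beta
#' @slot nobs,p sample size and number of coefficients
#' @slot diagnostics list: Shapiro-Wilk p on normalized residuals,
#'   Breusch-Pagan-type score-test p, VIFs (multiple regressions only)
#' @slot model list with response/predictor names and the weight vector
#'
#' @exportClass PglsFit
setClass("PglsFit", representation(
    beta = "numeric", se = "numeric", tstat = "numeric", pvalue = "numeric",
    lambda = "numeric", lambdaEstimated = "logical",
    sigma2 = "numeric", tau2 = "numeric", tau2Estimated = "logical",
    loglik = "numeric", k = "integer", aic = "numeric",
    r2 = "numeric", adjR2 = "numeric",
    residuals = "numeric", normalizedResiduals = "numeric",
    fitted = "numeric", nobs = "integer", p = "integer",
    diagnostics = "list", model = "list"))

setValidity("PglsFit", function(object) {
    if (object@lambda < 0 || object@lambda > 1)
        return("lambda outside [0,1]")
    if (object@sigma2 < 0) return("sigma2 < 0")
    if (abs(object@aic - (-2 * object@loglik + 2 * object@k)) > 1e-8)
        return("aic != -2 loglik + 2 k")
    if (length(object@beta) != object@p) return("beta length != p")
    TRUE
})
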