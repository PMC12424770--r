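#' @rdname SpeciesCohort-class
#' @aliases cohortRecords,SpeciesCohort-method
#' @export
setMethod("cohortRecords", "SpeciesCohort", function(x) x@records)

#' @rdname SpeciesCohort-class
#' @export
setMethod("speciesNames", "SpeciesCohort", function(x) x@records$species_id)

#' @rdname SpeciesCohort-class
#' @export
setMethod("samplingWeights", "SpeciesCohort", function(x) {
    w <- x@records$weight
    names(w) <- x@records$species_id
    w
})

#' @rdname SpeciesCohort-class
#' @export
setMethod("length", "SpeciesCohort", function(x) nrow(x@records))

setMethod("show", "SpeciesCohort", function(object) {
    df <- object@records
    cat("SpeciesCohort with", nrow(df), "species\n")
    if (nrow(df)) {
        cat(sprintf("  necropsies: %d-%d (median %.0f)\n",
                    min(df$n_necropsies), max(df$n_necropsies),
                    stats::median(df$n_necropsies)))
        cat(sprintf("  neoplasia prevalence: %.3f-%.3f\n",
                    min(df$neoplasia_prevalence),
                    max(df$neoplasia_prevalence)))
        cat(sprintf("  malignancy prevalence: %.3f-%.3f\n",
                    min(df$malignancy_prevalence),
                    max(df$malignancy_prevalence)))
        cat(sprintf("  longevity known for %d species\n",
                    sum(!is.na(df$longevity))))
    }
    invisible(NULL)
})

#' @rdname ProximityStats-class
#' @param x,object a \code{ProximityStats}
#' @export
setMethod("iqrMean", "ProximityStats", function(x) x@iqrMean)

#' @rdname ProximityStats-class
#' @export
setMethod("median", "ProximityStats", function(x) x@median)

setMethod("show", "ProximityStats", function(object) {
    cat("ProximityStats over", object@n, "distances\n")
    cat(sprintf("  median %.1f, Q1 %.1f, Q3 %.1f (IQR %.1f)\n",
                object@median, object@q1, object@q3, object@iqr))
    cat(sprintf("  fences [%.1f, %.1f]; IQR mean %.2f (%d outliers excluded)\n",
                object@lower, object@upper, object@iqrMean, object@nExcluded))
    invisible(NULL)
})

#' @rdname PglsFit-class
#' @aliases coef,PglsFit-method logLik,PglsFit-method
#' @param x,object a \code{PglsFit}
#' @param adjusted return the adjusted R-squared?
#' @param type \code{"response"} for raw residuals, \code{"normalized"} for
#'   residuals whitened by the fitted covariance
#' @param ... ignored
#' @export
setMethod("coef", "PglsFit", function(object, ...) object@beta)

#' @rdname PglsFit-class
#' @export
setMethod("logLik", "PglsFit", function(object, ...) {
    ll <- object@loglik
    attr(ll, "df") <- object@k
    attr(ll, "nobs") <- object@nobs
    class(ll) <- "logLik"
    ll
})

#' @rdname PglsFit-class
#' @export
setMethod("residuals", "PglsFit", function(object,
                                           type = c("response", "normalized"),
                                           ...) {
    type <- match.arg(type)
    if (type == "response") object@residuals else object@normalizedResiduals
})

#' @rdname PglsFit-class
#' @export
setMethod("fitted", "PglsFit", function(object, ...) object@fitted)

#' @rdname PglsFit-class
#' @export
setMethod("lambdaHat", "PglsFit", function(x) x@lambda)

#' @rdname PglsFit-class
#' @export
setMethod("sigma2Hat", "PglsFit", function(x) x@sigma2)

#' @rdname PglsFit-class
#' @export
setMethod("pValues", "PglsFit", function(x) x@pvalue)

#' @rdname PglsFit-class
#' @export
setMethod("rSquared", "PglsFit", function(x, adjusted = FALSE) {
    if (adjusted) x@adjR2 else x@r2
})

#' @rdname PglsFit-class
#' @export
setMethod("aicValue", "PglsFit", function(x) x@aic)

#' @rdname PglsFit-class
#' @export
setMethod("fitDiagnostics", "PglsFit", function(x) x@diagnostics)

setMethod("show", "PglsFit", function(object) {
    cat("PglsFit:", object@model$response, "~",
        paste(object@model$predictors, collapse = " + "), "\n")
    cat(sprintf("  n = %d species; lambda %s = %.4f; sigma2 = %.4g; tau2 = %.4g\n",
                object@nobs,
                if (object@lambdaEstimated) "(ML)" else "(fixed)",
                object@lambda, object@sigma2, object@tau2))
    tab <- data.frame(Estimate = object@beta, StdErr = object@se,
                      t = object@tstat, p = object@pvalue)
    print(round(tab, 5))
    cat(sprintf("  logLik = %.3f; AIC = %.3f (k = %d); R2 = %.4f",
                object@loglik, object@aic, object@k, object@r2))
    if (length(object@model$predictors) > 1L)
        cat(sprintf(" (adj %.4f)", object@adjR2))
    cat("\n")
    invisible(NULL)
})
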