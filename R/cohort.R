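## Cohort table: loading, validation, filtering, and sampling weights.

#' Tumor prevalence from necropsy tallies
#'
#' Prevalence is the fraction of necropsies reporting a tumor (any tumor for
#' neoplasia prevalence, malignant tumors for malignancy prevalence).
#'
#' @param n_tumor number of necropsies reporting the tumor class
#' @param n_total total number of necropsy records
#' @param species optional species label used in error messages
#' @return \code{n_tumor / n_total} as a fraction in [0, 1]
#' @examples
#' computePrevalence(5, 20)   # 0.25
#' @export
computePrevalence <- function(n_tumor, n_total, species = NULL) {
    who <- if (is.null(species)) "" else paste0(" for species ", species)
    if (any(n_total == 0))
        stop("n_total is zero", who, call. = FALSE)
    if (any(n_tumor < 0) || any(n_total < 0))
        stop("negative counts", who, call. = FALSE)
    if (any(n_tumor > n_total))
        stop("tumor count exceeds necropsy count", who, call. = FALSE)
    n_tumor / n_total
}

#' Inverse-square-root sampling weight
#'
#' Species necropsy data are weighted by the inverse square root of the
#' species' total necropsy count, so that poorly sampled species contribute
#' larger sampling-error variance to the phylogenetic regression.
#'
#' @param n_necropsies necropsy count, >= 1
#' @return \code{1 / sqrt(n_necropsies)}
#' @examples
#' samplingWeight(25)  # 0.2
#' @export
samplingWeight <- function(n_necropsies) {
    if (any(n_necropsies < 1))
        stop("n_necropsies must be >= 1", call. = FALSE)
    1 / sqrt(n_necropsies)
}

#' Construct a SpeciesCohort from raw tallies
#'
#' Computes prevalences and sampling weights from the counts and validates
#' the count nesting 0 <= malignant <= neoplasia <= necropsies.
#'
#' @param species_id character vector of species labels (must match the
#'   phylogeny tip labels used downstream)
#' @param n_necropsies,n_neoplasia,n_malignant integer tallies
#' @param longevity longevity in months; \code{NA} where unknown
#' @return a \code{\linkS4class{SpeciesCohort}}
#' @export
SpeciesCohort <- function(species_id, n_necropsies, n_neoplasia, n_malignant,
                          longevity = NA_real_) {
    n <- length(species_id)
    longevity <- rep_len(as.numeric(longevity), n)
    bad <- n_malignant > n_neoplasia | n_neoplasia > n_necropsies |
        n_malignant < 0
    if (any(bad))
        stop("count nesting violated for species: ",
             paste(species_id[bad], collapse = ", "), call. = FALSE)
    df <- data.frame(
        species_id = as.character(species_id),
        n_necropsies = as.integer(n_necropsies),
        n_neoplasia = as.integer(n_neoplasia),
        n_malignant = as.integer(n_malignant),
        longevity = longevity,
        neoplasia_prevalence = ifelse(n_necropsies > 0,
                                      n_neoplasia / n_necropsies, NA_real_),
        malignancy_prevalence = ifelse(n_necropsies > 0,
                                       n_malignant / n_necropsies, NA_real_),
        weight = ifelse(n_necropsies >= 1, 1 / sqrt(n_necropsies), NA_real_),
        stringsAsFactors = FALSE)
    rownames(df) <- NULL
    new("SpeciesCohort", records = df)
}

#' Read a species cohort table from TSV
#'
#' Expects a UTF-8 tab-delimited file with header columns
#' \code{species_id}, \code{n_necropsies}, \code{n_neoplasia},
#' \code{n_malignant}, \code{longevity_months} (empty cell = missing).
#'
#' @param path path to the TSV file
#' @return a \code{\linkS4class{SpeciesCohort}}
#' @export
readCohortTable <- function(path) {
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE,
                            na.strings = c("", "NA"))
    need <- c("species_id", "n_necropsies", "n_neoplasia", "n_malignant")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("cohort table ", path, " lacks columns: ",
             paste(miss, collapse = ", "), call. = FALSE)
    if (!"longevity_months" %in% names(df)) df$longevity_months <- NA_real_
    SpeciesCohort(df$species_id, df$n_necropsies, df$n_neoplasia,
                  df$n_malignant, df$longevity_months)
}

#' Write a cohort table to TSV
#'
#' @param cohort a \code{\linkS4class{SpeciesCohort}}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeCohortTable <- function(cohort, path) {
    stopifnot(is(cohort, "SpeciesCohort"))
    utils::write.table(cohortRecords(cohort), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Filter the cohort to adequately sampled species with observed cancer
#'
#' Retains species with at least \code{min_records} necropsies and with at
#' least one recorded neoplasia and (by default) at least one recorded
#' malignancy; zeros in well-sampled clades are treated as undersampling
#' artifacts rather than true absence of cancer. Every removed species is
#' logged with all reasons that apply, insufficient sampling first.
#'
#' @param cohort a \code{\linkS4class{SpeciesCohort}}
#' @param min_records minimum necropsy count (default 20)
#' @param require_malignant if \code{TRUE} (default) species with zero
#'   malignancies are excluded from the whole cohort, not just from
#'   malignancy models
#' @return a list with elements \code{cohort} (the filtered
#'   \code{SpeciesCohort}) and \code{exclusions} (a \code{data.frame} with
#'   columns \code{species_id}, \code{reason}; one row per species-reason
#'   pair)
#' @export
filterCohort <- function(cohort, min_records = 20, require_malignant = TRUE) {
    stopifnot(is(cohort, "SpeciesCohort"))
    df <- cohortRecords(cohort)
    reasons <- list(
        `insufficient necropsies` = df$n_necropsies < min_records,
        `zero neoplasia` = df$n_neoplasia == 0,
        `zero malignancy` = if (require_malignant) df$n_malignant == 0
                            else rep(FALSE, nrow(df)))
    drop <- Reduce(`|`, reasons)
    excl <- do.call(rbind, lapply(names(reasons), function(r) {
        idx <- which(reasons[[r]])
        if (!length(idx)) return(NULL)
        data.frame(species_id = df$species_id[idx], reason = r,
                   stringsAsFactors = FALSE)
    }))
    if (is.null(excl))
        excl <- data.frame(species_id = character(), reason = character(),
                           stringsAsFactors = FALSE)
    ## deterministic order: reason priority first, then species
    excl <- excl[order(match(excl$reason, names(reasons)), excl$species_id), ,
                 drop = FALSE]
    rownames(excl) <- NULL
    kept <- df[!drop, , drop = FALSE]
    if (nrow(kept) == 0L)
        stop("no species survive cohort filtering", call. = FALSE)
    rownames(kept) <- NULL
    list(cohort = new("SpeciesCohort", records = kept), exclusions = excl)
}

#' Write an exclusion log as JSON
#'
#' @param exclusions the \code{exclusions} element of
#'   \code{\link{filterCohort}}'s result
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeExclusionLog <- function(exclusions, path) {
    jsonlite::write_json(exclusions, path, dataframe = "rows", pretty = TRUE)
    invisible(path)
}
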