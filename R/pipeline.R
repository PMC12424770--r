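## End-to-end orchestration: predictor construction from annotation files,
## trait transformation, weighted PGLS across the four model families, AIC
## lambda comparison, and per-family FDR control.

.configDefaults <- list(
    cohort_filter = list(min_necropsies = 20, require_malignant = TRUE),
    thresholds = list(l1_consensus_length = 6100, l1_length_tolerance = 0.10,
                      sine_min_len = 100, sine_max_len = 400,
                      max_divergence = 5.0),
    distance_dialect = "gap",
    transform = list(grid_min = -2, grid_max = 2, grid_step = 0.025),
    fdr = list(q = 0.05, family = "per_table"),
    families = c("abundance", "proximity_mean", "proximity_median",
                 "genic_insertion", "cgo_load"),
    covariates = c("none", "longevity"),
    min_model_species = 10)

.mergeConfig <- function(config) {
    out <- .configDefaults
    for (nm in names(config)) {
        if (is.list(config[[nm]]) && is.list(out[[nm]]))
            out[[nm]][names(config[[nm]])] <- config[[nm]]
        else out[[nm]] <- config[[nm]]
    }
    out
}

#' Load and validate a pipeline configuration
#'
#' Accepts a YAML file path or an equivalent named list. Relative paths are
#' resolved against the YAML file's directory. Unspecified settings fall
#' back to the documented defaults (activity thresholds, 20-necropsy
#' cohort filter, gap distance dialect, Tukey grid -2..2 step 0.025, 5%
#' FDR per result table).
#'
#' @param config YAML path or named list
#' @return the normalised configuration list
#' @export
validateConfig <- function(config) {
    if (is.character(config)) {
        base <- dirname(normalizePath(config))
        config <- yaml::read_yaml(config)
        config$paths <- lapply(config$paths, function(p)
            if (startsWith(p, "/")) p else file.path(base, p))
    }
    config <- .mergeConfig(config)
    if (is.null(config$paths$tree) || is.null(config$paths$cohort))
        stop("config must name at least paths$tree and paths$cohort",
             call. = FALSE)
    for (nm in c("tree", "cohort", "cancer_genes", "orthogroups",
                 "orthogroup_counts")) {
        p <- config$paths[[nm]]
        if (!is.null(p) && !file.exists(p))
            stop("configured file missing: ", nm, " = ", p, call. = FALSE)
    }
    for (nm in c("repeats_dir", "genes_dir")) {
        p <- config$paths[[nm]]
        if (!is.null(p) && !dir.exists(p))
            stop("configured directory missing: ", nm, " = ", p,
                 call. = FALSE)
    }
    config
}

.speciesFile <- function(dir, sp, exts = c(".bed", ".out")) {
    for (e in exts) {
        p <- file.path(dir, paste0(sp, e))
        if (file.exists(p)) return(p)
    }
    NULL
}

#' Build the species-by-predictor table
#'
#' Reads the cohort, applies the necropsy filter, and computes every
#' genomic predictor available for each retained species: active-element
#' counts, IQR-trimmed proximity statistics to protein-coding genes and
#' CGOs, genic-insertion counts, and cancer-gene-ortholog category counts.
#' Species lacking an input (no gene annotation, absent from the
#' orthogroup tables) get \code{NA} in the affected columns and are
#' excluded per model, never globally.
#'
#' @param config a validated configuration (see \code{\link{validateConfig}})
#' @return a list: \code{table} (data.frame, rownames = species),
#'   \code{exclusions} (cohort exclusion log), \code{notes} (per-species
#'   data-availability messages)
#' @export
buildPredictorTable <- function(config) {
    config <- .mergeConfig(config)
    cohort <- readCohortTable(config$paths$cohort)
    filt <- filterCohort(cohort,
                         min_records = config$cohort_filter$min_necropsies,
                         require_malignant =
                             config$cohort_filter$require_malignant)
    df <- cohortRecords(filt$cohort)
    sp <- df$species_id
    th <- config$thresholds
    l1p <- list(consensus_length = th$l1_consensus_length,
                length_tolerance = th$l1_length_tolerance,
                max_divergence = th$max_divergence)
    sip <- list(min_len = th$sine_min_len, max_len = th$sine_max_len,
                max_divergence = th$max_divergence)
    dialect <- config$distance_dialect
    ## compute only what the configured model families consume
    need_genes <- any(c("proximity_mean", "proximity_median",
                        "genic_insertion") %in% config$families)
    need_cgo <- "cgo_load" %in% config$families

    ogs <- NULL
    cgo_tab <- NULL
    if (need_cgo && !is.null(config$paths$orthogroups) &&
        !is.null(config$paths$cancer_genes)) {
        ogs <- readOrthogroups(config$paths$orthogroups,
                               config$paths$orthogroup_counts)
        cg <- readCancerGeneTable(config$paths$cancer_genes)
        cgo_tab <- cgoProfiles(cg, ogs)
        rownames(cgo_tab) <- cgo_tab$species_id
    }

    notes <- character(0)
    na_block <- c(n_active_l1 = NA_real_, n_active_sine = NA_real_,
                  n_combined = NA_real_)
    prox_names <- as.vector(outer(
        c("prox_l1_pc", "prox_comb_pc", "prox_l1_cgo", "prox_comb_cgo"),
        c("median", "iqrmean"), paste, sep = "_"))
    genic_names <- c("genic_l1_pc", "genic_comb_pc", "genic_l1_cgo",
                     "genic_comb_cgo")
    cgo_names <- paste0("cgo_", c("total", "somatic", "germline",
                                  "oncogene", "tsg", "fusion"))

    rows <- lapply(sp, function(s) {
        out <- as.list(c(na_block,
                         stats::setNames(rep(NA_real_, length(prox_names)),
                                         prox_names),
                         stats::setNames(rep(NA_real_, length(genic_names)),
                                         genic_names),
                         stats::setNames(rep(NA_real_, length(cgo_names)),
                                         cgo_names)))
        rep_path <- if (!is.null(config$paths$repeats_dir))
            .speciesFile(config$paths$repeats_dir, s) else NULL
        if (is.null(rep_path)) {
            notes <<- c(notes, paste0(s, ": no repeat annotation"))
        } else {
            dial <- if (endsWith(rep_path, ".out")) "rmsk_out" else "bed"
            reps <- readRepeatAnnotation(rep_path, dialect = dial)
            cnt <- countActiveElements(reps, s, l1_params = l1p,
                                       sine_params = sip)
            out$n_active_l1 <- cnt$n_active_l1
            out$n_active_sine <- cnt$n_active_sine
            out$n_combined <- cnt$n_combined
            gene_path <- if (need_genes &&
                             !is.null(config$paths$genes_dir))
                .speciesFile(config$paths$genes_dir, s, ".bed") else NULL
            if (is.null(gene_path)) {
                if (need_genes)
                    notes <<- c(notes, paste0(s, ": no gene annotation"))
            } else {
                side <- file.path(config$paths$genes_dir,
                                  paste0(s, "_cgo.tsv"))
                genes <- readGeneBed(gene_path,
                                     cgo_path = if (file.exists(side)) side)
                cgo_genes <- genes[S4Vectors::mcols(genes)$is_cgo]
                act <- flagActive(reps, l1_params = l1p, sine_params = sip)
                fam <- S4Vectors::mcols(reps)$superfamily
                act_l1 <- reps[act & fam == "L1"]
                act_comb <- reps[act]
                fill <- function(active_set, targets, tag) {
                    if (!length(targets)) return()
                    if (length(active_set)) {
                        dd <- closestDistances(active_set, targets,
                                               dialect = dialect)$distances
                        if (any(!is.na(dd))) {
                            ps <- proximityStats(dd)
                            out[[paste0("prox_", tag, "_median")]] <<-
                                ps@median
                            out[[paste0("prox_", tag, "_iqrmean")]] <<-
                                ps@iqrMean
                        }
                        out[[paste0("genic_", tag)]] <<-
                            genicInsertionCount(active_set, targets)
                    }
                }
                fill(act_l1, genes, "l1_pc")
                fill(act_comb, genes, "comb_pc")
                fill(act_l1, cgo_genes, "l1_cgo")
                fill(act_comb, cgo_genes, "comb_cgo")
            }
        }
        if (!is.null(cgo_tab)) {
            if (s %in% rownames(cgo_tab)) {
                for (nm in c("total", "somatic", "germline", "oncogene",
                             "tsg", "fusion"))
                    out[[paste0("cgo_", nm)]] <- cgo_tab[s, nm]
            } else {
                notes <<- c(notes, paste0(s, ": absent from orthogroups"))
            }
        }
        as.data.frame(out)
    })
    tab <- do.call(rbind, rows)
    tab <- cbind(df[, c("neoplasia_prevalence", "malignancy_prevalence",
                        "longevity", "weight", "n_necropsies")], tab)
    rownames(tab) <- sp
    list(table = tab, exclusions = filt$exclusions, notes = notes)
}

#' The default model grid of the four model families
#'
#' One row per fitted model: family x response (neoplasia / malignancy
#' prevalence) x element set (L1-only / combined L1+SINE, where relevant)
#' x gene set (protein-coding genes / CGOs, for proximity and genic
#' insertion) x covariate (none / longevity).
#'
#' @param families subset of the five family names
#' @param covariates subset of \code{c("none", "longevity")}
#' @return data.frame with columns \code{model_id}, \code{family},
#'   \code{response}, \code{predictor}, \code{covariate}
#' @export
defaultModelGrid <- function(families = .configDefaults$families,
                             covariates = .configDefaults$covariates) {
    preds <- list(
        abundance = c("n_active_l1", "n_combined"),
        proximity_mean = paste0("prox_", c("l1_pc", "comb_pc", "l1_cgo",
                                           "comb_cgo"), "_iqrmean"),
        proximity_median = paste0("prox_", c("l1_pc", "comb_pc", "l1_cgo",
                                             "comb_cgo"), "_median"),
        genic_insertion = c("genic_l1_pc", "genic_comb_pc", "genic_l1_cgo",
                            "genic_comb_cgo"),
        cgo_load = paste0("cgo_", c("total", "somatic", "germline",
                                    "oncogene", "tsg", "fusion")))
    rows <- list()
    for (fam in intersect(names(preds), families))
        for (resp in c("neoplasia_prevalence", "malignancy_prevalence"))
            for (pr in preds[[fam]])
                for (cov in covariates)
                    rows[[length(rows) + 1L]] <- data.frame(
                        family = fam, response = resp, predictor = pr,
                        covariate = cov)
    grid <- do.call(rbind, rows)
    grid$model_id <- sprintf(
        "%s.%s.%s%s", grid$family,
        sub("_prevalence", "", grid$response), grid$predictor,
        ifelse(grid$covariate == "none", "", paste0("+", grid$covariate)))
    grid[, c("model_id", "family", "response", "predictor", "covariate")]
}

## Tukey-transform a named set of variables once, caching powers
.transformVariables <- function(tab, vars, grid) {
    out <- list()
    for (v in vars) {
        x <- tab[[v]]
        ok <- !is.na(x)
        tx <- rep(NA_real_, length(x))
        res <- tryCatch(tukeyTransform(x[ok], grid = grid),
                        error = function(e) NULL)
        if (is.null(res)) {
            tx[ok] <- x[ok]
            out[[v]] <- list(power = NA_real_, values = tx,
                             w = NA_real_, w_raw = NA_real_)
        } else {
            tx[ok] <- res$transformed
            out[[v]] <- list(power = res$power, values = tx,
                             w = res$w, w_raw = res$w_raw)
        }
    }
    out
}

#' Run the full comparative analysis
#'
#' Builds the predictor table, Tukey-transforms the response and predictor
#' variables, min-max normalises the predictors, and fits every model in
#' the configured grid by weighted PGLS with estimated Pagel's lambda
#' (1/sqrt(n) sampling weights), comparing lambda in {0, ML, 1} by AIC.
#' p-values of the focal predictor are FDR-adjusted within each family x
#' response table (Benjamini-Hochberg, 5% by default). Models whose data
#' are unavailable or degenerate are reported with an error status; the
#' batch never aborts.
#'
#' @param config YAML path or configuration list (see
#'   \code{\link{validateConfig}})
#' @param out_dir optional directory for \code{report.json} and
#'   \code{models.tsv}
#' @return a report list: \code{models} (one row per model), \code{fits}
#'   (named list of \code{\linkS4class{PglsFit}}s), \code{transforms},
#'   \code{correlations}, \code{exclusions}, \code{notes}, \code{n_species}
#' @export
runPipeline <- function(config, out_dir = NULL) {
    config <- validateConfig(config)
    built <- buildPredictorTable(config)
    tab <- built$table
    tree <- ape::read.tree(config$paths$tree)
    keep <- intersect(rownames(tab), tree$tip.label)
    if (length(keep) < 3)
        stop("fewer than 3 cohort species are tree tips", call. = FALSE)
    tab <- tab[keep, , drop = FALSE]
    C <- vcvFromTree(tree, keep)
    w_all <- stats::setNames(tab$weight, rownames(tab))

    grid <- defaultModelGrid(config$families, config$covariates)
    tgrid <- seq(config$transform$grid_min, config$transform$grid_max,
                 by = config$transform$grid_step)
    vars <- unique(c(grid$response, grid$predictor,
                     if ("longevity" %in% grid$covariate) "longevity"))
    vars <- vars[vars %in% names(tab)]
    trans <- .transformVariables(tab, vars, tgrid)

    fits <- list()
    rows <- lapply(seq_len(nrow(grid)), function(i) {
        g <- grid[i, ]
        row <- data.frame(
            model_id = g$model_id, family = g$family,
            response = g$response, predictor = g$predictor,
            covariate = g$covariate, n_species = NA_integer_,
            slope = NA_real_, slope_se = NA_real_, p = NA_real_,
            p_adj = NA_real_, lambda_hat = NA_real_, r2 = NA_real_,
            adj_r2 = NA_real_, aic_0 = NA_real_, aic_hat = NA_real_,
            aic_1 = NA_real_, shapiro_p = NA_real_, bp_p = NA_real_,
            max_vif = NA_real_, status = "ok", stringsAsFactors = FALSE)
        used <- c(g$response, g$predictor,
                  if (g$covariate == "longevity") "longevity")
        if (!all(used %in% names(trans))) {
            row$status <- "error: variable unavailable"
            return(row)
        }
        dat <- data.frame(row.names = rownames(tab))
        dat$y <- trans[[g$response]]$values
        dat$x <- trans[[g$predictor]]$values
        if (g$covariate == "longevity")
            dat$longevity <- trans[["longevity"]]$values
        dat <- dat[stats::complete.cases(dat), , drop = FALSE]
        if (nrow(dat) < config$min_model_species) {
            row$status <- sprintf("error: only %d usable species",
                                  nrow(dat))
            return(row)
        }
        res <- tryCatch({
            dat$x <- minmaxNormalize(dat$x)
            if (!is.null(dat$longevity))
                dat$longevity <- minmaxNormalize(dat$longevity)
            form <- if (g$covariate == "longevity") y ~ x + longevity
                    else y ~ x
            cmp <- compareLambdaModels(form, dat, C,
                                       weights = w_all[rownames(dat)])
            fit <- cmp$fits$lambdaML
            row$n_species <- fit@nobs
            row$slope <- unname(coef(fit)["x"])
            row$slope_se <- unname(fit@se["x"])
            row$p <- unname(pValues(fit)["x"])
            row$lambda_hat <- lambdaHat(fit)
            row$r2 <- rSquared(fit)
            row$adj_r2 <- rSquared(fit, adjusted = TRUE)
            row$aic_0 <- cmp$table$aic[cmp$table$model == "lambda0"]
            row$aic_hat <- cmp$table$aic[cmp$table$model == "lambdaML"]
            row$aic_1 <- cmp$table$aic[cmp$table$model == "lambda1"]
            dg <- fitDiagnostics(fit)
            row$shapiro_p <- dg$shapiro_p
            row$bp_p <- dg$bp_p
            row$max_vif <- if (is.null(dg$vif)) NA_real_ else max(dg$vif)
            fits[[g$model_id]] <<- fit
            row
        }, error = function(e) {
            row$status <- paste("error:", conditionMessage(e))
            row
        })
        res
    })
    models <- do.call(rbind, rows)

    ## BH-FDR within each family x response result table
    if (identical(config$fdr$family, "global")) {
        ok <- !is.na(models$p)
        if (any(ok))
            models$p_adj[ok] <- bhFdr(models$p[ok],
                                      config$fdr$q)$p_adjusted
    } else {
        for (key in unique(paste(models$family, models$response))) {
            sel <- paste(models$family, models$response) == key &
                !is.na(models$p)
            if (any(sel))
                models$p_adj[sel] <- bhFdr(models$p[sel],
                                           config$fdr$q)$p_adjusted
        }
    }

    transforms <- data.frame(
        variable = names(trans),
        power = vapply(trans, function(t) t$power, 0),
        w_before = vapply(trans, function(t) t$w_raw, 0),
        w_after = vapply(trans, function(t) t$w, 0),
        row.names = NULL)

    ## interrelationship panel among key predictors
    corr_pairs <- list(c("n_active_l1", "genic_l1_pc"),
                       c("n_combined", "genic_comb_pc"),
                       c("cgo_oncogene", "cgo_tsg"),
                       c("n_active_l1", "cgo_fusion"))
    correlations <- do.call(rbind, lapply(corr_pairs, function(pr) {
        if (!all(pr %in% names(tab))) return(NULL)
        ok <- stats::complete.cases(tab[, pr])
        if (sum(ok) < 3) return(NULL)
        r <- tryCatch(pearsonR(tab[ok, pr[1]], tab[ok, pr[2]]),
                      error = function(e) NA_real_)
        data.frame(var1 = pr[1], var2 = pr[2], n = sum(ok), r = r)
    }))

    report <- list(models = models, fits = fits, transforms = transforms,
                   correlations = correlations,
                   exclusions = built$exclusions, notes = built$notes,
                   n_species = nrow(tab))
    if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        jsonlite::write_json(
            report[c("models", "transforms", "correlations", "exclusions",
                     "notes", "n_species")],
            file.path(out_dir, "report.json"),
            dataframe = "rows", auto_unbox = TRUE, pretty = TRUE,
            digits = NA, na = "null")
        utils::write.table(models, file.path(out_dir, "models.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    report
}
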