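## Cancer-gene-ortholog load from OrthoFinder orthogroup tables.

#' Parse OrthoFinder orthogroup tables
#'
#' Reads the two text outputs of an orthogroup inference run:
#' \code{Orthogroups.tsv} (first column the orthogroup id, one column per
#' species, cells comma-separated gene identifiers) and
#' \code{Orthogroups.GeneCount.tsv} (same layout with integer counts and an
#' optional trailing \code{Total} column). The two files are
#' cross-validated: both must contain the same orthogroup identifiers and
#' the counts must equal the member-list lengths.
#'
#' @param groups_path path to \code{Orthogroups.tsv}
#' @param counts_path path to \code{Orthogroups.GeneCount.tsv}
#' @return a list: \code{species} (column names), \code{counts}
#'   (orthogroup x species integer matrix), \code{members} (named list of
#'   per-species gene-id lists), \code{gene2og} (named character vector
#'   mapping every member gene id to its orthogroup)
#' @export
readOrthogroups <- function(groups_path, counts_path) {
    grp <- utils::read.delim(groups_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             na.strings = NULL)
    cnt <- utils::read.delim(counts_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, check.names = FALSE)
    og_g <- grp[[1]]
    og_c <- cnt[[1]]
    if (length(setdiff(og_g, og_c)) || length(setdiff(og_c, og_g)))
        stop("orthogroup identifiers differ between files: ",
             paste(union(setdiff(og_g, og_c), setdiff(og_c, og_g)),
                   collapse = ", "), call. = FALSE)
    species <- setdiff(names(grp)[-1], "Total")
    cnt <- cnt[match(og_g, og_c), , drop = FALSE]
    counts <- as.matrix(cnt[, species, drop = FALSE])
    rownames(counts) <- og_g
    storage.mode(counts) <- "integer"
    members <- vector("list", length(og_g))
    names(members) <- og_g
    gene_ids <- character(0)
    gene_ogs <- character(0)
    for (i in seq_along(og_g)) {
        per_sp <- lapply(species, function(sp) {
            cell <- grp[i, sp]
            if (is.na(cell) || !nzchar(trimws(cell))) return(character(0))
            trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
        })
        names(per_sp) <- species
        nmem <- lengths(per_sp)
        bad <- which(nmem != counts[i, species])
        if (length(bad))
            stop("orthogroup ", og_g[i], ": gene count disagrees with ",
                 "member list for species ",
                 paste(species[bad], collapse = ", "), call. = FALSE)
        members[[i]] <- per_sp
        ids <- unlist(per_sp, use.names = FALSE)
        gene_ids <- c(gene_ids, ids)
        gene_ogs <- c(gene_ogs, rep(og_g[i], length(ids)))
    }
    gene2og <- gene_ogs
    names(gene2og) <- gene_ids
    list(species = species, counts = counts, members = members,
         gene2og = gene2og)
}

#' Read a cancer-gene metadata table
#'
#' Tab-separated with columns \code{symbol}, \code{protein_id},
#' \code{somatic}, \code{germline} (logical or 0/1), \code{role} (one of
#' \code{oncogene}, \code{tsg}, \code{both}, \code{other}) and \code{fusion}
#' (logical or 0/1) -- the fields exported by cancer gene census resources.
#'
#' @param path path to the TSV
#' @return a \code{data.frame} of cancer-gene entries
#' @export
readCancerGeneTable <- function(path) {
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    need <- c("symbol", "protein_id", "somatic", "germline", "role", "fusion")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("cancer-gene table lacks columns: ",
             paste(miss, collapse = ", "), call. = FALSE)
    df$somatic <- as.logical(df$somatic)
    df$germline <- as.logical(df$germline)
    df$fusion <- as.logical(df$fusion)
    badrole <- !df$role %in% c("oncogene", "tsg", "both", "other")
    if (any(badrole))
        stop("unknown role value(s): ",
             paste(unique(df$role[badrole]), collapse = ", "), call. = FALSE)
    usable <- df$somatic | df$germline
    if (any(!usable))
        warning(sum(!usable), " entries are neither somatic nor germline")
    df
}

#' Count cancer-gene orthologs for one species
#'
#' For each cancer gene, its contribution to a species is that species'
#' gene count in the orthogroup containing the gene's query protein (zero
#' when the protein is unassigned to any orthogroup). Counting is per gene:
#' two cancer genes collapsing into one orthogroup each contribute the full
#' species count (set \code{dedupe = TRUE} to count each orthogroup once,
#' with category flags OR-ed across its cancer genes, for sensitivity
#' analysis). Genes with role \code{"both"} contribute to both the oncogene
#' and the tumor-suppressor tallies.
#'
#' @param entries cancer-gene table (see \code{\link{readCancerGeneTable}})
#' @param orthogroups parsed tables (see \code{\link{readOrthogroups}})
#' @param species_id one of \code{orthogroups$species}
#' @param dedupe collapse cancer genes sharing an orthogroup?
#' @return one-row \code{data.frame}: \code{species_id}, \code{total},
#'   \code{somatic}, \code{germline}, \code{oncogene}, \code{tsg},
#'   \code{fusion}, \code{n_unresolved} (entries with no orthogroup)
#' @export
countCgo <- function(entries, orthogroups, species_id, dedupe = FALSE) {
    if (!species_id %in% orthogroups$species)
        stop("species ", species_id, " absent from orthogroup tables",
             call. = FALSE)
    og <- unname(orthogroups$gene2og[entries$protein_id])
    unresolved <- is.na(og)
    contrib <- numeric(nrow(entries))
    contrib[!unresolved] <-
        orthogroups$counts[og[!unresolved], species_id]
    flags <- data.frame(
        somatic = entries$somatic,
        germline = entries$germline,
        oncogene = entries$role %in% c("oncogene", "both"),
        tsg = entries$role %in% c("tsg", "both"),
        fusion = entries$fusion)
    if (dedupe) {
        keep <- !unresolved
        split_idx <- split(which(keep), og[keep])
        contrib_d <- vapply(split_idx, function(ix) contrib[ix[1]], 0)
        flags_d <- do.call(rbind, lapply(split_idx, function(ix) {
            as.data.frame(lapply(flags[ix, , drop = FALSE], any))
        }))
        total <- sum(contrib_d)
        cat_counts <- vapply(names(flags), function(f)
            sum(contrib_d[flags_d[[f]]]), 0)
    } else {
        total <- sum(contrib)
        cat_counts <- vapply(names(flags), function(f)
            sum(contrib[flags[[f]]]), 0)
    }
    data.frame(species_id = species_id, total = total,
               somatic = cat_counts[["somatic"]],
               germline = cat_counts[["germline"]],
               oncogene = cat_counts[["oncogene"]],
               tsg = cat_counts[["tsg"]],
               fusion = cat_counts[["fusion"]],
               n_unresolved = sum(unresolved),
               stringsAsFactors = FALSE)
}

#' Cancer-gene-ortholog profiles for all species
#'
#' @param entries,orthogroups,dedupe see \code{\link{countCgo}}
#' @return a \code{data.frame} with one \code{\link{countCgo}} row per
#'   species in the orthogroup tables
#' @export
cgoProfiles <- function(entries, orthogroups, dedupe = FALSE) {
    out <- do.call(rbind, lapply(orthogroups$species, function(sp)
        countCgo(entries, orthogroups, sp, dedupe = dedupe)))
    rownames(out) <- NULL
    out
}
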