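## Closest-feature distances and genic-insertion counts between active
## elements and gene sets, with IQR-trimmed summary statistics.

#' Build a gene GRanges
#'
#' @param chrom,start,end interval fields, 1-based closed coordinates
#' @param gene_id gene identifiers (kept in the \code{gene_id} metadata
#'   column)
#' @param is_cgo logical: is the gene a cancer-gene ortholog?
#' @param cgo_categories character vector of comma-separated category sets
#'   (subset of \code{somatic,germline,oncogene,tsg,fusion}); empty for
#'   non-CGO genes
#' @return a \code{GRanges} with \code{gene_id}, \code{is_cgo} and
#'   \code{cgo_categories} metadata columns
#' @export
geneGRanges <- function(chrom, start, end, gene_id, is_cgo = FALSE,
                        cgo_categories = "") {
    if (any(end < start)) stop("negative-width gene interval", call. = FALSE)
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start = start, end = end))
    n <- length(gr)
    is_cgo <- rep_len(is_cgo, n)
    cgo_categories <- rep_len(cgo_categories, n)
    if (any(!is_cgo & nzchar(cgo_categories)))
        stop("cgo_categories set for non-CGO gene", call. = FALSE)
    S4Vectors::mcols(gr)$gene_id <- as.character(gene_id)
    S4Vectors::mcols(gr)$is_cgo <- is_cgo
    S4Vectors::mcols(gr)$cgo_categories <- cgo_categories
    gr
}

#' Read gene intervals from BED, with an optional CGO sidecar table
#'
#' The BED file is BED6-like (0-based half-open) with the gene identifier in
#' the name column. CGO status comes from a tab-separated sidecar with
#' columns \code{gene_id} and \code{categories} (comma-separated subset of
#' \code{somatic,germline,oncogene,tsg,fusion}); genes absent from the
#' sidecar are non-CGO.
#'
#' @param path BED file of gene spans
#' @param cgo_path optional sidecar TSV flagging cancer-gene orthologs
#' @return a gene \code{GRanges} (see \code{\link{geneGRanges}})
#' @export
readGeneBed <- function(path, cgo_path = NULL) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
    if (!length(lines))
        return(geneGRanges(character(), integer(), integer(), character()))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 4))
        stop("malformed gene BED row (need >= 4 fields) at line ",
             which(nf < 4)[1], call. = FALSE)
    chrom <- vapply(parts, `[`, "", 1L)
    start0 <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
    end0 <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
    gene_id <- vapply(parts, `[`, "", 4L)
    bad <- which(is.na(start0) | is.na(end0) | end0 <= start0 | start0 < 0)
    if (length(bad))
        stop("malformed gene BED row at line ", bad[1], call. = FALSE)
    cats <- rep("", length(gene_id))
    if (!is.null(cgo_path)) {
        side <- utils::read.delim(cgo_path, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
        if (!all(c("gene_id", "categories") %in% names(side)))
            stop("CGO sidecar needs columns gene_id, categories",
                 call. = FALSE)
        m <- match(gene_id, side$gene_id)
        cats[!is.na(m)] <- side$categories[m[!is.na(m)]]
    }
    geneGRanges(chrom, start0 + 1, end0, gene_id,
                is_cgo = nzchar(cats), cgo_categories = cats)
}

#' Distance from each query element to its nearest gene
#'
#' For each query interval the distance to the closest target on the same
#' chromosome: 0 when they share at least one base, otherwise the edge gap
#' (bookended intervals have gap 0). Queries on chromosomes with no target
#' cannot be scored; they are returned as \code{NA} and counted, never given
#' a sentinel distance. Strand is ignored throughout.
#'
#' The \code{"gap1"} dialect reproduces closest-feature tools that report
#' gap + 1 for non-overlapping pairs (overlaps stay 0); relative
#' cross-species comparisons are unaffected by the choice.
#'
#' @param queries a repeat \code{GRanges} (typically the active elements)
#' @param targets a gene \code{GRanges}
#' @param dialect \code{"gap"} (default) or \code{"gap1"}
#' @return a list: \code{distances} (numeric, one per query, \code{NA} where
#'   no target shares the chromosome), \code{n_no_target} (number of
#'   \code{NA}s)
#' @export
closestDistances <- function(queries, targets, dialect = c("gap", "gap1")) {
    dialect <- match.arg(dialect)
    dist <- rep(NA_real_, length(queries))
    if (length(queries) && length(targets)) {
        ## disjoint chromosome sets are expected (flagged as NA below), so
        ## the seqlevel-mismatch warning carries no information here
        hits <- suppressWarnings(
            GenomicRanges::distanceToNearest(queries, targets,
                                             ignore.strand = TRUE))
        dist[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
        if (dialect == "gap1") {
            ov <- suppressWarnings(
                GenomicRanges::countOverlaps(queries, targets,
                                             ignore.strand = TRUE)) > 0
            bump <- !is.na(dist) & !ov
            dist[bump] <- dist[bump] + 1
        }
    }
    list(distances = dist, n_no_target = sum(is.na(dist)))
}

#' Number of active elements inserted within genes
#'
#' Counts query elements overlapping at least one gene by one or more
#' bases; an element overlapping several genes is counted once.
#'
#' @param active a repeat \code{GRanges} of active elements
#' @param genes a gene \code{GRanges}
#' @return integer count, at most \code{length(active)}
#' @export
genicInsertionCount <- function(active, genes) {
    if (!length(active) || !length(genes)) return(0L)
    sum(suppressWarnings(
        GenomicRanges::countOverlaps(active, genes,
                                     ignore.strand = TRUE)) > 0L)
}

#' IQR-trimmed summary of a distance distribution
#'
#' Genomic distance distributions are heavy-tailed, so the plain mean is
#' dominated by a few extreme values. This summary reports the median and
#' the mean computed inside the Tukey fences [Q1 - 1.5 IQR, Q3 + 1.5 IQR]
#' (inclusive), with quartiles by linear interpolation between order
#' statistics (position (n - 1) p, the default convention of mainstream
#' statistical software; configurable via \code{quantile_type}).
#'
#' @param distances numeric vector of distances in bases; \code{NA}s
#'   (unscorable queries) are dropped first
#' @param quantile_type quartile algorithm passed to
#'   \code{\link[stats]{quantile}} (default 7, linear interpolation)
#' @return a \code{\linkS4class{ProximityStats}}
#' @export
proximityStats <- function(distances, quantile_type = 7) {
    distances <- distances[!is.na(distances)]
    if (!length(distances))
        stop("no distances computable", call. = FALSE)
    qs <- stats::quantile(distances, c(0.25, 0.5, 0.75),
                          type = quantile_type, names = FALSE)
    iqr <- qs[3] - qs[1]
    lower <- qs[1] - 1.5 * iqr
    upper <- qs[3] + 1.5 * iqr
    keep <- distances >= lower & distances <= upper
    new("ProximityStats",
        n = length(distances), median = qs[2], q1 = qs[1], q3 = qs[3],
        iqr = iqr, lower = lower, upper = upper,
        iqrMean = mean(distances[keep]),
        nExcluded = sum(!keep))
}
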