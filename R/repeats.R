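## RepeatMasker-style annotation parsing and active-element classification.
##
## "Potentially active" means a recent, intact insertion: for L1 a
## near-consensus-length element (within +/-10% of the 6.1 kb consensus),
## for SINEs an element of 100-400 bp, both at <= 5% divergence from the
## family consensus. All bounds are inclusive.

.superfamilyFromClass <- function(cls) {
    out <- rep("other", length(cls))
    out[startsWith(cls, "LINE/L1")] <- "L1"
    out[startsWith(cls, "SINE")] <- "SINE"
    out
}

## the class/family string may be embedded in a BED name as "AluY#SINE/Alu"
.classFromName <- function(name) {
    has <- grepl("#", name, fixed = TRUE)
    name[has] <- sub("^[^#]*#", "", name[has])
    name
}

#' Read a repeat annotation into a GRanges
#'
#' Parses either native RepeatMasker \code{.out} output (space-aligned, three
#' header lines, 1-based inclusive coordinates) or the BED dialect produced
#' by \code{rmsk2bed}-style conversion (0-based half-open; the name column
#' carries the repeat class/family, optionally as
#' \code{"element#class/family"}; column 7 carries percent divergence).
#' Coordinates are normalised to the usual Bioconductor 1-based closed
#' \code{GRanges} convention, so a BED row \code{(100, 200)} and an
#' \code{.out} row \code{(101, 200)} yield the same 100-bp range.
#'
#' @param path annotation file
#' @param dialect \code{"bed"} or \code{"rmsk_out"}
#' @return a \code{GRanges} with metadata columns \code{superfamily}
#'   (\code{"L1"}, \code{"SINE"} or \code{"other"}), \code{divergence}
#'   (percent substitutions from consensus) and \code{repClass} (the raw
#'   class/family string)
#' @export
readRepeatAnnotation <- function(path, dialect = c("bed", "rmsk_out")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    if (dialect == "bed") .readRepeatBed(path) else .readRepeatOut(path)
}

.readRepeatBed <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
    if (!length(lines)) return(.emptyRepeatGRanges())
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 7))
        stop("malformed BED repeat row (need >= 7 fields) at line ",
             which(nf < 7)[1], call. = FALSE)
    chrom <- vapply(parts, `[`, "", 1L)
    start0 <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
    end0 <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
    name <- vapply(parts, `[`, "", 4L)
    strand <- vapply(parts, `[`, "", 6L)
    div <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 7L)))
    bad <- which(is.na(start0) | is.na(end0) | is.na(div) | end0 <= start0 |
                 start0 < 0 | div < 0)
    if (length(bad))
        stop("malformed BED repeat row at line ", bad[1], call. = FALSE)
    strand[!strand %in% c("+", "-")] <- "*"
    cls <- .classFromName(name)
    repeatGRanges(chrom, start0 + 1, end0, strand = strand,
                  repClass = cls, divergence = div)
}

.readRepeatOut <- function(path) {
    lines <- readLines(path, warn = FALSE)
    ## native output starts with two header lines and one blank line
    if (length(lines) >= 1 && grepl("^\\s*SW|^\\s*score", lines[1]))
        lines <- lines[-seq_len(min(3L, length(lines)))]
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(.emptyRepeatGRanges())
    parts <- strsplit(lines, "\\s+")
    nf <- lengths(parts)
    if (any(nf < 11))
        stop("malformed RepeatMasker .out row (need >= 11 fields) at line ",
             which(nf < 11)[1], call. = FALSE)
    getf <- function(i) vapply(parts, `[`, "", i)
    div <- suppressWarnings(as.numeric(getf(2L)))
    chrom <- getf(5L)
    begin <- suppressWarnings(as.numeric(getf(6L)))
    end <- suppressWarnings(as.numeric(getf(7L)))
    strand <- ifelse(getf(9L) == "C", "-", "+")
    cls <- getf(11L)
    bad <- which(is.na(div) | is.na(begin) | is.na(end) | end < begin |
                 begin < 1 | div < 0)
    if (length(bad))
        stop("malformed RepeatMasker .out row at line ", bad[1],
             call. = FALSE)
    repeatGRanges(chrom, begin, end, strand = strand, repClass = cls,
                  divergence = div)
}

.emptyRepeatGRanges <- function() {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        superfamily = character(), divergence = numeric(),
        repClass = character())
    gr
}

#' Build a repeat GRanges from parsed fields
#'
#' Low-level constructor shared by the file readers and the synthetic
#' landscape generator. Coordinates are 1-based closed.
#'
#' @param chrom,start,end,strand interval fields
#' @param repClass RepeatMasker class/family string (e.g. \code{"LINE/L1"})
#' @param divergence percent substitutions from the family consensus
#' @return a \code{GRanges} with \code{superfamily}, \code{divergence} and
#'   \code{repClass} metadata columns
#' @export
repeatGRanges <- function(chrom, start, end, strand = "*", repClass,
                          divergence) {
    if (any(end < start)) stop("negative-width repeat interval", call. = FALSE)
    if (any(divergence < 0)) stop("negative divergence", call. = FALSE)
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start = start, end = end),
                                 strand = strand)
    S4Vectors::mcols(gr)$superfamily <- .superfamilyFromClass(repClass)
    S4Vectors::mcols(gr)$divergence <- divergence
    S4Vectors::mcols(gr)$repClass <- repClass
    gr
}

#' Active-element predicates
#'
#' \code{isActiveL1} tests whether L1 records are full-length recent
#' insertions: annotated length within \code{length_tolerance} of the
#' consensus length and divergence at most \code{max_divergence} percent.
#' \code{isActiveSine} tests SINE records against an absolute length window.
#' Both bounds are inclusive at either end.
#'
#' @param gr a repeat \code{GRanges} containing only the relevant
#'   superfamily (an error otherwise, to catch misrouted records)
#' @param consensus_length L1 consensus length in bp (default 6100)
#' @param length_tolerance fractional window around the consensus
#'   (default 0.10, i.e. 5490-6710 bp)
#' @param min_len,max_len SINE length window in bp (default 100-400)
#' @param max_divergence maximum percent divergence (default 5)
#' @return logical vector, one element per record
#' @export
isActiveL1 <- function(gr, consensus_length = 6100, length_tolerance = 0.10,
                       max_divergence = 5.0) {
    if (length(gr) && any(S4Vectors::mcols(gr)$superfamily != "L1"))
        stop("isActiveL1 called on non-L1 records", call. = FALSE)
    len <- GenomicRanges::width(gr)
    lo <- (1 - length_tolerance) * consensus_length
    hi <- (1 + length_tolerance) * consensus_length
    len >= lo & len <= hi & S4Vectors::mcols(gr)$divergence <= max_divergence
}

#' @rdname isActiveL1
#' @export
isActiveSine <- function(gr, min_len = 100, max_len = 400,
                         max_divergence = 5.0) {
    if (length(gr) && any(S4Vectors::mcols(gr)$superfamily != "SINE"))
        stop("isActiveSine called on non-SINE records", call. = FALSE)
    len <- GenomicRanges::width(gr)
    len >= min_len & len <= max_len &
        S4Vectors::mcols(gr)$divergence <= max_divergence
}

#' Flag and extract potentially active elements
#'
#' \code{flagActive} returns one logical per record (always \code{FALSE} for
#' superfamilies other than L1/SINE); \code{activeElements} subsets the
#' input to the flagged records.
#'
#' @param gr a repeat \code{GRanges} (mixed superfamilies allowed)
#' @param ... thresholds passed on to \code{\link{isActiveL1}} and
#'   \code{\link{isActiveSine}}
#' @param l1_params,sine_params named lists of threshold overrides for the
#'   two predicates
#' @return \code{flagActive}: a logical vector; \code{activeElements}: a
#'   \code{GRanges}
#' @export
flagActive <- function(gr, l1_params = list(), sine_params = list()) {
    fam <- S4Vectors::mcols(gr)$superfamily
    out <- logical(length(gr))
    isl1 <- fam == "L1"
    issine <- fam == "SINE"
    if (any(isl1))
        out[isl1] <- do.call(isActiveL1, c(list(gr[isl1]), l1_params))
    if (any(issine))
        out[issine] <- do.call(isActiveSine, c(list(gr[issine]), sine_params))
    out
}

#' @rdname flagActive
#' @export
activeElements <- function(gr, ...) gr[flagActive(gr, ...)]

#' Count potentially active L1 and SINE elements
#'
#' Species in which no full-length L1 is detected still get a combined
#' L1+SINE burden equal to their SINE count, so the combined predictor is
#' defined for every species.
#'
#' @param gr a repeat \code{GRanges}
#' @param species_id species label attached to the output row
#' @param ... threshold overrides (see \code{\link{flagActive}})
#' @return one-row \code{data.frame} with columns \code{species_id},
#'   \code{n_active_l1}, \code{n_active_sine}, \code{n_combined}
#' @export
countActiveElements <- function(gr, species_id = NA_character_, ...) {
    act <- flagActive(gr, ...)
    fam <- S4Vectors::mcols(gr)$superfamily
    n_l1 <- sum(act & fam == "L1")
    n_sine <- sum(act & fam == "SINE")
    data.frame(species_id = species_id,
               n_active_l1 = n_l1, n_active_sine = n_sine,
               n_combined = n_l1 + n_sine,
               stringsAsFactors = FALSE)
}
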