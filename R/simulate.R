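## Seed-deterministic generators: phylogenies, lambda-structured traits,
## binomial necropsy tallies, and annotation landscapes with brute-force
## ground truth. The generators emit the exact file formats the pipeline
## reads, so fixtures and real runs share one code path.

.withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv()))
            get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(seed)
    }
    expr
}

#' Simulate a pure-birth ultrametric phylogeny
#'
#' A Yule tree with all tip depths equal, rescaled to unit depth. Tip labels
#' are \code{sp001, sp002, ...}. Deterministic for a given seed.
#'
#' @param n_taxa number of tips, >= 2
#' @param seed integer seed (\code{NULL} to use the current RNG state)
#' @return an \code{ape} \code{phylo} object
#' @export
simulateTree <- function(n_taxa, seed = NULL) {
    if (n_taxa < 2) stop("need at least 2 taxa", call. = FALSE)
    .withSeed(seed, {
        tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
        depth <- max(ape::node.depth.edgelength(tr))
        tr$edge.length <- tr$edge.length / depth
        tr$tip.label <- sprintf("sp%03d", seq_len(n_taxa))
        tr
    })
}

#' Simulate a trait vector under the PGLS generative model
#'
#' Draws \eqn{y \sim N(X\beta,\ \sigma^2 C(\lambda) + \mathrm{diag}(w^2))}:
#' the exact model assumed by \code{\link{fitPgls}}.
#'
#' @param C phylogenetic variance-covariance matrix (e.g. from
#'   \code{\link{vcvFromTree}})
#' @param lambda,sigma2 phylogenetic signal and Brownian rate of the
#'   residual process
#' @param beta coefficient vector (default 0: pure noise)
#' @param X design matrix (default an intercept column of zeros -- i.e.
#'   mean zero)
#' @param w per-species sampling-error standard deviations (default 0)
#' @param seed integer seed
#' @return numeric vector named by the rownames of \code{C}
#' @export
simulateTraits <- function(C, lambda, sigma2, beta = 0, X = NULL, w = 0,
                           seed = NULL) {
    n <- nrow(C)
    if (is.null(X)) X <- matrix(0, n, length(beta))
    if (ncol(X) != length(beta)) stop("dim mismatch", call. = FALSE)
    w <- rep_len(w, n)
    V <- sigma2 * lambdaTransform(C, lambda) + diag(w^2, n)
    mu <- drop(X %*% beta)
    if (max(abs(V)) == 0) {
        y <- mu
    } else {
        U <- tryCatch(chol(V), error = function(e)
            tryCatch(chol(V + diag(1e-10 * max(diag(V)), n)),
                     error = function(e2) NULL))
        if (is.null(U))
            stop("covariance is not positive semi-definite", call. = FALSE)
        y <- .withSeed(seed, mu + drop(crossprod(U, stats::rnorm(n))))
    }
    names(y) <- rownames(C)
    y
}

#' Simulate necropsy tallies from true prevalences
#'
#' Neoplasia counts are binomial in the necropsy total; malignant counts
#' are drawn as binomial subsets of the neoplasia counts, so the count
#' nesting malignant <= neoplasia <= necropsies holds by construction.
#'
#' @param neoplasia_prev per-species true neoplasia prevalence in [0, 1]
#' @param malignant_frac per-species fraction of neoplasia cases that are
#'   malignant (recycled)
#' @param n_necropsies per-species necropsy totals
#' @param seed integer seed
#' @return data.frame with columns \code{n_necropsies}, \code{n_neoplasia},
#'   \code{n_malignant}
#' @export
simulateNecropsies <- function(neoplasia_prev, malignant_frac = 0.5,
                               n_necropsies, seed = NULL) {
    if (any(neoplasia_prev < 0 | neoplasia_prev > 1))
        stop("prevalences must lie in [0, 1]", call. = FALSE)
    k <- length(neoplasia_prev)
    malignant_frac <- rep_len(malignant_frac, k)
    .withSeed(seed, {
        neo <- stats::rbinom(k, n_necropsies, neoplasia_prev)
        mal <- stats::rbinom(k, neo, malignant_frac)
        data.frame(n_necropsies = n_necropsies, n_neoplasia = neo,
                   n_malignant = mal)
    })
}

## brute-force O(n*m) edge-gap distances between 1-based closed intervals;
## the independent oracle used for generator ground truth
.bruteGap <- function(qs, qe, ts, te) {
    vapply(seq_along(qs), function(i) {
        if (!length(ts)) return(NA_real_)
        g <- pmax(ts - qe[i] - 1, qs[i] - te - 1, 0)
        min(g)
    }, 0)
}

#' Simulate a genome annotation landscape with known ground truth
#'
#' Places gene and repeat intervals uniformly on a single synthetic
#' chromosome. Active elements get lengths inside the activity windows
#' (L1: 5490-6710 bp around the 6.1 kb consensus; SINE: 100-400 bp) and
#' divergence <= 5%; inactive elements are constructed to violate at least
#' one criterion (wrong length, excess divergence, or both). The returned
#' truth record carries exact active counts, genic-insertion counts and
#' nearest-gene distances computed by an independent brute-force scan, so
#' pipeline outputs can be checked exactly.
#'
#' @param genome_length chromosome length in bp
#' @param n_genes,n_l1,n_sine interval counts
#' @param active_frac_l1,active_frac_sine fraction of elements generated as
#'   active (the generated count is \code{round(frac * n)})
#' @param gene_length gene span in bp (default 5000)
#' @param cgo_frac fraction of genes flagged as cancer-gene orthologs
#' @param seed integer seed
#' @param chrom chromosome name
#' @return a list: \code{repeats} (repeat \code{GRanges}, shuffled order),
#'   \code{genes} (gene \code{GRanges}), and \code{truth} (list with
#'   \code{n_active_l1}, \code{n_active_sine}, \code{n_combined},
#'   \code{active} flags aligned to \code{repeats}, \code{genic_pc},
#'   \code{genic_cgo}, \code{dist_pc}, \code{dist_cgo} -- distances of
#'   active elements to the nearest gene / CGO by brute force)
#' @export
simulateRepeatLandscape <- function(genome_length = 2e6, n_genes = 60,
                                    n_l1 = 80, n_sine = 120,
                                    active_frac_l1 = 0.3,
                                    active_frac_sine = 0.3,
                                    gene_length = 5000, cgo_frac = 0.25,
                                    seed = NULL, chrom = "chr1") {
    need <- n_genes * gene_length + n_l1 * 6710 + n_sine * 1000
    if (need > genome_length)
        stop("intervals do not fit in genome_length (need >= ", need,
             " bp)", call. = FALSE)
    .withSeed(seed, {
        n_act_l1 <- as.integer(round(active_frac_l1 * n_l1))
        n_act_sine <- as.integer(round(active_frac_sine * n_sine))

        mkLens <- function(n_act, n_tot, act_lo, act_hi, bad_lo, bad_hi) {
            n_in <- n_tot - n_act
            len <- integer(n_tot)
            div <- numeric(n_tot)
            act <- logical(n_tot)
            act[seq_len(n_act)] <- TRUE
            len[act] <- sample(act_lo:act_hi, n_act, replace = TRUE)
            div[act] <- stats::runif(n_act, 0, 5)
            if (n_in > 0) {
                mode <- sample(c("len", "div", "both"), n_in, replace = TRUE)
                badlen <- sample(bad_lo:bad_hi, n_in, replace = TRUE)
                len[!act] <- ifelse(mode == "div",
                                    sample(act_lo:act_hi, n_in,
                                           replace = TRUE), badlen)
                div[!act] <- ifelse(mode == "len",
                                    stats::runif(n_in, 0, 5),
                                    stats::runif(n_in, 5.5, 30))
            }
            list(len = len, div = div, act = act)
        }
        l1 <- mkLens(n_act_l1, n_l1, 5490, 6710, 500, 5400)
        si <- mkLens(n_act_sine, n_sine, 100, 400, 450, 1000)

        len <- c(l1$len, si$len)
        div <- c(l1$div, si$div)
        act <- c(l1$act, si$act)
        cls <- c(rep("LINE/L1", n_l1), rep("SINE/Alu", n_sine))
        start <- vapply(len, function(l)
            sample.int(genome_length - l, 1), 0L)
        reps <- repeatGRanges(chrom, start, start + len - 1L,
                              strand = sample(c("+", "-"), length(len),
                                              replace = TRUE),
                              repClass = cls, divergence = div)
        ord <- sample(length(reps))
        reps <- reps[ord]
        act <- act[ord]

        gstart <- vapply(rep(gene_length, n_genes), function(l)
            sample.int(genome_length - l, 1), 0L)
        is_cgo <- seq_len(n_genes) %in%
            sample.int(n_genes, round(cgo_frac * n_genes))
        cats <- ifelse(is_cgo, "somatic,oncogene", "")
        genes <- geneGRanges(chrom, gstart, gstart + gene_length - 1L,
                             gene_id = sprintf("g%04d", seq_len(n_genes)),
                             is_cgo = is_cgo, cgo_categories = cats)

        ## brute-force truth on the active subset
        qs <- GenomicRanges::start(reps)[act]
        qe <- GenomicRanges::end(reps)[act]
        gs <- GenomicRanges::start(genes)
        ge <- GenomicRanges::end(genes)
        cg <- S4Vectors::mcols(genes)$is_cgo
        dist_pc <- .bruteGap(qs, qe, gs, ge)
        dist_cgo <- .bruteGap(qs, qe, gs[cg], ge[cg])
        overlaps <- function(ts, te)
            vapply(seq_along(qs), function(i)
                any(ts <= qe[i] & te >= qs[i]), TRUE)
        truth <- list(
            n_active_l1 = n_act_l1, n_active_sine = n_act_sine,
            n_combined = n_act_l1 + n_act_sine, active = act,
            genic_pc = sum(overlaps(gs, ge)),
            genic_cgo = sum(overlaps(gs[cg], ge[cg])),
            dist_pc = dist_pc, dist_cgo = dist_cgo)
        list(repeats = reps, genes = genes, truth = truth)
    })
}

#' Write a repeat GRanges in the BED dialect the pipeline reads
#'
#' BED6+1: 0-based half-open coordinates, the class/family string in the
#' name column, percent divergence in column 7.
#'
#' @param gr repeat \code{GRanges}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeRepeatBed <- function(gr, path) {
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr),
        name = S4Vectors::mcols(gr)$repClass,
        score = 0L,
        strand = sub("\\*", "+", as.character(GenomicRanges::strand(gr))),
        divergence = S4Vectors::mcols(gr)$divergence)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write a gene GRanges as BED plus a CGO sidecar TSV
#'
#' @param gr gene \code{GRanges}
#' @param path BED output path
#' @param cgo_path sidecar TSV path (\code{gene_id}, \code{categories});
#'   written only for genes flagged as CGOs
#' @return \code{path}, invisibly
#' @export
writeGeneBed <- function(gr, path, cgo_path = NULL) {
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr),
        name = S4Vectors::mcols(gr)$gene_id,
        score = 0L, strand = "+")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    if (!is.null(cgo_path)) {
        m <- S4Vectors::mcols(gr)
        side <- data.frame(gene_id = m$gene_id[m$is_cgo],
                           categories = m$cgo_categories[m$is_cgo])
        utils::write.table(side, cgo_path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

#' Simulate a complete comparative-oncology study and write its fileset
#'
#' Generates an ultrametric phylogeny, per-species repeat/gene annotation
#' landscapes, necropsy tallies whose true neoplasia prevalence increases
#' with the species' combined active L1+SINE burden, longevity values, a
#' cancer-gene table with orthogroup assignments, and a ready-to-run
#' pipeline configuration. Every file is plain text in the format the
#' corresponding reader expects.
#'
#' The generative model for prevalence is
#' \code{prev = base + effect * minmax(combined active count) + eta},
#' with \code{eta} a lambda-structured phylogenetic deviation
#' (\code{lambda_true}, sd \code{phylo_sd}) and the result clamped to
#' [0.01, 0.95]; malignant cases are a binomial fraction
#' \code{malignant_frac} of neoplasia cases.
#'
#' @param dir output directory (created if needed)
#' @param n_species number of species
#' @param seed integer seed; every random draw derives from it
#' @param base,effect intercept and slope of true prevalence on the
#'   min-max-normalised combined active count (defaults 0.05 and 0.35)
#' @param lambda_true,phylo_sd phylogenetic signal and sd of the
#'   prevalence deviation (defaults 0.5 and 0.05)
#' @param malignant_frac fraction of neoplasia cases that progress to
#'   malignancy (default 0.45)
#' @param landscape named list of overrides passed to
#'   \code{\link{simulateRepeatLandscape}} (sizes only; per-species active
#'   fractions are drawn internally)
#' @param n_cancer_genes number of cancer genes in the orthogroup tables
#' @return a list: \code{dir}, \code{config} (path to \code{config.yaml}),
#'   \code{truth} (per-species true counts, prevalences and the generative
#'   parameters)
#' @export
simulateStudy <- function(dir, n_species = 55, seed = 1,
                          base = 0.05, effect = 0.35,
                          lambda_true = 0.5, phylo_sd = 0.05,
                          malignant_frac = 0.45,
                          landscape = list(), n_cancer_genes = 40) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    dir.create(file.path(dir, "repeats"), showWarnings = FALSE)
    dir.create(file.path(dir, "genes"), showWarnings = FALSE)
    dir.create(file.path(dir, "cgo"), showWarnings = FALSE)

    tree <- simulateTree(n_species, seed = seed)
    sp <- tree$tip.label
    ape::write.tree(tree, file.path(dir, "tree.nwk"))
    C <- vcvFromTree(tree)

    .withSeed(seed + 1L, {
        ls_defaults <- list(genome_length = 2e6, n_genes = 60, n_l1 = 80,
                            n_sine = 120, gene_length = 5000,
                            cgo_frac = 0.25)
        ls_defaults[names(landscape)] <- landscape
        frac_l1 <- stats::runif(n_species, 0.05, 0.6)
        frac_sine <- stats::runif(n_species, 0.05, 0.6)
        land_seeds <- sample.int(.Machine$integer.max - 1L, n_species)
        combined <- integer(n_species)
        for (i in seq_len(n_species)) {
            land <- do.call(simulateRepeatLandscape,
                            c(ls_defaults,
                              list(active_frac_l1 = frac_l1[i],
                                   active_frac_sine = frac_sine[i],
                                   seed = land_seeds[i])))
            combined[i] <- land$truth$n_combined
            writeRepeatBed(land$repeats,
                           file.path(dir, "repeats",
                                     paste0(sp[i], ".bed")))
            writeGeneBed(land$genes,
                         file.path(dir, "genes", paste0(sp[i], ".bed")),
                         cgo_path = file.path(dir, "genes",
                                              paste0(sp[i], "_cgo.tsv")))
        }

        a <- minmaxNormalize(combined)
        eta <- simulateTraits(C, lambda = lambda_true, sigma2 = phylo_sd^2,
                              seed = NULL)
        prev <- pmin(pmax(base + effect * a + eta, 0.01), 0.95)
        n_nec <- 20L + stats::rnbinom(n_species, mu = 80, size = 2)
        tallies <- simulateNecropsies(prev, malignant_frac, n_nec)
        longevity <- round(exp(stats::rnorm(n_species, log(200), 0.5)))
        cohort <- data.frame(species_id = sp,
                             n_necropsies = tallies$n_necropsies,
                             n_neoplasia = tallies$n_neoplasia,
                             n_malignant = tallies$n_malignant,
                             longevity_months = longevity)
        utils::write.table(cohort, file.path(dir, "cohort.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)

        ## cancer genes + orthogroup tables with known per-species counts
        genes <- data.frame(
            symbol = sprintf("CG%03d", seq_len(n_cancer_genes)),
            protein_id = sprintf("ENSP%05d", seq_len(n_cancer_genes)),
            somatic = stats::runif(n_cancer_genes) < 0.8,
            germline = stats::runif(n_cancer_genes) < 0.3,
            role = sample(c("oncogene", "tsg", "both", "other"),
                          n_cancer_genes, replace = TRUE,
                          prob = c(0.4, 0.35, 0.1, 0.15)),
            fusion = stats::runif(n_cancer_genes) < 0.3)
        genes$somatic <- genes$somatic | !genes$germline
        utils::write.table(genes, file.path(dir, "cgo", "cancer_genes.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        ogids <- sprintf("OG%07d", seq_len(n_cancer_genes))
        cnts <- matrix(stats::rpois(n_cancer_genes * n_species, 1.2),
                       n_cancer_genes, n_species,
                       dimnames = list(ogids, sp))
        memb <- vapply(seq_len(n_cancer_genes), function(i) {
            paste(vapply(seq_len(n_species), function(j) {
                if (cnts[i, j] == 0) return("")
                paste(sprintf("%s_g%03d_%d", sp[j], i,
                              seq_len(cnts[i, j])), collapse = ", ")
            }, ""), collapse = "\t")
        }, "")
        og_lines <- c(paste(c("Orthogroup", sp), collapse = "\t"),
                      paste(ogids, vapply(seq_len(n_cancer_genes),
                            function(i) {
                ## the query protein is a member of its own orthogroup
                cells <- strsplit(memb[i], "\t", fixed = TRUE)[[1]]
                cells <- c(cells, rep("", n_species - length(cells)))
                paste(cells, collapse = "\t")
            }, ""), sep = "\t"))
        ## append the human query proteins as an extra species column so
        ## each cancer gene's protein id resolves to its orthogroup
        og_lines[1] <- paste(og_lines[1], "query", sep = "\t")
        og_lines[-1] <- paste(og_lines[-1], genes$protein_id, sep = "\t")
        writeLines(og_lines, file.path(dir, "cgo", "Orthogroups.tsv"))
        cnt_df <- data.frame(Orthogroup = ogids, cnts, query = 1L,
                             check.names = FALSE)
        cnt_df$Total <- rowSums(cnt_df[, c(sp, "query")])
        utils::write.table(cnt_df,
                           file.path(dir, "cgo",
                                     "Orthogroups.GeneCount.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)

        config <- list(
            seed = seed,
            paths = list(
                tree = "tree.nwk", cohort = "cohort.tsv",
                repeats_dir = "repeats", genes_dir = "genes",
                cancer_genes = "cgo/cancer_genes.tsv",
                orthogroups = "cgo/Orthogroups.tsv",
                orthogroup_counts = "cgo/Orthogroups.GeneCount.tsv"),
            cohort_filter = list(min_necropsies = 20,
                                 require_malignant = TRUE),
            distance_dialect = "gap",
            fdr = list(q = 0.05))
        yaml::write_yaml(config, file.path(dir, "config.yaml"))

        list(dir = dir, config = file.path(dir, "config.yaml"),
             truth = list(species = sp, combined_active = combined,
                          true_prevalence = prev,
                          cgo_counts = cnts,
                          base = base, effect = effect,
                          lambda_true = lambda_true, phylo_sd = phylo_sd,
                          malignant_frac = malignant_frac))
    })
}
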