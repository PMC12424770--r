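rgr <- function(chrom, s, e) {
    repeatGRanges(chrom, s, e, repClass = "LINE/L1",
                  divergence = rep(1, length(s)))
}
ggr <- function(chrom, s, e) {
    geneGRanges(chrom, s, e, gene_id = sprintf("g%d", seq_along(s)))
}

test_that("closest distance follows the edge-gap convention", {
    ## spec'd on 0-based half-open intervals; GRanges below are the 1-based
    ## closed equivalents of [10,20), [15,30), [25,40), [20,30)
    q <- rgr("c", 11, 20)
    expect_equal(closestDistances(q, ggr("c", 16, 30))$distances, 0)
    expect_equal(closestDistances(q, ggr("c", 26, 40))$distances, 5)
    ## bookended: shares no base, gap 0
    expect_equal(
        closestDistances(q, ggr("c", c(21, 101), c(30, 200)))$distances, 0)
    ## gap1 dialect bumps non-overlapping distances by one
    expect_equal(
        closestDistances(q, ggr("c", 26, 40), dialect = "gap1")$distances, 6)
    expect_equal(
        closestDistances(q, ggr("c", 16, 30), dialect = "gap1")$distances, 0)
    ## no target on the query's chromosome: flagged, not sentinel-valued
    res <- closestDistances(rgr(c("c", "d"), c(11, 11), c(20, 20)),
                            ggr("c", 26, 40))
    expect_equal(res$distances, c(5, NA))
    expect_equal(res$n_no_target, 1)
})

test_that("genic insertion counts each repeat at most once", {
    expect_equal(genicInsertionCount(rgr("c", 11, 20), ggr("c", 16, 30)), 1)
    ## one repeat overlapping two genes still counts once
    expect_equal(
        genicInsertionCount(rgr("c", 11, 60),
                            ggr("c", c(16, 41), c(30, 80))), 1)
    expect_equal(
        genicInsertionCount(rgr("c", 11, 20), ggr("c", 100, 200)), 0)
    expect_equal(genicInsertionCount(rgr("c", 11, 20), ggr("c", 1, 10)[0]), 0)
})

test_that("distances and genic counts match a brute-force all-pairs scan", {
    set.seed(101)
    n_trials <- 250
    for (trial in seq_len(n_trials)) {
        q <- randomIntervals(sample.int(60, 1))
        t <- randomIntervals(sample.int(60, 1))
        qg <- rgr(q$chrom, q$start, q$end)
        tg <- ggr(t$chrom, t$start, t$end)
        got <- closestDistances(qg, tg)$distances
        want <- bruteClosest(q$chrom, q$start, q$end,
                             t$chrom, t$start, t$end)
        expect_identical(got, want)
        expect_identical(genicInsertionCount(qg, tg),
                         bruteGenicCount(q$chrom, q$start, q$end,
                                         t$chrom, t$start, t$end))
    }
})

test_that("distances are translation-invariant", {
    set.seed(55)
    q <- randomIntervals(40)
    t <- randomIntervals(40)
    d0 <- closestDistances(rgr(q$chrom, q$start, q$end),
                           ggr(t$chrom, t$start, t$end))$distances
    shift <- 12345
    d1 <- closestDistances(rgr(q$chrom, q$start + shift, q$end + shift),
                           ggr(t$chrom, t$start + shift,
                               t$end + shift))$distances
    expect_identical(d0, d1)
})

test_that("proximity stats use interpolated quartiles and Tukey fences", {
    ## symmetric, no outliers: trimmed mean equals the plain mean
    ps <- proximityStats(1:9)
    expect_equal(ps@median, 5)
    expect_equal(iqrMean(ps), 5)
    expect_equal(ps@nExcluded, 0L)
    ## hand-computed: quartiles at positions (9-1)*0.25 = 2 and 6 (0-based)
    ps2 <- proximityStats(c(0, 10, 20, 30, 40, 50, 60, 70, 1000))
    expect_equal(ps2@q1, 20)
    expect_equal(ps2@q3, 60)
    expect_equal(ps2@iqr, 40)
    expect_equal(ps2@lower, -40)
    expect_equal(ps2@upper, 120)
    expect_equal(ps2@median, 40)
    expect_equal(iqrMean(ps2), 35)
    expect_equal(ps2@nExcluded, 1L)
    ## degenerate single value
    ps3 <- proximityStats(7)
    expect_equal(ps3@median, 7)
    expect_equal(ps3@iqr, 0)
    expect_equal(iqrMean(ps3), 7)
    expect_error(proximityStats(numeric(0)), "no distances")
    expect_error(proximityStats(c(NA_real_, NA_real_)), "no distances")
})

test_that("trimmed mean stays within the retained range; equals mean when
          no outliers", {
    set.seed(77)
    for (i in 1:50) {
        d <- rexp(sample(3:80, 1)) * 1000
        ps <- proximityStats(d)
        kept <- d[d >= ps@lower & d <= ps@upper]
        expect_gte(iqrMean(ps), min(kept))
        expect_lte(iqrMean(ps), max(kept))
        if (ps@nExcluded == 0L)
            expect_equal(iqrMean(ps), mean(d), tolerance = 1e-9)
    }
})

test_that("landscape truth distances equal pipeline distances exactly", {
    for (seed in c(11, 29)) {
        land <- simulateRepeatLandscape(n_l1 = 50, n_sine = 70,
                                        n_genes = 40, seed = seed)
        act <- activeElements(land$repeats)
        d <- closestDistances(act, land$genes)$distances
        expect_identical(d, land$truth$dist_pc)
        cg <- land$genes[S4Vectors::mcols(land$genes)$is_cgo]
        expect_identical(closestDistances(act, cg)$distances,
                         land$truth$dist_cgo)
        expect_identical(genicInsertionCount(act, land$genes),
                         land$truth$genic_pc)
        expect_identical(genicInsertionCount(act, cg),
                         land$truth$genic_cgo)
    }
})
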