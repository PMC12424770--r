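mkRepeat <- function(len, div, cls = "LINE/L1", start = 1000) {
    repeatGRanges("chr1", start, start + len - 1, repClass = cls,
                  divergence = div)
}

test_that("BED and .out dialects normalise to the same coordinates", {
    bed <- tempfile(fileext = ".bed")
    writeLines(paste(
        c("chr1\t100\t200\tL1MA1#LINE/L1\t0\t+\t2.1",
          "chr1\t500\t800\tAluY#SINE/Alu\t0\t-\t1.0",
          "chr2\t10\t60\tERVK-1#LTR/ERVK\t0\t+\t3.0"), collapse = "\n"), bed)
    grb <- readRepeatAnnotation(bed, "bed")
    out <- tempfile(fileext = ".out")
    writeLines(c(
        "   SW  perc perc perc  query      position in query",
        "score  div. del. ins.  sequence   begin end (left)",
        "",
        " 1000   2.1  0.0  0.0  chr1   101  200 (0) +  L1MA1  LINE/L1    1  100  (0)   1",
        "  900   1.0  0.0  0.0  chr1   501  800 (0) C  AluY   SINE/Alu   1  300  (0)   2",
        "  800   3.0  0.0  0.0  chr2    11   60 (0) +  ERVK-1 LTR/ERVK   1   50  (0)   3"),
        out)
    gro <- readRepeatAnnotation(out, "rmsk_out")
    expect_equal(GenomicRanges::start(grb), GenomicRanges::start(gro))
    expect_equal(GenomicRanges::width(grb), GenomicRanges::width(gro))
    expect_equal(GenomicRanges::width(grb), c(100, 300, 50))
    expect_equal(S4Vectors::mcols(grb)$superfamily,
                 c("L1", "SINE", "other"))
    expect_equal(S4Vectors::mcols(gro)$superfamily,
                 c("L1", "SINE", "other"))
    expect_equal(S4Vectors::mcols(grb)$divergence, c(2.1, 1.0, 3.0))
})

test_that("malformed annotation rows are rejected with a line number", {
    bed <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t100\t200\tLINE/L1\t0\t+\t2.0",
                 "chr1\t300\t250\tLINE/L1\t0\t+\t2.0"), bed)
    expect_error(readRepeatAnnotation(bed, "bed"), "line 2")
    bed2 <- tempfile(fileext = ".bed")
    writeLines("chr1\t100\t200\tLINE/L1", bed2)
    expect_error(readRepeatAnnotation(bed2, "bed"), "7 fields")
    expect_error(readRepeatAnnotation(tempfile(), "bed"), "no such file")
})

test_that("L1 activity window is +/-10% of the 6.1 kb consensus, <=5% div", {
    expect_true(isActiveL1(mkRepeat(6100, 2.0)))
    expect_false(isActiveL1(mkRepeat(5489, 2.0)))  # lower bound is 5490
    expect_true(isActiveL1(mkRepeat(5490, 2.0)))
    expect_true(isActiveL1(mkRepeat(6710, 5.0)))   # both bounds inclusive
    expect_false(isActiveL1(mkRepeat(6711, 2.0)))
    expect_false(isActiveL1(mkRepeat(6100, 5.1)))
    expect_error(isActiveL1(mkRepeat(300, 1, cls = "SINE/Alu")), "non-L1")
})

test_that("SINE activity window is 100-400 bp inclusive, <=5% div", {
    s <- function(len, div) mkRepeat(len, div, cls = "SINE/MIR")
    expect_true(isActiveSine(s(300, 1.0)))
    expect_false(isActiveSine(s(99, 1.0)))
    expect_true(isActiveSine(s(100, 1.0)))
    expect_true(isActiveSine(s(400, 5.0)))
    expect_false(isActiveSine(s(401, 1.0)))
    expect_false(isActiveSine(s(300, 5.01)))
    expect_error(isActiveSine(mkRepeat(6100, 1)), "non-SINE")
})

test_that("active counts are order-invariant with combined = L1 + SINE", {
    gr <- c(mkRepeat(6100, 2), mkRepeat(6100, 9), mkRepeat(2000, 1),
            mkRepeat(300, 1, "SINE/Alu"), mkRepeat(120, 4.9, "SINE/MIR"),
            mkRepeat(350, 2, "SINE/Alu"), mkRepeat(350, 8, "SINE/Alu"),
            mkRepeat(500, 1, "SINE/Alu"),
            mkRepeat(700, 1, "LTR/ERVK"))
    cnt <- countActiveElements(gr, "spX")
    expect_equal(cnt$n_active_l1, 1)
    expect_equal(cnt$n_active_sine, 3)
    expect_equal(cnt$n_combined, 4)
    set.seed(42)
    for (i in 1:5) {
        cnt2 <- countActiveElements(gr[sample(length(gr))], "spX")
        expect_identical(cnt2, cnt)
    }
    ## no L1s at all: combined still equals the SINE count
    sines <- gr[S4Vectors::mcols(gr)$superfamily == "SINE"]
    cnt3 <- countActiveElements(sines, "spY")
    expect_equal(cnt3$n_active_l1, 0)
    expect_equal(cnt3$n_combined, cnt3$n_active_sine)
    ## empty input
    cnt0 <- countActiveElements(gr[0], "spZ")
    expect_equal(unlist(cnt0[, -1]), c(n_active_l1 = 0, n_active_sine = 0,
                                       n_combined = 0))
})

test_that("counts equal generator ground truth across seeded landscapes", {
    for (seed in c(1, 7, 23)) {
        land <- simulateRepeatLandscape(n_l1 = 40, n_sine = 60,
                                        n_genes = 30, seed = seed)
        cnt <- countActiveElements(land$repeats, "s")
        expect_equal(cnt$n_active_l1, land$truth$n_active_l1)
        expect_equal(cnt$n_active_sine, land$truth$n_active_sine)
        expect_equal(cnt$n_combined, land$truth$n_combined)
        expect_equal(flagActive(land$repeats), land$truth$active)
    }
})

test_that("repeat BED writer round-trips through the reader", {
    land <- simulateRepeatLandscape(n_l1 = 20, n_sine = 30, n_genes = 10,
                                    seed = 3)
    p <- tempfile(fileext = ".bed")
    writeRepeatBed(land$repeats, p)
    back <- readRepeatAnnotation(p, "bed")
    expect_equal(GenomicRanges::start(back),
                 GenomicRanges::start(land$repeats))
    expect_equal(S4Vectors::mcols(back)$superfamily,
                 S4Vectors::mcols(land$repeats)$superfamily)
    expect_equal(S4Vectors::mcols(back)$divergence,
                 S4Vectors::mcols(land$repeats)$divergence,
                 tolerance = 1e-10)
})
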