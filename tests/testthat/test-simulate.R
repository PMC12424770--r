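test_that("pure-birth trees are ultrametric and seed-deterministic", {
    tr <- simulateTree(2, seed = 1)
    expect_equal(length(tr$tip.label), 2)
    expect_equal(tr$edge.length[1], tr$edge.length[2])
    for (n in c(5, 40)) {
        t1 <- simulateTree(n, seed = 9)
        depths <- ape::node.depth.edgelength(t1)[seq_len(n)]
        expect_lt(diff(range(depths)), 1e-9)
        t2 <- simulateTree(n, seed = 9)
        expect_identical(ape::write.tree(t1), ape::write.tree(t2))
        t3 <- simulateTree(n, seed = 10)
        expect_false(identical(ape::write.tree(t1), ape::write.tree(t3)))
    }
    expect_error(simulateTree(1), "at least 2")
})

test_that("trait simulation honours its target covariance", {
    tr <- simulateTree(8, seed = 21)
    C <- vcvFromTree(tr)
    ## degenerate: no noise at all returns the mean exactly
    X <- cbind(1, seq_len(8))
    y0 <- simulateTraits(C, lambda = 0.5, sigma2 = 0, beta = c(1, 2),
                         X = X, w = 0)
    expect_equal(unname(y0), drop(X %*% c(1, 2)))
    ## Monte-Carlo covariance matches sigma2 C(lambda) + diag(w2)
    w <- seq(0.1, 0.8, length.out = 8)
    V <- 0.7 * lambdaTransform(C, 0.4) + diag(w^2)
    set.seed(22)
    Y <- replicate(4000, as.vector(
        simulateTraits(C, lambda = 0.4, sigma2 = 0.7, w = w)))
    emp <- cov(t(Y))
    expect_lt(max(abs(emp - V)), 0.05 * max(abs(V)) + 0.02)
    ## lambda = 0: off-diagonals near zero
    set.seed(23)
    Y0 <- replicate(4000, as.vector(
        simulateTraits(C, lambda = 0, sigma2 = 1)))
    emp0 <- cov(t(Y0))
    off <- emp0[row(emp0) != col(emp0)]
    expect_lt(max(abs(off)), 0.1)
})

test_that("necropsy tallies are nested binomials at the right rates", {
    out0 <- simulateNecropsies(c(0, 1), malignant_frac = 0.5,
                               n_necropsies = c(50, 50), seed = 3)
    expect_equal(out0$n_neoplasia, c(0, 50))
    expect_equal(out0$n_malignant[1], 0)
    big <- simulateNecropsies(0.25, 0.4, 10000, seed = 4)
    expect_lt(abs(big$n_neoplasia / 10000 - 0.25), 0.02)
    expect_lt(abs(big$n_malignant / big$n_neoplasia - 0.4), 0.03)
    set.seed(5)
    many <- simulateNecropsies(runif(200), runif(200),
                               sample(20:500, 200, TRUE))
    expect_true(all(many$n_malignant <= many$n_neoplasia))
    expect_true(all(many$n_neoplasia <= many$n_necropsies))
    expect_error(simulateNecropsies(1.2, 0.5, 10), "\\[0, 1\\]")
})

test_that("landscape generator is deterministic and packing-checked", {
    l1 <- simulateRepeatLandscape(n_l1 = 30, n_sine = 40, n_genes = 20,
                                  seed = 6)
    l2 <- simulateRepeatLandscape(n_l1 = 30, n_sine = 40, n_genes = 20,
                                  seed = 6)
    expect_identical(GenomicRanges::start(l1$repeats),
                     GenomicRanges::start(l2$repeats))
    expect_identical(l1$truth, l2$truth)
    expect_error(simulateRepeatLandscape(genome_length = 1e4), "fit")
    ## zero active fraction: the pipeline counts must be all zero
    l0 <- simulateRepeatLandscape(n_l1 = 30, n_sine = 40, n_genes = 10,
                                  active_frac_l1 = 0, active_frac_sine = 0,
                                  seed = 7)
    cnt <- countActiveElements(l0$repeats, "s")
    expect_equal(cnt$n_combined, 0)
})

test_that("classification recovers generator truth on many seeded
          landscapes", {
    for (seed in seq_len(30)) {
        land <- simulateRepeatLandscape(n_l1 = 25, n_sine = 35,
                                        n_genes = 15,
                                        active_frac_l1 = runif(1),
                                        active_frac_sine = runif(1),
                                        seed = seed)
        cnt <- countActiveElements(land$repeats, "s")
        expect_equal(cnt$n_active_l1, land$truth$n_active_l1)
        expect_equal(cnt$n_active_sine, land$truth$n_active_sine)
    }
})

test_that("study fileset is complete, readable, and truth-consistent", {
    st <- localStudy(n_species = 8, seed = 33)
    expect_true(file.exists(st$config))
    cfg <- validateConfig(st$config)
    co <- readCohortTable(cfg$paths$cohort)
    expect_equal(length(co), 8)
    tr <- ape::read.tree(cfg$paths$tree)
    expect_setequal(tr$tip.label, speciesNames(co))
    ## per-species combined counts re-derived from the emitted BED files
    for (i in c(1, 5)) {
        sp <- st$truth$species[i]
        reps <- readRepeatAnnotation(
            file.path(st$dir, "repeats", paste0(sp, ".bed")), "bed")
        cnt <- countActiveElements(reps, sp)
        expect_equal(cnt$n_combined, st$truth$combined_active[i])
    }
    ## same seed regenerates byte-identical files
    st2 <- localStudy(n_species = 8, seed = 33)
    f1 <- file.path(st$dir, "cohort.tsv")
    f2 <- file.path(st2$dir, "cohort.tsv")
    expect_identical(readLines(f1), readLines(f2))
})
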