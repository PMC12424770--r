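test_that("phylogenetic VCV encodes shared path lengths", {
    ## ((A:1,B:1):1,C:2); shared root-to-MRCA path of A,B is 1
    tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
    C <- vcvFromTree(tr)
    expect_equal(C[c("A", "B", "C"), c("A", "B", "C")],
                 matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3,
                        dimnames = list(c("A", "B", "C"),
                                        c("A", "B", "C"))))
    ## subsetting prunes and reorders
    C2 <- vcvFromTree(tr, c("C", "A"))
    expect_equal(rownames(C2), c("C", "A"))
    expect_equal(unname(diag(C2)), c(2, 2))
    expect_error(vcvFromTree(tr, c("A", "Z")), "Z")
    ## ultrametric trees have a constant diagonal
    tu <- simulateTree(20, seed = 2)
    expect_lt(diff(range(diag(vcvFromTree(tu)))), 1e-9)
})

test_that("lambda transform scales only the off-diagonal", {
    C <- vcvFromTree(simulateTree(10, seed = 4))
    expect_equal(lambdaTransform(C, 1), C)
    C0 <- lambdaTransform(C, 0)
    expect_equal(C0, diag(diag(C)), ignore_attr = TRUE)
    Ch <- lambdaTransform(C, 0.5)
    off <- row(C) != col(C)
    expect_equal(Ch[off], C[off] / 2)
    expect_equal(diag(Ch), diag(C))
    expect_error(lambdaTransform(C, 1.2), "lambda")
    expect_error(lambdaTransform(C, -0.1), "lambda")
})

test_that("AIC is -2 logLik + 2k", {
    expect_equal(aicScore(0, 2), 4)
    expect_equal(aicScore(-10, 3), 26)
    expect_equal(aicScore(5, 3) - aicScore(5, 2), 2)
    expect_error(aicScore(0, 0), "k")
})

test_that("lambda = 0 with equal weights reduces to OLS", {
    tr <- simulateTree(40, seed = 31)
    C <- vcvFromTree(tr)
    set.seed(32)
    df <- data.frame(x = rnorm(40), row.names = tr$tip.label)
    df$y <- 1 + 2 * df$x + rnorm(40)
    ols <- coef(lm(y ~ x, df))
    for (w in list(NULL, rep(0.3, 40))) {
        fit <- fitPgls(y ~ x, df, C, weights = w, lambda = 0)
        expect_equal(unname(coef(fit)), unname(ols), tolerance = 1e-8)
    }
})

test_that("lambda = 1 with zero weights matches a direct GLS solve", {
    tr <- simulateTree(35, seed = 41)
    C <- vcvFromTree(tr)
    set.seed(42)
    df <- data.frame(x = rnorm(35), row.names = tr$tip.label)
    df$y <- 0.5 - 1.5 * df$x +
        as.vector(simulateTraits(C, lambda = 1, sigma2 = 1, seed = 43))
    fit <- fitPgls(y ~ x, df, C, lambda = 1)
    want <- bruteGls(df$y, cbind(1, df$x), C)
    expect_equal(unname(coef(fit)), drop(want), tolerance = 1e-8)
})

test_that("noiseless data are interpolated exactly with R2 = 1", {
    tr <- simulateTree(20, seed = 51)
    C <- vcvFromTree(tr)
    df <- data.frame(x = seq_len(20) / 10, row.names = tr$tip.label)
    df$y <- 2 * df$x
    fit <- fitPgls(y ~ x, df, C, lambda = 0.5)
    expect_equal(unname(coef(fit)), c(0, 2), tolerance = 1e-6)
    expect_equal(rSquared(fit), 1, tolerance = 1e-6)
})

test_that("likelihood nesting: estimated lambda dominates fixed lambda", {
    tr <- simulateTree(30, seed = 61)
    C <- vcvFromTree(tr)
    set.seed(62)
    for (lam_true in c(0, 0.6, 1)) {
        df <- data.frame(x = rnorm(30), row.names = tr$tip.label)
        df$y <- df$x + as.vector(
            simulateTraits(C, lambda = lam_true, sigma2 = 0.5))
        cmp <- compareLambdaModels(y ~ x, df, C)
        ll <- cmp$table$loglik
        names(ll) <- cmp$table$model
        expect_gte(ll["lambdaML"] + 1e-6, ll["lambda0"])
        expect_gte(ll["lambdaML"] + 1e-6, ll["lambda1"])
        ## one extra parameter for the estimated-lambda model
        expect_equal(cmp$table$k[cmp$table$model == "lambdaML"],
                     cmp$table$k[cmp$table$model == "lambda0"] + 1)
        ## boundary estimate reproduces the fixed fit exactly
        hat <- cmp$table$lambda[cmp$table$model == "lambdaML"]
        if (hat == 0)
            expect_equal(ll[["lambdaML"]], ll[["lambda0"]],
                         tolerance = 1e-9)
    }
})

test_that("sampling-error weights shrink the influence of noisy species", {
    tr <- simulateTree(50, seed = 71)
    C <- vcvFromTree(tr)
    set.seed(72)
    df <- data.frame(x = rnorm(50), row.names = tr$tip.label)
    w <- samplingWeight(sample(c(20, 500), 50, replace = TRUE))
    names(w) <- tr$tip.label
    df$y <- 0.8 * df$x + as.vector(
        simulateTraits(C, lambda = 0.5, sigma2 = 0.2, w = w, seed = 73))
    fit <- fitPgls(y ~ x, df, C, weights = w)
    expect_true(fit@tau2Estimated)
    expect_gt(fit@tau2, 0)
    ## strict mode pins tau2 = 1 and drops a parameter
    fit2 <- fitPgls(y ~ x, df, C, weights = w, tau = "fixed")
    expect_equal(fit2@tau2, 1)
    expect_equal(fit2@k, fit@k - 1L)
    ## both recover the slope to reasonable accuracy
    expect_lt(abs(coef(fit)["x"] - 0.8), 0.35)
})

test_that("rank-deficient designs and unknown species are rejected", {
    tr <- simulateTree(15, seed = 81)
    C <- vcvFromTree(tr)
    df <- data.frame(x = rnorm(15), row.names = tr$tip.label)
    df$x2 <- df$x
    df$y <- rnorm(15)
    expect_error(fitPgls(y ~ x + x2, df, C), "rank deficient")
    rownames(df)[1] <- "missing_tip"
    expect_error(fitPgls(y ~ x, df, C), "missing_tip")
})

test_that("BH-FDR matches the step-up formula", {
    expect_equal(bhFdr(0.03)$p_adjusted, 0.03)
    expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04))$p_adjusted,
                 rep(0.04, 4))
    expect_equal(bhFdr(rep(1, 5))$p_adjusted, rep(1, 5))
    expect_false(any(bhFdr(rep(1, 5))$reject))
    set.seed(91)
    for (i in 1:20) {
        p <- runif(sample(2:40, 1))^2
        adj <- bhFdr(p)$p_adjusted
        expect_equal(adj, bruteBH(p), tolerance = 1e-12)
        ## monotone non-decreasing in raw-p order
        expect_true(all(diff(adj[order(p)]) >= -1e-12))
    }
    expect_error(bhFdr(c(0.5, 1.2)), "0, 1")
})

test_that("VIF flags collinearity and reports Inf for duplicates", {
    set.seed(95)
    n <- 100
    x1 <- rnorm(n)
    x2 <- rnorm(n)
    v <- vifScores(cbind(a = x1, b = x2))
    expect_true(all(v < 1.5))
    x3 <- x1 + rnorm(n, sd = 0.01)
    v2 <- vifScores(cbind(a = x1, c = x3))
    expect_gt(v2["a"], 5)
    r2 <- summary(lm(x1 ~ x3))$r.squared
    expect_equal(unname(v2["a"]), 1 / (1 - r2), tolerance = 1e-9)
    expect_equal(unname(vifScores(cbind(x1, x1))), c(Inf, Inf))
    expect_error(vifScores(cbind(x1)), "two predictors")
})

test_that("Pearson correlation behaves at the limits", {
    x <- rnorm(20)
    expect_equal(pearsonR(x, 2 * x), 1)
    expect_equal(pearsonR(x, -x), -1)
    set.seed(99)
    a <- rnorm(10000)
    b <- rnorm(10000)
    expect_lt(abs(pearsonR(a, b)), 0.05)
    expect_error(pearsonR(x, rep(1, 20)), "constant")
    expect_error(pearsonR(x, rnorm(5)), "length")
})

test_that("model diagnostics are reported on normalized residuals", {
    tr <- simulateTree(60, seed = 111)
    C <- vcvFromTree(tr)
    set.seed(112)
    df <- data.frame(x = rnorm(60), z = rnorm(60),
                     row.names = tr$tip.label)
    df$y <- df$x + 0.5 * df$z +
        as.vector(simulateTraits(C, lambda = 0.5, sigma2 = 0.3))
    fit <- fitPgls(y ~ x + z, df, C)
    dg <- fitDiagnostics(fit)
    expect_true(dg$shapiro_p > 0 && dg$shapiro_p <= 1)
    expect_true(dg$bp_p > 0 && dg$bp_p <= 1)
    expect_named(dg$vif, c("x", "z"))
    expect_equal(length(residuals(fit, "normalized")), 60)
    expect_equal(fitted(fit) + residuals(fit), df$y, ignore_attr = TRUE)
    expect_equal(rSquared(fit, adjusted = TRUE),
                 1 - (1 - rSquared(fit)) * 59 / 57, tolerance = 1e-12)
})
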