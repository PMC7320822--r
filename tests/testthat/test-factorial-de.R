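test_that("ANOVA matches the brute-force projection oracle on balanced designs", {
    for (seed in 1:5) {
        dat <- randomBalancedData(seed)
        m <- matrix(dat$y, 1, dimnames = list("f1", dat$design$sample_id))
        fit <- fitFactorialAnova(m, design = dat$design)
        oracle <- anovaProjectionOracle(dat$y, dat$design)
        expect_equal(unname(fit$ss["f1", oracle$terms]),
                     unname(oracle$ss), tolerance = 1e-8)
        expect_equal(unname(fit$F["f1", oracle$terms]),
                     unname(oracle$F), tolerance = 1e-8)
        expect_equal(unname(fit$p["f1", oracle$terms]),
                     unname(oracle$p), tolerance = 1e-8)
        expect_equal(fit$residual_ss[["f1"]], oracle$residual_ss,
                     tolerance = 1e-8)
        expect_equal(fit$residual_df, oracle$residual_df)
        # dfs partition n - 1
        expect_equal(sum(fit$df) + fit$residual_df, nrow(dat$design) - 1L)
    }
})

test_that("a planted single-factor effect is detected on the right term only", {
    d <- makeDesign(2, 2, 2, 2)
    set.seed(77)
    y <- ifelse(d$location == "L2", 2, 0) + rnorm(16, 0, 1e-6)
    m <- matrix(y, 1, dimnames = list("f1", d$sample_id))
    fit <- fitFactorialAnova(m, design = d)
    expect_lt(fit$p["f1", "location"], 1e-10)
    expect_true(all(fit$p["f1", setdiff(colnames(fit$p), "location")] > 0.01))
})

test_that("null features give uniform p-values for every term", {
    d <- makeDesign(2, 2, 2, 2)
    set.seed(123)
    m <- matrix(rnorm(300 * 16), 300, dimnames = list(
        sprintf("f%03d", 1:300), d$sample_id))
    fit <- fitFactorialAnova(m, design = d)
    for (term in fit$terms) {
        ks <- suppressWarnings(ks.test(fit$p[, term], "punif"))
        expect_gt(ks$p.value, 0.001)
    }
})

test_that("the model refuses saturation and single-level factors", {
    d <- makeDesign(2, 2, 2, 1)
    m <- matrix(rnorm(16), 2, dimnames = list(c("a", "b"), d$sample_id))
    expect_error(fitFactorialAnova(m, design = d), "saturated")
    d2 <- makeDesign(2, 2, 2, 2)
    d2$variety <- factor("V1")
    m2 <- matrix(rnorm(nrow(d2)), 1, dimnames = list("a", d2$sample_id))
    expect_error(fitFactorialAnova(m2, design = d2), "fewer than 2 levels")
})

test_that("BH adjustment reproduces the step-up computation", {
    expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(adjustBH(0.5), 0.5)
    set.seed(4)
    p <- runif(50)
    adj <- adjustBH(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # order-preserving: adjusted values non-decreasing in p
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    expect_error(adjustBH(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("fold changes are max level-mean gaps, invariant to sample order", {
    d <- makeDesign(3, 2, 2, 1)
    lv <- as.integer(d$location)  # used to craft level means 0 / 1 / 3 on variety
    means <- c(0, 1, 3)[as.integer(d$variety)]
    m <- rbind(f1 = means, f2 = rep(1, nrow(d)))
    colnames(m) <- d$sample_id
    fc <- computeGroupFoldChanges(m, "variety", design = d)
    expect_equal(unname(fc["f1"]), 3)
    expect_equal(unname(fc["f2"]), 0)
    perm <- sample(nrow(d))
    fcP <- computeGroupFoldChanges(m[, perm], "variety", design = d)
    expect_equal(fcP, fc)
})

test_that("differential calls respect alpha and the SD fold-change filter", {
    d <- simulateDesign(simulationConfig(design = c(3, 3, 6, 2)))
    sim <- simulateDEFeatures(d, nFeatures = 600, nDE = 40,
                              factorName = "location", effect = 2,
                              noiseSd = 1, seed = 10)
    fit <- fitFactorialAnova(sim$ose)
    fcs <- lapply(stats::setNames(nm = c("variety", "location", "stage")),
                  function(f) computeGroupFoldChanges(sim$ose, f))
    de <- selectDifferentialFeatures(fit, fcs, alpha = 0.01, sdMult = 2)
    loc <- de[de$factor == "location", ]
    called <- loc$feature_id[loc$is_de]
    sens <- mean(names(sim$deTruth)[sim$deTruth] %in% called)
    fdr <- if (length(called))
        mean(!called %in% names(sim$deTruth)[sim$deTruth]) else 0
    expect_gte(sens, 0.9)
    expect_lte(fdr, 0.05)

    all <- selectDifferentialFeatures(fit, fcs, alpha = 1, sdMult = 0)
    expect_true(all(all$is_de))
    none <- selectDifferentialFeatures(fit, fcs, alpha = 1, sdMult = Inf)
    expect_false(any(none$is_de))
    s <- attr(de, "summary")
    expect_named(s$n_de, c("variety", "location", "stage"))
})
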