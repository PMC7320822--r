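test_that("MI attains ln B on identical vectors and is symmetric", {
    set.seed(12)
    x <- rnorm(1000)
    expect_equal(estimateMI(x, x, bins = 10), log(10), tolerance = 1e-12)
    y <- rnorm(1000)
    expect_equal(estimateMI(x, y), estimateMI(y, x), tolerance = 1e-12)
    expect_gte(estimateMI(x, y), 0)
    expect_warning(mi0 <- estimateMI(rep(1, 20), rnorm(20)), "constant")
    expect_equal(mi0, 0)
    expect_error(estimateMI(x[1:5], y[1:5]), "at least 8")
})

test_that("the estimator's null bias is small at the default binning", {
    set.seed(13)
    mis <- replicate(60, estimateMI(rnorm(1000), rnorm(1000)))
    expect_lt(mean(mis), 0.05)
})

test_that("threshold calibration is monotone and matches bulk quantiles", {
    t4 <- calibrateMiThreshold(200, pTarget = 1e-4, nPerm = 3000, seed = 2)
    t8 <- calibrateMiThreshold(200, pTarget = 1e-8, nPerm = 3000, seed = 2)
    expect_gt(t8, t4)
    tMed <- calibrateMiThreshold(200, pTarget = 0.5, nPerm = 3000, seed = 2)
    set.seed(31)
    null <- intermod:::.sampleNullMI(200, intermod:::.defaultBins(200), 3000)
    expect_lt(abs(tMed - median(null)), 0.01)
    expect_error(calibrateMiThreshold(200, nPerm = 500), ">= 1000")
    # tail p-values at the threshold reproduce the target
    expect_equal(miTailP(as.numeric(t8), t8), 1e-8, tolerance = 0.2)
})

test_that("regulator networks recover planted sigmoid targets", {
    set.seed(17)
    n <- 108
    reg <- rnorm(n)
    sig <- scale(1 / (1 + exp(-3 * scale(reg))))[, 1]
    m <- rbind(
        regulator = reg,
        t(vapply(1:5, function(i) 2 * sig + rnorm(n, 0, 0.5),
                 numeric(n))),
        t(vapply(1:60, function(i) rnorm(n), numeric(n))))
    rownames(m) <- c("regulator", paste0("tgt", 1:5), paste0("bg", 1:60))
    colnames(m) <- paste0("s", 1:n)
    thr <- calibrateMiThreshold(n, pTarget = 1e-3, nPerm = 20000, seed = 3)
    net <- buildRegulatorNetwork(m, "regulator", thr)
    hits <- miEdges(net)$target
    expect_true(all(paste0("tgt", 1:5) %in% hits))
    expect_lte(sum(grepl("^bg", hits)), 3)   # ~0.06 expected false edges

    none <- buildRegulatorNetwork(m, "regulator", Inf)
    expect_equal(nrow(miEdges(none)), 0L)

    dup <- rbind(m, copy = m["regulator", ])
    netDup <- buildRegulatorNetwork(dup, "regulator", thr)
    e <- miEdges(netDup)
    B <- intermod:::.defaultBins(n)
    expect_equal(e$mi[e$target == "copy"], log(B), tolerance = 1e-12)

    expect_warning(
        empty <- buildRegulatorNetwork(m, "absent", thr),
        "no regulators")
    expect_equal(nrow(miEdges(empty)), 0L)
})

test_that("DPI removes the indirect edge of a Markov chain and is idempotent", {
    set.seed(23)
    correct <- 0
    for (rep in 1:25) {
        n <- 400
        x <- rnorm(n)
        y <- x + rnorm(n, 0, 0.6)
        z <- y + rnorm(n, 0, 0.6)
        m <- rbind(x = x, y = y, z = z)
        colnames(m) <- paste0("s", 1:n)
        net <- buildRegulatorNetwork(m, c("x", "y", "z"), threshold = 0)
        net <- applyDPI(net)
        e <- miEdges(net)
        key <- paste(pmin(e$regulator, e$target), pmax(e$regulator, e$target))
        kept <- e$kept_after_dpi
        if (!kept[key == "x z"] && kept[key == "x y"] && kept[key == "y z"])
            correct <- correct + 1
        # idempotence: a second pass on the kept subgraph removes nothing
        sub <- net
        sub@edges <- e[kept, , drop = FALSE]
        again <- applyDPI(sub)
        expect_true(all(miEdges(again)$kept_after_dpi))
    }
    expect_gte(correct / 25, 0.9)
})

test_that("DPI leaves triangle-free networks and tolerance 1 untouched", {
    edges <- data.frame(regulator = c("r", "r"), target = c("a", "b"),
                        mi = c(0.5, 0.2), p = NA_real_,
                        kept_after_dpi = NA)
    net <- new("MiNetwork", edges = edges, regulators = "r",
               module = "m", miThreshold = 0, pThreshold = NA_real_)
    expect_true(all(miEdges(applyDPI(net))$kept_after_dpi))

    tri <- data.frame(regulator = c("r", "r", "a"), target = c("a", "b", "b"),
                      mi = c(0.5, 0.1, 0.4), p = NA_real_,
                      kept_after_dpi = NA)
    netT <- new("MiNetwork", edges = tri, regulators = c("r", "a"),
                module = "m", miThreshold = 0, pThreshold = NA_real_)
    expect_true(all(miEdges(applyDPI(netT, tolerance = 1))$kept_after_dpi))
    pruned <- miEdges(applyDPI(netT))
    expect_equal(pruned$kept_after_dpi, c(TRUE, FALSE, TRUE))
})
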