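test_that("unsigned adjacency follows |r|^beta with unit diagonal", {
    set.seed(1)
    base <- rnorm(30)
    m <- rbind(a = base, b = base, c = rnorm(30))
    colnames(m) <- paste0("s", 1:30)
    net <- computeAdjacency(m, beta = 6)
    expect_equal(unname(net$adjacency["a", "b"]), 1)
    expect_equal(diag(net$adjacency), c(a = 1, b = 1, c = 1))
    r <- abs(cor(m["a", ], m["c", ]))
    expect_equal(unname(net$adjacency["a", "c"]), r^6, tolerance = 1e-12)
    # monotone decreasing in beta for |r| < 1
    net2 <- computeAdjacency(m, beta = 12)
    expect_lt(net2$adjacency["a", "c"], net$adjacency["a", "c"])
    mm <- rbind(m, flat = rep(1, 30))
    expect_error(computeAdjacency(mm, beta = 6), "flat")
})

test_that("TOM agrees with the triple-loop oracle and its closed-form cases", {
    ids <- paste0("f", 1:3)
    ones <- matrix(1, 3, 3, dimnames = list(ids, ids))
    netOnes <- structure(list(adjacency = ones, beta = 1), class = "coexNetwork")
    expect_true(all(computeTOM(netOnes)$tom == 1))

    eye <- diag(3); dimnames(eye) <- list(ids, ids)
    netEye <- structure(list(adjacency = eye, beta = 1), class = "coexNetwork")
    tomEye <- computeTOM(netEye)$tom
    expect_equal(tomEye, eye)

    set.seed(5)
    for (n in c(4, 6, 11)) {
        a <- matrix(runif(n * n), n)
        a <- (a + t(a)) / 2; diag(a) <- 1
        dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
        net <- structure(list(adjacency = a, beta = 1), class = "coexNetwork")
        tom <- computeTOM(net)$tom
        oracle <- tomTripleLoopOracle(a)
        dimnames(oracle) <- dimnames(a)
        expect_equal(tom, oracle, tolerance = 1e-12)
        expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
        expect_equal(tom, t(tom))
    }
})

test_that("planted blocks are recovered exactly and naming follows size order", {
    set.seed(21)
    n <- 40
    e1 <- rnorm(n); e2 <- rnorm(n)
    m <- rbind(
        t(replicate(12, e1 + rnorm(n, 0, 0.1))),
        t(replicate(8, e2 + rnorm(n, 0, 0.1))))
    dimnames(m) <- list(paste0("g", 1:20), paste0("s", 1:n))
    net <- computeTOM(computeAdjacency(m, beta = 7))
    mset <- detectModules(net, minSize = 5)
    a <- moduleAssignment(mset)
    expect_setequal(unique(a[1:12]), "turquoise")   # larger block first
    expect_setequal(unique(a[13:20]), "blue")

    # relabelling features permutes, not changes, the partition
    perm <- sample(20)
    msetP <- detectModules(computeTOM(computeAdjacency(m[perm, ], beta = 7)),
                           minSize = 5)
    expect_equal(unname(moduleAssignment(msetP)[rownames(m)]), unname(a))

    expect_warning(big <- detectModules(net, minSize = 21), "grey")
    expect_true(all(moduleAssignment(big) == "grey"))
})

test_that("eigengenes summarize, orient and normalize module profiles", {
    set.seed(33)
    n <- 50
    e <- rnorm(n)
    m <- t(replicate(10, 5 + 2 * e + rnorm(n, 0, 0.01)))
    dimnames(m) <- list(paste0("g", 1:10), paste0("s", 1:n))
    assign <- stats::setNames(rep("turquoise", 10), rownames(m))
    mset <- new("ModuleSet", assignment = assign,
                eigengenes = matrix(numeric(0), 0, 0),
                kme = matrix(numeric(0), 0, 0),
                kmeP = matrix(numeric(0), 0, 0),
                minSize = 3L, params = list())
    mset <- computeEigengenes(m, mset)
    eg <- moduleEigengenes(mset)["turquoise", ]
    expect_gte(cor(eg, e), 0.999)
    expect_equal(var(eg), 1, tolerance = 1e-9)

    # flipping all member profiles flips the eigengene
    msetF <- computeEigengenes(-m, mset)
    expect_equal(moduleEigengenes(msetF)["turquoise", ], -eg,
                 tolerance = 1e-6)
})

test_that("kME and its p-value follow the t-distribution oracle", {
    set.seed(44)
    n <- 27
    e <- rnorm(n)
    m <- rbind(self = e, noise = rnorm(n))
    colnames(m) <- paste0("s", 1:n)
    eg <- matrix(e / sd(e), 1, n,
                 dimnames = list("turquoise", colnames(m)))
    assign <- stats::setNames(c("turquoise", "grey"), rownames(m))
    mset <- new("ModuleSet", assignment = assign, eigengenes = eg,
                kme = matrix(numeric(0), 0, 0),
                kmeP = matrix(numeric(0), 0, 0), minSize = 1L,
                params = list())
    mset <- computeKME(m, mset)
    expect_equal(unname(moduleKME(mset)["self", "turquoise"]), 1,
                 tolerance = 1e-12)
    expect_lt(moduleKMEPvalues(mset)["self", "turquoise"], 1e-12)

    # worked value: r = 0.5 at n = 27 against the integral oracle
    tstat <- 0.5 * sqrt(25) / sqrt(1 - 0.25)
    expect_equal(intermod:::.pearsonP(0.5, 27), tTwoSidedOracle(tstat, 25),
                 tolerance = 1e-9)
    expect_equal(intermod:::.pearsonP(0.5, 27), 0.0079127, tolerance = 1e-4)
    expect_equal(intermod:::.pearsonP(0, 27), 1)

    expect_error(computeKME(m[, 1:3], mset), "at least 4")
})

test_that("soft-threshold scan returns diagnostics and the default fallback", {
    sim <- simulateExpression(simulationConfig(
        nGenes = 150, nMetabolites = 50, nModulesGene = 2,
        moduleSizeGene = 30, moduleSizeMetab = 10, seed = 6))
    m <- abundances(sim$genes)
    one <- suppressWarnings(pickSoftThreshold(m, powers = 7))
    expect_equal(nrow(one$table), 1L)
    res <- suppressWarnings(pickSoftThreshold(m, powers = c(2, 7),
                                              r2Min = 0.999))
    w <- capture_warnings(pickSoftThreshold(m, powers = c(2, 7),
                                            r2Min = 0.999))
    expect_true(any(grepl("default beta", w)))
    expect_equal(res$beta, 7)
    expect_true(all(is.finite(res$table$meanK)))
})
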