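test_that("Fisher combination reproduces its closed forms and oracle", {
    # k = 1 identity
    expect_equal(fisherCombine(0.3)$p_combined, 0.3, tolerance = 1e-12)
    # all ones
    f1 <- fisherCombine(rep(1, 4))
    expect_equal(f1$x2, 0)
    expect_equal(f1$p_combined, 1)
    # worked example: five p = 0.05
    f <- fisherCombine(rep(0.05, 5))
    expect_equal(f$x2, 29.957, tolerance = 1e-4)
    expect_equal(f$df, 10L)
    expect_equal(f$p_combined, chisqSurvivalOracle(f$x2, 10),
                 tolerance = 1e-9)
    expect_error(fisherCombine(numeric(0)), "no p-values")
    expect_error(fisherCombine(c(0.5, 1.5)), "\\[0,1\\]")
    # zero p clamped, not infinite
    expect_true(is.finite(fisherCombine(c(0, 0.5))$x2))
})

test_that("consistent moderate evidence outranks one strong channel", {
    a <- fisherCombine(rep(0.02, 5))
    b <- fisherCombine(c(1e-6, rep(0.5, 4)))
    expect_equal(a$x2, 39.12, tolerance = 1e-3)
    expect_equal(b$x2, 33.18, tolerance = 1e-3)
    expect_lt(a$p_combined, b$p_combined)
    expect_equal(a$p_combined, chisqSurvivalOracle(a$x2, 10),
                 tolerance = 1e-9)
})

test_that("the score is monotone in every channel", {
    base <- rep(0.2, 5)
    s0 <- -log10(fisherCombine(base)$p_combined)
    for (i in 1:5) {
        p <- base; p[i] <- 0.01
        expect_gt(-log10(fisherCombine(p)$p_combined), s0)
    }
})

test_that("evidence assembly enforces the universe and missing-channel rules", {
    kme <- matrix(c(0.001, 0.5, 0.002, 0.6), 2, 2,
                  dimnames = list(c("g1", "g2"), c("turquoise", "blue")))
    mset <- new("ModuleSet",
                assignment = c(g1 = "turquoise", g2 = "blue", g3 = "grey"),
                eigengenes = matrix(rbind(c(-1, 1, -1, 1),
                                          c(1, -1, -1, 1)) / sqrt(4 / 3),
                    2, 4,
                    dimnames = list(c("turquoise", "blue"), paste0("s", 1:4))),
                kme = kme, kmeP = kme, minSize = 1L, params = list())
    de <- do.call(rbind, lapply(c("variety", "location", "stage"),
        function(f) data.frame(feature_id = c("g1", "g2", "g3"), factor = f,
                               p = c(0.01, 0.2, 0.5),
                               p_adj = c(0.03, 0.4, 0.9))))
    ev <- assembleEvidence(de, mset, integration = NULL)
    expect_setequal(ev$gene_id, c("g1", "g2"))     # grey gene excluded
    expect_true(all(ev$k == 4L))                   # no metabolite channel
    expect_equal(ev$p_kme_own_module[ev$gene_id == "g2"], 0.6)

    ranked <- rankGenes(ev)
    expect_equal(ranked$df, c(8L, 8L))
    expect_equal(ranked$rank, 1:2)

    integ <- data.frame(feature_id = rep(c("g1", "g2"), 2),
                        module = rep(c("MM1", "MM2"), each = 2),
                        r = 0, p = c(0.4, 0.9, 0.05, 0.7),
                        significant = FALSE)
    ev5 <- assembleEvidence(de, mset, integ)
    expect_true(all(ev5$k == 5L))
    expect_equal(ev5$p_kme_best_metab_module[ev5$gene_id == "g1"], 0.05)
})

test_that("ties rank adjacently in lexicographic gene order", {
    kme <- matrix(0.2, 3, 1, dimnames = list(c("gB", "gA", "gC"), "turquoise"))
    mset <- new("ModuleSet",
                assignment = c(gB = "turquoise", gA = "turquoise",
                               gC = "turquoise"),
                eigengenes = matrix(c(-1, 1, -1, 1) / sqrt(4 / 3), 1, 4,
                    dimnames = list("turquoise", paste0("s", 1:4))),
                kme = kme, kmeP = kme, minSize = 1L, params = list())
    de <- do.call(rbind, lapply(c("variety", "location", "stage"),
        function(f) data.frame(feature_id = c("gB", "gA", "gC"), factor = f,
                               p = 0.1, p_adj = 0.2)))
    ranked <- rankGenes(assembleEvidence(de, mset))
    expect_equal(ranked$gene_id, c("gA", "gB", "gC"))
})

test_that("null evidence produces uniform combined p-values", {
    set.seed(19)
    pm <- matrix(runif(1000 * 5), 1000)
    pc <- apply(pm, 1L, function(v) fisherCombine(v)$p_combined)
    ks <- suppressWarnings(ks.test(pc, "punif"))
    expect_gt(ks$p.value, 0.01)
})

test_that("the planted regulator earns five small channels and a top rank", {
    sim <- simulateMultiOmics(simulationConfig(
        nGenes = 400, nMetabolites = 120, moduleSizeGene = 60,
        moduleSizeMetab = 25, nModulesGene = 4, nModulesMetab = 2, seed = 27))
    a0 <- sim$truth$module_assignment_gene
    a <- ifelse(a0 == "none", "grey", a0); names(a) <- names(a0)
    mset <- new("ModuleSet", assignment = a,
                eigengenes = matrix(numeric(0), 0, 0),
                kme = matrix(numeric(0), 0, 0),
                kmeP = matrix(numeric(0), 0, 0), minSize = 1L,
                params = list())
    mset <- computeKME(sim$genes, computeEigengenes(sim$genes, mset))
    fit <- fitFactorialAnova(sim$genes)
    fcs <- lapply(stats::setNames(nm = c("variety", "location", "stage")),
                  function(f) computeGroupFoldChanges(sim$genes, f))
    de <- selectDifferentialFeatures(fit, fcs)
    am <- sim$truth$module_assignment_metab
    amg <- ifelse(am == "none", "grey", am); names(amg) <- names(am)
    msetM <- new("ModuleSet", assignment = amg,
                 eigengenes = matrix(numeric(0), 0, 0),
                 kme = matrix(numeric(0), 0, 0),
                 kmeP = matrix(numeric(0), 0, 0), minSize = 1L,
                 params = list())
    msetM <- computeEigengenes(sim$metabolites, msetM)
    integ <- correlateToEigengenes(sim$genes, msetM)
    ev <- rankGenes(assembleEvidence(de, mset, integ))
    reg <- ev[ev$gene_id == sim$truth$planted_regulator, ]
    channels <- unlist(reg[, c("p_kme_own_module", "p_de_location",
                               "p_de_variety", "p_de_stage",
                               "p_kme_best_metab_module")])
    expect_true(all(channels < 0.01))
    expect_lte(reg$rank, ceiling(0.01 * nrow(ev)))
})
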