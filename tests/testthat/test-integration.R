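makeEigengeneMatrix <- function(profiles, samples) {
    eg <- do.call(rbind, lapply(profiles, function(e) e / sd(e)))
    dimnames(eg) <- list(names(profiles), samples)
    eg
}

test_that("coupled features are called significant, orthogonal ones are not", {
    set.seed(3)
    n <- 108
    samples <- paste0("s", 1:n)
    e <- rnorm(n)
    eg <- makeEigengeneMatrix(list(turquoise = e), samples)
    coupled <- e + rnorm(n, 0, 0.1)
    ec <- e - mean(e)
    ortho <- rnorm(n)
    ortho <- ortho - mean(ortho)
    ortho <- ortho - sum(ortho * ec) / sum(ec * ec) * ec
    m <- rbind(coupled = coupled, ortho = ortho)
    colnames(m) <- samples
    res <- correlateToEigengenes(m, eg, alpha = 0.01)
    rc <- res[res$feature_id == "coupled", ]
    expect_gte(rc$r, 0.9)
    expect_lt(rc$p, 1e-10)
    expect_true(rc$significant)
    ro <- res[res$feature_id == "ortho", ]
    expect_equal(ro$r, 0, tolerance = 1e-10)
    expect_equal(ro$p, 1, tolerance = 1e-8)
    expect_false(ro$significant)
    expect_equal(rc$r2, rc$r^2)
})

test_that("correlation direction is symmetric in feature and eigengene", {
    set.seed(8)
    n <- 40
    samples <- paste0("s", 1:n)
    f <- rnorm(n); e <- rnorm(n)
    m <- matrix(f, 1, dimnames = list("feat", samples))
    eg <- makeEigengeneMatrix(list(blue = e), samples)
    fwd <- correlateToEigengenes(m, eg)
    mE <- matrix(e, 1, dimnames = list("eig", samples))
    egF <- makeEigengeneMatrix(list(feat = f), samples)
    rev <- correlateToEigengenes(mE, egF)
    expect_equal(fwd$r, rev$r, tolerance = 1e-12)
    expect_equal(fwd$p, rev$p, tolerance = 1e-12)
})

test_that("null features reject at the nominal rate", {
    set.seed(5)
    n <- 108
    samples <- paste0("s", 1:n)
    eg <- makeEigengeneMatrix(list(turquoise = rnorm(n), blue = rnorm(n)),
                              samples)
    m <- matrix(rnorm(500 * n), 500, dimnames = list(paste0("f", 1:500),
                                                     samples))
    res <- correlateToEigengenes(m, eg, alpha = 0.01)
    rate <- mean(res$significant)
    se <- sqrt(0.01 * 0.99 / nrow(res))
    expect_lt(abs(rate - 0.01), 2.58 * se + 1e-3)
})

test_that("sample mismatch is reported with the offending ids", {
    m <- matrix(rnorm(8), 2, dimnames = list(c("a", "b"), paste0("s", 1:4)))
    eg <- matrix(rnorm(4), 1, dimnames = list("blue", paste0("x", 1:4)))
    expect_error(correlateToEigengenes(m, eg), "x1")
})

test_that("planted cross-layer couplings have maximal reciprocal support", {
    sim <- simulateMultiOmics(simulationConfig(
        nGenes = 250, nMetabolites = 120, moduleSizeGene = 40,
        moduleSizeMetab = 25, nModulesGene = 3, nModulesMetab = 2, seed = 14))
    truthToModuleSet <- function(assign, m) {
        labels <- setdiff(unique(assign), "none")
        a <- ifelse(assign == "none", "grey", assign)
        names(a) <- names(assign)
        mset <- new("ModuleSet", assignment = a,
                    eigengenes = matrix(numeric(0), 0, 0),
                    kme = matrix(numeric(0), 0, 0),
                    kmeP = matrix(numeric(0), 0, 0), minSize = 1L,
                    params = list())
        computeEigengenes(m, mset)
    }
    gset <- truthToModuleSet(sim$truth$module_assignment_gene,
                             abundances(sim$genes))
    mset <- truthToModuleSet(sim$truth$module_assignment_metab,
                             abundances(sim$metabolites))
    fwd <- correlateToEigengenes(sim$metabolites, gset, alpha = 0.01)
    rev <- correlateToEigengenes(sim$genes, mset, alpha = 0.01)
    links <- significantLinks(fwd, rev, gset, mset)
    planted <- sim$truth$gene_metab_links_true
    top <- links[seq_len(nrow(planted)), ]
    expect_setequal(paste(top$gene_module, top$metab_module),
                    paste(planted$gene_module, planted$metab_module))
    expect_true(all(top$reciprocal))
    # alternating planted signs survive into the link table
    s1 <- links[links$gene_module == "GM1" & links$metab_module == "MM1", ]
    s2 <- links[links$gene_module == "GM2" & links$metab_module == "MM2", ]
    expect_equal(s1$sign_forward, 1)
    expect_equal(s2$sign_forward, -1)
})

test_that("empty significant sets give an empty link table without error", {
    emptyModSet <- new("ModuleSet",
                       assignment = stats::setNames(character(0), character(0)),
                       eigengenes = matrix(numeric(0), 0, 0),
                       kme = matrix(numeric(0), 0, 0),
                       kmeP = matrix(numeric(0), 0, 0), minSize = 1L,
                       params = list())
    fwd <- data.frame(feature_id = character(), module = character(),
                      r = numeric(), r2 = numeric(), p = numeric(),
                      significant = logical())
    out <- significantLinks(fwd, fwd, emptyModSet, emptyModSet)
    expect_equal(nrow(out), 0L)
})
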