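#' @include AllClasses.R AllGenerics.R utils.R dataio.R
NULL

#' Configuration for the synthetic multi-omics generator
#'
#' Defaults emulate the structure of a crossed field experiment profiled on
#' two omics layers: a 3 varieties x 3 locations x 6 stages design with 2
#' replicates (108 samples), log2-scale expression with additive factorial
#' effects, block-correlated co-expression modules driven by latent
#' eigengene profiles, metabolite modules linearly coupled to gene-module
#' eigengenes, a low/high coefficient-of-variation mixture, and one planted
#' regulator carrying signal in every prioritization channel.
#'
#' @param nGenes,nMetabolites feature counts per layer.
#' @param nModulesGene,nModulesMetab number of planted modules.
#' @param moduleSizeGene,moduleSizeMetab members per planted module.
#' @param design integer vector `(nVariety, nLocation, nStage, nReplicate)`.
#' @param effectSize factor effect amplitude in log2 units: the largest
#'   planted level gap of a module eigengene is `2 * effectSize`.
#' @param withinModuleCor target expected pairwise correlation of module
#'   members (loadings are calibrated to it).
#' @param noiseSd residual standard deviation, log2 units.
#' @param cvLowFrac fraction of background genes whose noise is shrunk
#'   five-fold, creating the low-variability mixture component.
#' @param couplingR target |Pearson r| between a metabolite-module latent
#'   profile and its linked gene-module eigengene.
#' @param nTargets number of planted regulator targets.
#' @param seed RNG seed; identical configs give bit-identical output.
#' @return a validated `simulationConfig` list.
#' @export
simulationConfig <- function(nGenes = 2000, nMetabolites = 500,
                             nModulesGene = 5, nModulesMetab = 3,
                             moduleSizeGene = 50, moduleSizeMetab = 40,
                             design = c(nVariety = 3, nLocation = 3,
                                        nStage = 6, nReplicate = 2),
                             effectSize = 1, withinModuleCor = 0.8,
                             noiseSd = 1, cvLowFrac = 0.4,
                             couplingR = 0.8, nTargets = 5, seed = 1) {
    cfg <- list(nGenes = as.integer(nGenes),
                nMetabolites = as.integer(nMetabolites),
                nModulesGene = as.integer(nModulesGene),
                nModulesMetab = as.integer(nModulesMetab),
                moduleSizeGene = as.integer(moduleSizeGene),
                moduleSizeMetab = as.integer(moduleSizeMetab),
                design = as.integer(design), effectSize = effectSize,
                withinModuleCor = withinModuleCor, noiseSd = noiseSd,
                cvLowFrac = cvLowFrac, couplingR = couplingR,
                nTargets = as.integer(nTargets), seed = as.integer(seed))
    names(cfg$design) <- c("nVariety", "nLocation", "nStage", "nReplicate")
    with(cfg, {
        if (any(c(nGenes, nMetabolites, nModulesGene, nModulesMetab,
                  moduleSizeGene, moduleSizeMetab, nTargets) < 1L))
            stop("all counts must be positive")
        if (nModulesGene * moduleSizeGene + nTargets > nGenes)
            stop("gene module sizes plus targets exceed nGenes")
        if (nModulesMetab * moduleSizeMetab > nMetabolites)
            stop("metabolite module sizes exceed nMetabolites")
        if (withinModuleCor <= 0 || withinModuleCor >= 1)
            stop("withinModuleCor must lie in (0,1)")
        if (cvLowFrac <= 0 || cvLowFrac >= 1)
            stop("cvLowFrac must lie in (0,1)")
        if (noiseSd <= 0) stop("noiseSd must be positive")
        if (effectSize < 0) stop("effectSize must be non-negative")
    })
    class(cfg) <- "simulationConfig"
    cfg
}

#' Simulate the full factorial sample design
#'
#' Full crossing of variety x location x stage with the requested number of
#' replicates. Each crossed factor must have at least two levels so the
#' factorial ANOVA is estimable; a single replicate is allowed (but the
#' ANOVA stage will reject a saturated model).
#'
#' @param cfg a [simulationConfig()].
#' @return design data.frame (`sample_id`, `variety`, `location`, `stage`,
#'   `replicate`).
#' @export
simulateDesign <- function(cfg) {
    d <- cfg$design
    if (any(d[1:3] < 2L))
        stop("variety, location and stage each need >=2 levels for ANOVA use")
    if (d[4] < 1L) stop("nReplicate must be >=1")
    g <- expand.grid(replicate = seq_len(d[4]),
                     variety = paste0("V", seq_len(d[1])),
                     location = paste0("L", seq_len(d[2])),
                     stage = paste0("S", seq_len(d[3])),
                     stringsAsFactors = FALSE)
    out <- data.frame(
        sample_id = sprintf("%s_%s_%s_R%d", g$variety, g$location, g$stage,
                            g$replicate),
        variety = g$variety, location = g$location, stage = g$stage,
        replicate = g$replicate, stringsAsFactors = FALSE)
    .validateDesign(out)
}

# which design factors drive module m's eigengene; module 1 responds to all
# three (it hosts the planted regulator)
.modulePattern <- function(m) {
    pats <- list(c("variety", "location", "stage"), "stage", "location",
                 "variety", c("location", "stage"), c("variety", "stage"),
                 c("variety", "location"))
    pats[[(m - 1L) %% length(pats) + 1L]]
}

# sum-to-zero level offsets spanning [-effectSize, effectSize]
.levelOffsets <- function(nLevels, effectSize) {
    if (nLevels == 1L) return(0)
    effectSize * (2 * (seq_len(nLevels) - 1) / (nLevels - 1) - 1)
}

# latent eigengene profile for module m: planted factor effects plus N(0,1)
.moduleLatent <- function(m, design, effectSize) {
    n <- nrow(design)
    e <- stats::rnorm(n, 0, 1)
    ori <- 1
    for (f in .modulePattern(m)) {
        lv <- design[[f]]
        off <- .levelOffsets(nlevels(lv), effectSize)
        e <- e + ori * off[as.integer(lv)]
        ori <- -ori                       # decorrelate modules sharing factors
    }
    if (m == 1L && effectSize > 0) {      # one planted two-way interaction
        vc <- scale(as.integer(design$variety))[, 1]
        sc <- scale(as.integer(design$stage))[, 1]
        e <- e + 0.5 * effectSize * vc * sc
    }
    e
}

# member loading calibrated so the expected pairwise member correlation
# equals r: cor = lambda^2 var(e) / (lambda^2 var(e) + sigma^2)
.calibratedLoading <- function(r, sdLatent, noiseSd) {
    noiseSd / sdLatent * sqrt(r / (1 - r))
}

#' Simulate the transcript layer with planted modules and ground truth
#'
#' Each planted module is driven by a latent eigengene profile carrying
#' additive factor effects (per the module's pattern) plus unit Gaussian
#' noise; members load on it with loadings calibrated so the expected
#' within-module correlation equals `withinModuleCor`. Background genes are
#' pure noise, a fraction `cvLowFrac` of them with five-fold smaller noise
#' (the low-CV mixture component). Gene 1 of module 1 is the planted
#' regulator (an extra-large loading); `nTargets` additional genes are noisy
#' saturating (sigmoidal) functions of the regulator so that mutual
#' information detects the dependence.
#'
#' @param cfg a [simulationConfig()].
#' @return list with elements `genes` (an [OmicsSet] with design attached),
#'   `design`, and `truth` (module assignment, per-factor DE feature sets,
#'   planted regulator and targets, module latents).
#' @export
simulateExpression <- function(cfg) {
    stopifnot(inherits(cfg, "simulationConfig"))
    design <- simulateDesign(cfg)
    n <- nrow(design)
    set.seed(cfg$seed)
    K <- cfg$nModulesGene; sz <- cfg$moduleSizeGene
    ids <- sprintf("gene_%05d", seq_len(cfg$nGenes))
    assign <- rep("none", cfg$nGenes); names(assign) <- ids

    latents <- vapply(seq_len(K), .moduleLatent, numeric(n),
                      design = design, effectSize = cfg$effectSize)
    colnames(latents) <- paste0("GM", seq_len(K))
    rownames(latents) <- design$sample_id

    mu <- stats::runif(cfg$nGenes, 6, 12)
    X <- matrix(stats::rnorm(cfg$nGenes * n, 0, cfg$noiseSd),
                nrow = cfg$nGenes, dimnames = list(ids, design$sample_id))

    for (m in seq_len(K)) {
        idx <- ((m - 1L) * sz + 1L):(m * sz)
        base <- .calibratedLoading(cfg$withinModuleCor,
                                   stats::sd(latents[, m]), cfg$noiseSd)
        lam <- base * stats::runif(sz, 0.9, 1.1)
        if (m == 1L) lam[1L] <- base * 1.5      # the planted regulator: hub
        X[idx, ] <- X[idx, ] + tcrossprod(lam, latents[, m])
        assign[idx] <- paste0("GM", m)
    }

    regulator <- ids[1L]
    tIdx <- (K * sz + 1L):(K * sz + cfg$nTargets)
    z <- scale(mu[1L] + X[1L, ])[, 1]
    sig <- scale(1 / (1 + exp(-3 * z)))[, 1]    # saturating response
    for (j in tIdx)
        X[j, ] <- 2 * cfg$noiseSd * sig +
            stats::rnorm(n, 0, 0.5 * cfg$noiseSd)
    assign[tIdx] <- "GM1"

    bgIdx <- which(assign == "none")
    nLow <- floor(cfg$cvLowFrac * length(bgIdx))
    lowIdx <- bgIdx[seq_len(nLow)]
    X[lowIdx, ] <- X[lowIdx, ] * 0.2
    X <- X + mu

    deSets <- list(variety = character(), location = character(),
                   stage = character())
    if (cfg$effectSize > 0) {
        for (m in seq_len(K)) {
            members <- ids[assign == paste0("GM", m)]
            for (f in .modulePattern(m))
                deSets[[f]] <- union(deSets[[f]], members)
        }
    }

    truth <- list(
        module_assignment_gene = assign,
        de_features_true = deSets,
        planted_regulator = regulator,
        regulator_targets_true = stats::setNames(list(ids[tIdx]), regulator),
        cv_low_features = ids[lowIdx],
        gene_latents = latents)
    list(genes = attachDesign(OmicsSet(X, "transcript"), design),
         design = design, truth = truth)
}

#' Simulate the metabolite layer coupled to gene-module eigengenes
#'
#' Metabolite module `j` is driven by a latent profile equal to the linked
#' gene-module latent (sign alternating +, -, +, ...) plus Gaussian noise
#' sized so the latent-to-eigengene correlation is `couplingR`. Members load
#' on the latent exactly as on the gene side; background metabolites are
#' pure noise.
#'
#' @param cfg a [simulationConfig()].
#' @param geneSim result of [simulateExpression()] under the same config.
#' @return list with `metabolites` (an [OmicsSet]) and the completed `truth`
#'   (adds metabolite module assignment and the gene-metabolite link table).
#' @export
simulateMetabolome <- function(cfg, geneSim) {
    stopifnot(inherits(cfg, "simulationConfig"))
    design <- geneSim$design
    n <- nrow(design)
    latents <- geneSim$truth$gene_latents
    if (cfg$nModulesMetab > ncol(latents))
        stop("metabolite link references unknown gene module: only ",
             ncol(latents), " gene modules exist")
    set.seed(cfg$seed + 1000003L)
    K <- cfg$nModulesMetab; sz <- cfg$moduleSizeMetab
    ids <- sprintf("metab_%04d", seq_len(cfg$nMetabolites))
    assign <- rep("none", cfg$nMetabolites); names(assign) <- ids

    sigmaLink <- if (cfg$couplingR >= 1) 0 else
        sqrt(1 / cfg$couplingR^2 - 1)
    links <- data.frame(gene_module = paste0("GM", seq_len(K)),
                        metab_module = paste0("MM", seq_len(K)),
                        sign = ifelse(seq_len(K) %% 2L == 1L, 1L, -1L))
    mu <- stats::runif(cfg$nMetabolites, 8, 16)
    M <- matrix(stats::rnorm(cfg$nMetabolites * n, 0, cfg$noiseSd),
                nrow = cfg$nMetabolites, dimnames = list(ids, design$sample_id))
    mlat <- matrix(0, n, K, dimnames = list(design$sample_id,
                                            paste0("MM", seq_len(K))))
    for (m in seq_len(K)) {
        sdE <- stats::sd(latents[, m])
        lat <- links$sign[m] * latents[, m] +
            stats::rnorm(n, 0, sigmaLink * sdE)
        mlat[, m] <- lat
        idx <- ((m - 1L) * sz + 1L):(m * sz)
        base <- .calibratedLoading(cfg$withinModuleCor, stats::sd(lat),
                                   cfg$noiseSd)
        lam <- base * stats::runif(sz, 0.9, 1.1)
        M[idx, ] <- M[idx, ] + tcrossprod(lam, lat)
        assign[idx] <- paste0("MM", m)
    }
    M <- M + mu

    deSets <- list(variety = character(), location = character(),
                   stage = character())
    if (cfg$effectSize > 0) {
        for (m in seq_len(K)) {
            members <- ids[assign == paste0("MM", m)]
            for (f in .modulePattern(m))
                deSets[[f]] <- union(deSets[[f]], members)
        }
    }

    truth <- geneSim$truth
    truth$module_assignment_metab <- assign
    truth$de_metabolites_true <- deSets
    truth$gene_metab_links_true <- links
    truth$metab_latents <- mlat
    list(metabolites = attachDesign(OmicsSet(M, "metabolite"), design),
         truth = truth)
}

#' Simulate both omics layers in one call
#'
#' @param cfg a [simulationConfig()].
#' @return list with `genes`, `metabolites` (both [OmicsSet]), `design`, and
#'   the completed `truth`.
#' @export
simulateMultiOmics <- function(cfg = simulationConfig()) {
    gs <- simulateExpression(cfg)
    ms <- simulateMetabolome(cfg, gs)
    list(genes = gs$genes, metabolites = ms$metabolites,
         design = gs$design, truth = ms$truth)
}

#' Simulate a matrix of independent features with planted per-factor effects
#'
#' A lean generator for calibration studies of the differential-abundance
#' stage: `nDE` features receive additive sum-spanning level offsets with
#' largest gap `effect` on the named factor; the rest are pure noise.
#'
#' @param design a design data.frame (e.g. from [simulateDesign()]).
#' @param nFeatures,nDE feature counts.
#' @param factorName `"variety"`, `"location"` or `"stage"`.
#' @param effect largest level gap, log2 units.
#' @param noiseSd residual SD.
#' @param seed RNG seed.
#' @return list with `ose` (an [OmicsSet]) and `deTruth` (logical vector).
#' @export
simulateDEFeatures <- function(design, nFeatures = 2000, nDE = 100,
                               factorName = "location", effect = 2,
                               noiseSd = 1, seed = 1) {
    design <- .validateDesign(design)
    set.seed(as.integer(seed))
    n <- nrow(design)
    ids <- sprintf("feat_%05d", seq_len(nFeatures))
    X <- matrix(stats::rnorm(nFeatures * n, 0, noiseSd), nrow = nFeatures,
                dimnames = list(ids, design$sample_id))
    lv <- design[[factorName]]
    off <- .levelOffsets(nlevels(lv), effect / 2)
    deTruth <- stats::setNames(rep(FALSE, nFeatures), ids)
    if (nDE > 0) {
        deTruth[seq_len(nDE)] <- TRUE
        X[seq_len(nDE), ] <- X[seq_len(nDE), ] +
            rep(off[as.integer(lv)], each = nDE)
    }
    X <- X + 8
    list(ose = attachDesign(OmicsSet(X, "transcript"), design),
         deTruth = deTruth)
}

#' Write a simulated dataset to a directory
#'
#' Emits `genes.tsv`, `metabolites.tsv`, `design.tsv`, `truth.json`,
#' `regulators.txt` and `true_modules.gmt` (the planted gene modules, usable
#' as enrichment truth).
#'
#' @param sim result of [simulateMultiOmics()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeFeatureMatrix(sim$genes, file.path(dir, "genes.tsv"))
    writeFeatureMatrix(sim$metabolites, file.path(dir, "metabolites.tsv"))
    writeResultTable(sim$design, file.path(dir, "design.tsv"))
    writeLines(sim$truth$planted_regulator, file.path(dir, "regulators.txt"))
    tr <- sim$truth
    tr$gene_latents <- NULL; tr$metab_latents <- NULL
    jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = FALSE,
                         digits = NA)
    a <- sim$truth$module_assignment_gene
    sets <- split(names(a), a)
    sets <- sets[names(sets) != "none"]
    sets <- lapply(sets, function(v) { attr(v, "description") <- "planted module"; v })
    writeGMT(sets, file.path(dir, "true_modules.gmt"))
    invisible(dir)
}
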