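#' @include AllClasses.R AllGenerics.R utils.R dataio.R simulate.R varianceFilter.R factorialDE.R coexpression.R miNetwork.R integration.R prioritization.R enrichment.R
NULL

#' Default pipeline configuration
#'
#' Returns the nested parameter list consumed by [runPipeline()], one block
#' per stage, mirroring each stage function's arguments. Supply `paths` to
#' analyse on-disk data instead of simulating; any unset block keeps its
#' default. The global `seed` drives every stochastic stage.
#'
#' @param seed global RNG seed.
#' @param ... named blocks overriding defaults, e.g.
#'   `de = list(alpha = 0.05)`.
#' @return a `pipelineConfig` list.
#' @export
pipelineConfig <- function(seed = 1, ...) {
    cfg <- list(
        seed = as.integer(seed),
        paths = list(genes = NULL, metabolites = NULL, design = NULL,
                     regulators = NULL, gmt = NULL),
        simulate = list(),
        filter = list(cvScale = "linear", cutoff = 0.5, tol = 1e-8,
                      maxIter = 500L),
        de = list(alpha = 0.01, sdMult = 2),
        modules = list(beta = 7, minSizeGene = 30L, minSizeMetab = 10L,
                       cutMethod = "gap", cutQuantile = 0.98),
        grn = list(pTarget = 1e-8, nPerm = 20000L, bins = NULL,
                   dpiTolerance = 0),
        integrate = list(alpha = 0.01, bh = FALSE),
        prioritize = list(topN = 50L, useAdjusted = FALSE),
        enrich = list(fdr = 0.05))
    ov <- list(...)
    for (nm in names(ov))
        cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(ov[[nm]]))
            utils::modifyList(cfg[[nm]], ov[[nm]]) else ov[[nm]]
    class(cfg) <- "pipelineConfig"
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match [pipelineConfig()]
#'   blocks.
#' @return a `pipelineConfig` list.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    do.call(pipelineConfig,
            c(list(seed = if (is.null(y$seed)) 1 else y$seed),
              y[setdiff(names(y), "seed")]))
}

#' Principal-component QC of a sample matrix
#'
#' Feature-centred PCA of the samples; returns per-sample component scores
#' annotated with the design factors and the per-component fraction of
#' variance explained (non-increasing).
#'
#' @param x an [OmicsSet] or matrix.
#' @param design optional design data.frame (taken from `x` when attached).
#' @param nComponents number of components to report.
#' @return list with `scores` (data.frame) and `varianceExplained`.
#' @export
qcPCA <- function(x, design = NULL, nComponents = 2L) {
    m <- .matInput(x)
    if (ncol(m) < 3L) stop("PCA QC needs at least 3 samples")
    if (nComponents > min(dim(m)))
        stop("nComponents exceeds the matrix rank bound")
    pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    scores <- as.data.frame(pc$x[, seq_len(nComponents), drop = FALSE])
    scores <- cbind(sample_id = rownames(scores), scores,
                    stringsAsFactors = FALSE)
    d <- tryCatch(.designInput(x, design), error = function(e) NULL)
    if (!is.null(d))
        scores <- merge(scores, d, by = "sample_id", sort = FALSE)
    rownames(scores) <- NULL
    list(scores = scores, varianceExplained = ve[seq_len(nComponents)])
}

# ---- internal stage machinery -------------------------------------------

.stageOutputs <- function() list(
    simulate = c("genes.tsv", "metabolites.tsv", "design.tsv",
                 "regulators.txt", "true_modules.gmt"),
    qc = c("qc_pca_scores.tsv", "qc_pca_variance.tsv"),
    filter = c("filtered_genes.tsv", "mixture_fit.json"),
    de = c("de_genes.tsv", "de_metabolites.tsv", "de_summary.json"),
    modules = c("modules_genes_assignment.tsv",
                "modules_genes_eigengenes.tsv", "modules_genes_kme.tsv",
                "modules_genes_kme_p.tsv", "soft_threshold_genes.tsv",
                "modules_metab_assignment.tsv",
                "modules_metab_eigengenes.tsv", "modules_metab_kme.tsv",
                "modules_metab_kme_p.tsv", "soft_threshold_metab.tsv"),
    grn = "grn_edges.tsv",
    integrate = c("corr_metab_vs_geneME.tsv", "corr_gene_vs_metabME.tsv",
                  "module_links.tsv"),
    prioritize = c("evidence.tsv", "top_genes.tsv"),
    enrich = "enrichment.tsv")

.manifestLine <- function(dir, stage, params, outputs, nRows, secs) {
    line <- jsonlite::toJSON(list(stage = stage, params = params,
                                  outputs = outputs, n_rows = nRows,
                                  seconds = round(secs, 3)),
                             auto_unbox = TRUE, digits = NA, null = "null")
    cat(line, "\n", sep = "", file = file.path(dir, "manifest.jsonl"),
        append = TRUE)
}

.writeMatrixTable <- function(m, path, idCol) {
    df <- cbind(stats::setNames(data.frame(rownames(m),
                                           stringsAsFactors = FALSE), idCol),
                as.data.frame(m))
    writeResultTable(df, path)
}

.readMatrixTable <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
}

.readModuleSet <- function(dir, layer, minSize) {
    pre <- file.path(dir, paste0("modules_", layer, "_"))
    at <- utils::read.delim(paste0(pre, "assignment.tsv"),
                            check.names = FALSE)
    assign <- stats::setNames(at$module, at$feature_id)
    new("ModuleSet", assignment = assign,
        eigengenes = .readMatrixTable(paste0(pre, "eigengenes.tsv")),
        kme = .readMatrixTable(paste0(pre, "kme.tsv")),
        kmeP = .readMatrixTable(paste0(pre, "kme_p.tsv")),
        minSize = as.integer(minSize), params = list())
}

.moduleStage <- function(ose, minSize, beta, cutMethod, cutQuantile, dir,
                         layer) {
    sft <- pickSoftThreshold(.matInput(ose), r2Min = 0.8, defaultBeta = beta)
    net <- computeTOM(computeAdjacency(ose, beta = beta))
    mset <- detectModules(net, minSize = minSize, cutMethod = cutMethod,
                          cutQuantile = cutQuantile)
    if (!length(moduleLabels(mset)))
        stop("no ", layer, " modules detected; lower minSize or revisit the cut")
    mset <- computeKME(ose, computeEigengenes(ose, mset))
    pre <- file.path(dir, paste0("modules_", layer, "_"))
    a <- moduleAssignment(mset)
    writeResultTable(data.frame(feature_id = names(a), module = a,
                                stringsAsFactors = FALSE),
                     paste0(pre, "assignment.tsv"))
    .writeMatrixTable(moduleEigengenes(mset), paste0(pre, "eigengenes.tsv"),
                      "module")
    .writeMatrixTable(moduleKME(mset), paste0(pre, "kme.tsv"), "feature_id")
    .writeMatrixTable(moduleKMEPvalues(mset), paste0(pre, "kme_p.tsv"),
                      "feature_id")
    writeResultTable(sft$table,
                     file.path(dir, paste0("soft_threshold_", layer, ".tsv")))
    mset
}

#' Run the full integrative pipeline
#'
#' Executes the stages in dependency order — simulate (or ingest), PCA QC,
#' variance filter, factorial differential analysis, co-expression modules
#' per layer, regulator MI networks, two-way integration, Fisher
#' prioritization, enrichment — writing each stage's tables plus a
#' JSON-lines manifest into `outDir`. Every stage reads its inputs from the
#' directory, so with `resume = TRUE` the run restarts at the first stage
#' whose outputs are missing and downstream stages re-execute.
#'
#' @param cfg a [pipelineConfig()] (or YAML path).
#' @param outDir output directory.
#' @param resume skip stages whose outputs already exist.
#' @return invisibly, the manifest as a data.frame of completed stages.
#' @export
runPipeline <- function(cfg = pipelineConfig(), outDir, resume = FALSE) {
    if (is.character(cfg)) cfg <- readPipelineConfig(cfg)
    stopifnot(inherits(cfg, "pipelineConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    outs <- .stageOutputs()
    stages <- names(outs)
    done <- vapply(stages, function(s)
        all(file.exists(file.path(outDir, outs[[s]]))), logical(1))
    first <- if (resume) match(FALSE, done, nomatch = length(stages) + 1L)
             else 1L
    if (first > length(stages)) {
        message("all stages complete; nothing to do")
        return(invisible(NULL))
    }
    if (!resume) unlink(file.path(outDir, "manifest.jsonl"))
    run <- stages[seq(first, length(stages))]
    for (stage in run) {
        t0 <- proc.time()[["elapsed"]]
        nRows <- .runStage(stage, cfg, outDir)
        .manifestLine(outDir, stage, cfg[[stage]], outs[[stage]], nRows,
                      proc.time()[["elapsed"]] - t0)
        message("stage ", stage, " complete")
    }
    invisible(run)
}

.runStage <- function(stage, cfg, dir) {
    switch(stage,
    simulate = {
        if (!is.null(cfg$paths$genes)) {
            file.copy(cfg$paths$genes, file.path(dir, "genes.tsv"),
                      overwrite = TRUE)
            file.copy(cfg$paths$metabolites, file.path(dir, "metabolites.tsv"),
                      overwrite = TRUE)
            file.copy(cfg$paths$design, file.path(dir, "design.tsv"),
                      overwrite = TRUE)
            file.copy(cfg$paths$regulators, file.path(dir, "regulators.txt"),
                      overwrite = TRUE)
            file.copy(cfg$paths$gmt, file.path(dir, "true_modules.gmt"),
                      overwrite = TRUE)
            return(NA_integer_)
        }
        scfg <- do.call(simulationConfig,
                        utils::modifyList(list(seed = cfg$seed), cfg$simulate))
        sim <- simulateMultiOmics(scfg)
        writeSimulation(sim, dir)
        nrow(sim$design)
    },
    qc = {
        genes <- .readAligned(file.path(dir, "genes.tsv"),
                              file.path(dir, "design.tsv"), "transcript")
        pca <- qcPCA(genes, nComponents = 2L)
        writeResultTable(pca$scores, file.path(dir, "qc_pca_scores.tsv"))
        writeResultTable(data.frame(component = seq_along(pca$varianceExplained),
                                    variance_explained = pca$varianceExplained),
                         file.path(dir, "qc_pca_variance.tsv"))
        nrow(pca$scores)
    },
    filter = {
        genes <- .readAligned(file.path(dir, "genes.tsv"),
                              file.path(dir, "design.tsv"), "transcript")
        cv <- computeCV(genes, cvScale = cfg$filter$cvScale)
        fit <- fitGaussianMixtureEM(cv, tol = cfg$filter$tol,
                                    maxIter = cfg$filter$maxIter,
                                    seed = cfg$seed)
        kept <- selectHighVariance(genes, fit, cutoff = cfg$filter$cutoff)
        writeFeatureMatrix(kept, file.path(dir, "filtered_genes.tsv"))
        jsonlite::write_json(
            list(weights = fit@weights, means = fit@means, sds = fit@sds,
                 loglik = fit@loglik, n_iter = fit@nIter,
                 converged = fit@converged, n_kept = nrow(kept),
                 n_total = nrow(genes)),
            file.path(dir, "mixture_fit.json"), auto_unbox = TRUE, digits = NA)
        nrow(kept)
    },
    de = {
        design <- readSampleDesign(file.path(dir, "design.tsv"))
        summaries <- list()
        for (layer in c("genes", "metabolites")) {
            f <- if (layer == "genes") "filtered_genes.tsv" else "metabolites.tsv"
            ose <- attachDesign(readFeatureMatrix(
                file.path(dir, f),
                if (layer == "genes") "transcript" else "metabolite"), design)
            fit <- fitFactorialAnova(ose)
            fcs <- lapply(stats::setNames(nm = c("variety", "location",
                                                 "stage")),
                          function(f) computeGroupFoldChanges(ose, f))
            de <- selectDifferentialFeatures(fit, fcs,
                                             alpha = cfg$de$alpha,
                                             sdMult = cfg$de$sdMult)
            out <- if (layer == "genes") "de_genes.tsv" else "de_metabolites.tsv"
            writeResultTable(de, file.path(dir, out))
            summaries[[layer]] <- attr(de, "summary")
        }
        jsonlite::write_json(summaries, file.path(dir, "de_summary.json"),
                             auto_unbox = TRUE, digits = NA)
        length(summaries)
    },
    modules = {
        design <- readSampleDesign(file.path(dir, "design.tsv"))
        for (layer in c("genes", "metab")) {
            mf <- if (layer == "genes") "filtered_genes.tsv" else "metabolites.tsv"
            def <- if (layer == "genes") "de_genes.tsv" else "de_metabolites.tsv"
            ose <- attachDesign(readFeatureMatrix(
                file.path(dir, mf),
                if (layer == "genes") "transcript" else "metabolite"), design)
            de <- utils::read.delim(file.path(dir, def), check.names = FALSE)
            keep <- sort(unique(de$feature_id[de$is_de]))
            if (length(keep) < 10L)
                stop("fewer than 10 differential features in the ", layer,
                     " layer; modules are not meaningful")
            .moduleStage(ose[keep, ],
                         minSize = if (layer == "genes")
                             cfg$modules$minSizeGene else cfg$modules$minSizeMetab,
                         beta = cfg$modules$beta,
                         cutMethod = cfg$modules$cutMethod,
                         cutQuantile = cfg$modules$cutQuantile, dir, layer)
        }
        2L
    },
    grn = {
        design <- readSampleDesign(file.path(dir, "design.tsv"))
        genes <- attachDesign(readFeatureMatrix(
            file.path(dir, "filtered_genes.tsv"), "transcript"), design)
        regulators <- readLines(file.path(dir, "regulators.txt"))
        mset <- .readModuleSet(dir, "genes", cfg$modules$minSizeGene)
        thr <- calibrateMiThreshold(ncol(genes), bins = cfg$grn$bins,
                                    pTarget = cfg$grn$pTarget,
                                    nPerm = cfg$grn$nPerm,
                                    seed = cfg$seed + 7L)
        a <- moduleAssignment(mset)
        all <- list()
        for (lab in moduleLabels(mset)) {
            members <- names(a)[a == lab]
            if (!any(regulators %in% members)) next
            net <- applyDPI(buildRegulatorNetwork(
                genes[members, ], regulators, thr, bins = cfg$grn$bins,
                module = lab), tolerance = cfg$grn$dpiTolerance)
            e <- miEdges(net)
            if (nrow(e)) all[[lab]] <- cbind(module = lab, e)
        }
        edges <- if (length(all)) do.call(rbind, all) else
            data.frame(module = character(), regulator = character(),
                       target = character(), mi = numeric(), p = numeric(),
                       kept_after_dpi = logical())
        edges <- edges[order(edges$module, -edges$mi, edges$target), ,
                       drop = FALSE]
        writeResultTable(edges, file.path(dir, "grn_edges.tsv"))
        nrow(edges)
    },
    integrate = {
        design <- readSampleDesign(file.path(dir, "design.tsv"))
        gset <- .readModuleSet(dir, "genes", cfg$modules$minSizeGene)
        mset <- .readModuleSet(dir, "metab", cfg$modules$minSizeMetab)
        metab <- attachDesign(readFeatureMatrix(
            file.path(dir, "metabolites.tsv"), "metabolite"), design)
        genes <- attachDesign(readFeatureMatrix(
            file.path(dir, "filtered_genes.tsv"), "transcript"), design)
        deM <- utils::read.delim(file.path(dir, "de_metabolites.tsv"))
        keepM <- sort(unique(deM$feature_id[deM$is_de]))
        fwd <- correlateToEigengenes(metab[keepM, ], gset,
                                     alpha = cfg$integrate$alpha,
                                     bh = cfg$integrate$bh)
        rev <- correlateToEigengenes(genes[names(moduleAssignment(gset)), ],
                                     mset, alpha = cfg$integrate$alpha,
                                     bh = cfg$integrate$bh)
        writeResultTable(fwd, file.path(dir, "corr_metab_vs_geneME.tsv"))
        writeResultTable(rev, file.path(dir, "corr_gene_vs_metabME.tsv"))
        links <- significantLinks(fwd, rev, gset, mset)
        writeResultTable(links, file.path(dir, "module_links.tsv"))
        nrow(links)
    },
    prioritize = {
        gset <- .readModuleSet(dir, "genes", cfg$modules$minSizeGene)
        de <- utils::read.delim(file.path(dir, "de_genes.tsv"))
        rev <- utils::read.delim(file.path(dir, "corr_gene_vs_metabME.tsv"))
        ev <- assembleEvidence(de, gset, rev,
                               useAdjusted = cfg$prioritize$useAdjusted)
        ranked <- rankGenes(ev, topN = cfg$prioritize$topN)
        writeResultTable(ranked, file.path(dir, "evidence.tsv"))
        writeResultTable(attr(ranked, "top"), file.path(dir, "top_genes.tsv"))
        nrow(ranked)
    },
    enrich = {
        universe <- utils::read.delim(file.path(dir, "filtered_genes.tsv"),
                                      check.names = FALSE)[[1]]
        de <- utils::read.delim(file.path(dir, "de_genes.tsv"))
        selected <- sort(unique(de$feature_id[de$is_de]))
        pathways <- readGMT(file.path(dir, "true_modules.gmt"))
        enr <- fisherEnrichment(selected, universe, pathways,
                                fdrThreshold = cfg$enrich$fdr)
        writeResultTable(enr, file.path(dir, "enrichment.tsv"))
        nrow(enr)
    },
    stop("unknown stage: ", stage))
}
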