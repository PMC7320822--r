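#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Assemble the five evidence p-values per gene
#'
#' The gene universe is every gene assigned to a non-grey co-expression
#' module and present in the differential-expression results. Channels:
#' (1) the kME p-value of the gene's own module; (2-4) the raw factorial
#' ANOVA p for location, variety and stage (raw rather than BH-adjusted, as
#' adjusted values break the uniformity Fisher's method assumes; set
#' `useAdjusted = TRUE` to override); (5) the smallest p over the
#' metabolite-module eigengenes from the gene-versus-metabolite-ME
#' correlations ("best-correlated metabolite module"). A missing channel
#' reduces k for that gene rather than dropping it.
#'
#' @param de a `DeTable` from [selectDifferentialFeatures()].
#' @param modules the gene [ModuleSet] with kME computed.
#' @param integration [correlateToEigengenes()] result of genes vs
#'   metabolite MEs, or NULL when no metabolite layer exists (k becomes 4).
#' @param useAdjusted combine BH-adjusted instead of raw DE p-values.
#' @return data.frame with one row per gene: module, the five channel
#'   p-values (NA when missing) and k.
#' @export
assembleEvidence <- function(de, modules, integration = NULL,
                             useAdjusted = FALSE) {
    a <- moduleAssignment(modules)
    kmeP <- moduleKMEPvalues(modules)
    if (!nrow(kmeP)) stop("kME p-values not computed on the module set")
    inDe <- unique(de$feature_id)
    universe <- names(a)[a != "grey" & names(a) %in% inDe]
    dropped <- setdiff(names(a)[a != "grey"], inDe)
    if (length(dropped))
        message(length(dropped),
                " module gene(s) absent from the DE table; excluded")
    if (!length(universe)) stop("empty gene universe for prioritization")
    pcol <- if (useAdjusted) "p_adj" else "p"
    getDe <- function(f) {
        sub <- de[de$factor == f, , drop = FALSE]
        stats::setNames(sub[[pcol]], sub$feature_id)[universe]
    }
    p1 <- kmeP[cbind(match(universe, rownames(kmeP)),
                     match(a[universe], colnames(kmeP)))]
    p5 <- rep(NA_real_, length(universe))
    if (!is.null(integration)) {
        best <- tapply(integration$p, integration$feature_id, min)
        p5 <- as.numeric(best[universe])
    }
    out <- data.frame(
        gene_id = universe, module = a[universe],
        p_kme_own_module = p1,
        p_de_location = getDe("location"),
        p_de_variety = getDe("variety"),
        p_de_stage = getDe("stage"),
        p_kme_best_metab_module = p5,
        stringsAsFactors = FALSE, row.names = NULL)
    pm <- as.matrix(out[, 3:7])
    out$k <- rowSums(!is.na(pm))
    out
}

#' Fisher's combined probability test
#'
#' `X^2 = -2 sum ln p_i` referred to a chi-square distribution with `2k`
#' degrees of freedom. Zeros are clamped at `eps` before the log. For a
#' single p-value the combined p equals it exactly.
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @param eps clamp for zero p-values.
#' @return list with `x2`, `df`, `p_combined`.
#' @export
fisherCombine <- function(p, eps = 1e-300) {
    p <- p[!is.na(p)]
    if (!length(p)) stop("no p-values to combine")
    if (any(p < 0) || any(p > 1)) stop("p-values must lie in [0,1]")
    p <- pmax(p, eps)
    x2 <- -2 * sum(log(p))
    k <- length(p)
    list(x2 = x2, df = 2L * k,
         p_combined = stats::pchisq(x2, df = 2 * k, lower.tail = FALSE))
}

#' Rank genes by the combined evidence score
#'
#' Combines each gene's available channels with [fisherCombine()], scores
#' `-log10(p_combined)`, and ranks by decreasing score with deterministic
#' lexicographic tie-breaking on the gene id.
#'
#' @param evidence result of [assembleEvidence()].
#' @param topN how many genes to keep in the `"top"` attribute.
#' @return the evidence data.frame with `x2`, `df`, `p_combined`, `score`,
#'   `rank` columns added, sorted by rank; top-N table attached as
#'   attribute `"top"`.
#' @export
rankGenes <- function(evidence, topN = 50L) {
    pm <- as.matrix(evidence[, c("p_kme_own_module", "p_de_location",
                                 "p_de_variety", "p_de_stage",
                                 "p_kme_best_metab_module")])
    comb <- apply(pm, 1L, function(v) {
        f <- fisherCombine(v)
        c(f$x2, f$df, f$p_combined)
    })
    evidence$x2 <- comb[1, ]
    evidence$df <- as.integer(comb[2, ])
    evidence$p_combined <- comb[3, ]
    evidence$score <- -log10(pmax(evidence$p_combined, 1e-300))
    ord <- order(-evidence$score, evidence$gene_id)
    evidence <- evidence[ord, , drop = FALSE]
    evidence$rank <- seq_len(nrow(evidence))
    rownames(evidence) <- NULL
    attr(evidence, "top") <- utils::head(evidence, topN)
    evidence
}
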