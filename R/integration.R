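#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Correlate every feature of one layer with the other layer's eigengenes
#'
#' The two-way integration primitive: Pearson r between each feature
#' profile and each module eigengene over the shared samples, with the
#' two-sided t-test p (df = n - 2) and a significance flag at `alpha`
#' (raw p, as the integration stage applies no multiplicity correction by
#' default; set `bh = TRUE` to adjust within the table).
#'
#' @param x an [OmicsSet] or matrix (the features being correlated).
#' @param eigengenes modules x samples matrix (e.g.
#'   [moduleEigengenes()] of the other layer), or a [ModuleSet].
#' @param alpha significance threshold on p.
#' @param bh apply a Benjamini-Hochberg adjustment before flagging.
#' @return data.frame with columns feature_id, module, r, r2, p,
#'   significant; attributes `direction` counts per module and sign.
#' @export
correlateToEigengenes <- function(x, eigengenes, alpha = 0.01, bh = FALSE) {
    m <- .matInput(x)
    if (is(eigengenes, "ModuleSet")) eigengenes <- moduleEigengenes(eigengenes)
    if (!nrow(eigengenes)) stop("no eigengenes supplied")
    shared <- intersect(colnames(m), colnames(eigengenes))
    if (length(shared) < 4L)
        stop("fewer than 4 shared samples between matrix and eigengenes; ",
             "offending sets differ by: ",
             paste(union(setdiff(colnames(m), colnames(eigengenes)),
                         setdiff(colnames(eigengenes), colnames(m))),
                   collapse = ", "))
    m <- m[, shared, drop = FALSE]
    eigengenes <- eigengenes[, shared, drop = FALSE]
    n <- length(shared)
    r <- stats::cor(t(m), t(eigengenes), use = "pairwise.complete.obs")
    p <- matrix(.pearsonP(r, n), nrow(r), ncol(r), dimnames = dimnames(r))
    out <- data.frame(
        feature_id = rep(rownames(r), times = ncol(r)),
        module = rep(colnames(r), each = nrow(r)),
        r = as.vector(r), r2 = as.vector(r)^2, p = as.vector(p),
        stringsAsFactors = FALSE)
    pv <- if (bh) adjustBH(out$p) else out$p
    out$significant <- pv < alpha
    attr(out, "alpha") <- alpha
    attr(out, "n_samples") <- n
    counts <- stats::aggregate(cbind(n_sig = significant) ~ module, out, sum)
    pos <- stats::aggregate(cbind(n_sig_pos = significant & r > 0) ~ module,
                            out, sum)
    attr(out, "module_counts") <- merge(counts, pos, by = "module")
    class(out) <- c("integrationResult", "data.frame")
    out
}

#' Tabulate reciprocal cross-layer module links
#'
#' For every (gene module, metabolite module) pair: the number of
#' metabolites of that metabolite module significantly correlated with the
#' gene-module eigengene (forward), the number of member genes of the gene
#' module significantly correlated with the metabolite-module eigengene
#' (reverse), their dominant signs, a sign-consistency flag, and the
#' reciprocal-support flag (both directions non-empty). `support` is the
#' total count of supporting correlations.
#'
#' @param forward [correlateToEigengenes()] result, metabolites vs gene
#'   MEs.
#' @param reverse [correlateToEigengenes()] result, genes vs metabolite
#'   MEs.
#' @param geneModules [ModuleSet] of the gene layer.
#' @param metabModules [ModuleSet] of the metabolite layer.
#' @return data.frame, one row per module pair, sorted by decreasing
#'   support.
#' @export
significantLinks <- function(forward, reverse, geneModules, metabModules) {
    ga <- moduleAssignment(geneModules)
    ma <- moduleAssignment(metabModules)
    gLabs <- moduleLabels(geneModules)
    mLabs <- moduleLabels(metabModules)
    rows <- list()
    for (gm in gLabs) for (mm in mLabs) {
        fw <- forward[forward$module == gm &
                      ma[forward$feature_id] == mm &
                      forward$significant %in% TRUE, , drop = FALSE]
        rv <- reverse[reverse$module == mm &
                      ga[reverse$feature_id] == gm &
                      reverse$significant %in% TRUE, , drop = FALSE]
        signF <- if (nrow(fw)) sign(sum(sign(fw$r))) else 0
        signR <- if (nrow(rv)) sign(sum(sign(rv$r))) else 0
        rows[[paste(gm, mm)]] <- data.frame(
            gene_module = gm, metab_module = mm,
            n_forward = nrow(fw), n_reverse = nrow(rv),
            support = nrow(fw) + nrow(rv),
            sign_forward = signF, sign_reverse = signR,
            sign_consistent = (signF == 0 || signR == 0 || signF == signR),
            reciprocal = nrow(fw) >= 1L && nrow(rv) >= 1L,
            stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(data.frame(gene_module = character(),
                          metab_module = character(), n_forward = integer(),
                          n_reverse = integer(), support = integer(),
                          sign_forward = integer(), sign_reverse = integer(),
                          sign_consistent = logical(), reciprocal = logical()))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(-out$support, out$gene_module, out$metab_module), ]
}
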