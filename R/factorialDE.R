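#' @include AllClasses.R AllGenerics.R utils.R
NULL

# full factorial model matrix with sum-to-zero contrasts; returns the matrix
# plus the term assignment of each column
.factorialModelMatrix <- function(design) {
    for (f in c("variety", "location", "stage"))
        if (nlevels(design[[f]]) < 2L)
            stop("factor '", f, "' has fewer than 2 levels")
    old <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(old))
    mm <- stats::model.matrix(~ variety * location * stage, data = design)
    terms <- attr(stats::terms(~ variety * location * stage), "term.labels")
    list(X = mm, assign = attr(mm, "assign"), terms = terms)
}

.TERM_NAMES <- c("variety", "location", "stage", "variety:location",
                 "variety:stage", "location:stage", "variety:location:stage")

#' Per-feature full factorial ANOVA
#'
#' Fits, for every feature, the linear model with the three categorical main
#' effects (variety, location, stage), the three two-way interactions and
#' the three-way interaction, and partitions the sums of squares per term.
#' Sum-to-zero contrasts are used throughout; each term's sum of squares is
#' the increase in residual sum of squares when that term's columns are
#' dropped from the full model (marginal, Type-III). For balanced designs
#' this reproduces the classical orthogonal decomposition exactly; for
#' unbalanced replication a warning notes the marginal interpretation.
#'
#' @param x an [OmicsSet] (design attached) or numeric matrix.
#' @param design optional design data.frame overriding the attached one.
#' @return an object of class `anovaFit`: a list with `terms`, per-term
#'   matrices `ss`, `F`, `p` (features x terms), vectors `df` (per term),
#'   `residual_ss`, `residual_df`, `grand_mean`, and `feature_ids`.
#' @export
fitFactorialAnova <- function(x, design = NULL) {
    m <- .matInput(x)
    design <- .designInput(x, design)
    if (!identical(colnames(m), design$sample_id))
        m <- m[, design$sample_id, drop = FALSE]
    if (anyNA(m)) stop("ANOVA requires complete rows (no missing values)")
    n <- ncol(m)
    mmInfo <- .factorialModelMatrix(design)
    X <- mmInfo$X
    p <- ncol(X)
    if (n - p < 1L) stop("model saturated: replicates required")

    cells <- interaction(design$variety, design$location, design$stage)
    balanced <- length(unique(table(cells))) == 1L
    if (!balanced)
        warning("unbalanced design: per-term sums of squares are marginal (Type III)")

    Y <- t(m)                              # samples x features
    qrFull <- qr(X)
    rssFull <- colSums(qr.resid(qrFull, Y)^2)
    dfRes <- n - qrFull$rank

    nT <- length(mmInfo$terms)
    ss <- Fm <- pm <- matrix(NA_real_, nrow(m), nT,
                             dimnames = list(rownames(m), mmInfo$terms))
    dfTerm <- integer(nT); names(dfTerm) <- mmInfo$terms
    for (t in seq_len(nT)) {
        keep <- mmInfo$assign != t
        qrT <- qr(X[, keep, drop = FALSE])
        ssT <- colSums(qr.resid(qrT, Y)^2) - rssFull
        ssT[ssT < 0] <- 0                  # numerical guard
        dfT <- qrFull$rank - qrT$rank
        dfTerm[t] <- dfT
        ms <- ssT / dfT
        msRes <- rssFull / dfRes
        Fv <- ms / msRes
        pv <- stats::pf(Fv, dfT, dfRes, lower.tail = FALSE)
        zeroRes <- msRes <= .Machine$double.eps * pmax(ssT, 1)
        if (any(zeroRes)) {                # zero residual variance
            pv[zeroRes & ssT > 0] <- 0
            pv[zeroRes & ssT == 0] <- NaN
            if (any(zeroRes & ssT == 0))
                warning("feature(s) with all-zero sums of squares: p is NaN")
        }
        ss[, t] <- ssT; Fm[, t] <- Fv; pm[, t] <- pv
    }
    structure(list(terms = mmInfo$terms, ss = ss, F = Fm, p = pm,
                   df = dfTerm, residual_ss = rssFull, residual_df = dfRes,
                   grand_mean = rowMeans(m), feature_ids = rownames(m),
                   balanced = balanced),
              class = "anovaFit")
}

#' @export
print.anovaFit <- function(x, ...) {
    cat(sprintf("Factorial ANOVA fit: %d features, %d terms, residual df %d%s\n",
                length(x$feature_ids), length(x$terms), x$residual_df,
                if (x$balanced) " (balanced)" else " (unbalanced, Type III)"))
    invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `p.adjust(..., method = "BH")`; input order
#' is preserved and adjusted values are capped at 1.
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @return adjusted p-values in input order.
#' @export
adjustBH <- function(p) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0,1]")
    stats::p.adjust(p, method = "BH")
}

#' Per-feature fold change over the levels of one factor
#'
#' For each feature, level means are computed within each full-factorial
#' cell and averaged over the levels of the other two factors (so unbalanced
#' replication does not tilt them); the fold change is the largest absolute
#' pairwise difference of level means, in log2 units.
#'
#' @param x an [OmicsSet] or matrix.
#' @param factorName `"variety"`, `"location"` or `"stage"`.
#' @param design optional design override.
#' @return named numeric vector of per-feature fold changes.
#' @export
computeGroupFoldChanges <- function(x, factorName, design = NULL) {
    m <- .matInput(x)
    design <- .designInput(x, design)
    if (!factorName %in% c("variety", "location", "stage"))
        stop("unknown factor: ", factorName)
    lv <- design[[factorName]]
    if (nlevels(lv) < 2L) stop("factor '", factorName, "' has a single level")
    if (!identical(colnames(m), design$sample_id))
        m <- m[, design$sample_id, drop = FALSE]
    cells <- interaction(design$variety, design$location, design$stage,
                         drop = TRUE)
    cellMeans <- t(rowsum(t(m), cells) / as.vector(table(cells)))
    cellLevel <- lv[match(levels(cells), as.character(cells))]
    levelMeans <- t(rowsum(t(cellMeans), cellLevel) /
                    as.vector(table(cellLevel)))
    combos <- utils::combn(ncol(levelMeans), 2L)
    fc <- apply(abs(levelMeans[, combos[1, ], drop = FALSE] -
                    levelMeans[, combos[2, ], drop = FALSE]), 1L, max)
    stats::setNames(fc, rownames(m))
}

#' Call differential features per factor
#'
#' Per factor, raw ANOVA p-values are BH-adjusted across features and a
#' feature is differential when the adjusted p falls below `alpha` AND its
#' fold change reaches `sdMult` standard deviations of the all-feature fold
#' change distribution for that factor (the magnitude filter only removes
#' calls, never adds them). The summary attribute reports per-factor counts,
#' the union, and pairwise intersections of the factor DE sets.
#'
#' @param fit an `anovaFit` from [fitFactorialAnova()].
#' @param fc named list of per-factor fold-change vectors from
#'   [computeGroupFoldChanges()] (names = factors).
#' @param alpha adjusted-p threshold.
#' @param sdMult fold-change multiplier (in SDs of the FC distribution).
#' @param factors which main-effect terms to call on.
#' @return a `DeTable` data.frame (one row per feature x factor) with
#'   columns feature_id, factor, p, p_adj, fc, fc_threshold, is_de, and a
#'   `"summary"` attribute.
#' @export
selectDifferentialFeatures <- function(fit, fc, alpha = 0.01, sdMult = 2,
                                       factors = c("variety", "location",
                                                   "stage")) {
    stopifnot(inherits(fit, "anovaFit"))
    if (!length(fit$feature_ids)) stop("empty feature universe")
    rows <- lapply(factors, function(f) {
        pRaw <- fit$p[, f]
        fcv <- fc[[f]][fit$feature_ids]
        if (any(is.na(fcv))) stop("fold changes missing for factor ", f)
        pAdj <- adjustBH(pRaw)
        thr <- sdMult * stats::sd(fcv)
        data.frame(feature_id = fit$feature_ids, factor = f, p = pRaw,
                   p_adj = pAdj, fc = fcv, fc_threshold = thr,
                   is_de = pAdj < alpha & fcv >= thr,
                   stringsAsFactors = FALSE, row.names = NULL)
    })
    de <- do.call(rbind, rows)
    sets <- lapply(factors, function(f)
        de$feature_id[de$factor == f & de$is_de])
    names(sets) <- factors
    pairs <- utils::combn(factors, 2L, simplify = FALSE)
    inter <- lapply(pairs, function(pr)
        length(intersect(sets[[pr[1]]], sets[[pr[2]]])))
    names(inter) <- vapply(pairs, paste, character(1), collapse = "&")
    attr(de, "summary") <- list(
        n_de = vapply(sets, length, integer(1)),
        n_union = length(unique(unlist(sets))),
        n_pairwise = unlist(inter), alpha = alpha, sd_mult = sdMult)
    class(de) <- c("DeTable", "data.frame")
    de
}
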