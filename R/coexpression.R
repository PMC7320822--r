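#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Soft-threshold diagnostics and power choice
#'
#' For each candidate power the unsigned adjacency is built, per-feature
#' connectivity k computed, k binned into (up to) 10 equal-count bins, and
#' log10(bin frequency) regressed on log10(mean bin k). The signed
#' scale-free fit index is `-sign(slope) * R^2`; the chosen power is the
#' smallest one whose signed fit reaches `r2Min`, falling back to
#' `defaultBeta` (with a warning) when none does.
#'
#' @param x an [OmicsSet] or matrix.
#' @param powers candidate soft powers.
#' @param r2Min required signed fit index.
#' @param defaultBeta fallback power when the criterion is not met.
#' @return list with `table` (power, fit, meanK, medianK, maxK) and `beta`.
#' @export
pickSoftThreshold <- function(x, powers = c(1:10, 12, 14, 16, 18, 20),
                              r2Min = 0.8, defaultBeta = 7) {
    m <- .matInput(x)
    if (nrow(m) < 50L)
        warning("fewer than 50 features: scale-free fit is unreliable")
    r <- abs(stats::cor(t(m), use = "pairwise.complete.obs"))
    diag(r) <- 0
    fitRow <- function(beta) {
        a <- r^beta
        k <- rowSums(a)
        if (all(k == 0)) stop("all connectivities are zero")
        nb <- min(10L, length(unique(k)))
        br <- unique(stats::quantile(k, seq(0, 1, length.out = nb + 1L)))
        bin <- cut(k, br, include.lowest = TRUE)
        freq <- as.vector(table(bin)) / length(k)
        kMean <- tapply(k, bin, mean)
        ok <- freq > 0 & kMean > 0
        if (sum(ok) < 3L) return(c(NA_real_, mean(k), stats::median(k), max(k)))
        fitlm <- stats::lm(log10(freq[ok]) ~ log10(kMean[ok]))
        r2 <- summary(fitlm)$r.squared
        slope <- stats::coef(fitlm)[2]
        c(-sign(slope) * r2, mean(k), stats::median(k), max(k))
    }
    tab <- t(vapply(powers, fitRow, numeric(4)))
    tab <- data.frame(power = powers, fit = tab[, 1], meanK = tab[, 2],
                      medianK = tab[, 3], maxK = tab[, 4])
    hit <- which(!is.na(tab$fit) & tab$fit >= r2Min)
    if (length(hit)) beta <- tab$power[hit[1]]
    else {
        warning("no power reached the scale-free fit criterion (",
                r2Min, "); using default beta ", defaultBeta)
        beta <- defaultBeta
    }
    list(table = tab, beta = beta)
}

#' Unsigned weighted adjacency
#'
#' `a_ij = |Pearson r(x_i, x_j)|^beta`, `a_ii = 1`. Zero-variance features
#' must be removed beforehand.
#'
#' @param x an [OmicsSet] or matrix.
#' @param beta soft power (> 0).
#' @return list of class `coexNetwork` with `adjacency`, `beta`,
#'   `connectivity` (k = row sums minus the diagonal).
#' @export
computeAdjacency <- function(x, beta = 7) {
    m <- .matInput(x)
    if (ncol(m) < 3L) stop("need at least 3 samples")
    if (beta <= 0) stop("beta must be positive")
    v <- apply(m, 1L, stats::var)
    if (any(v == 0, na.rm = TRUE))
        stop("zero-variance feature(s): ",
             paste(rownames(m)[v == 0], collapse = ", "),
             "; remove before network construction")
    a <- abs(stats::cor(t(m), use = "pairwise.complete.obs"))^beta
    diag(a) <- 1
    structure(list(adjacency = a, beta = beta,
                   connectivity = rowSums(a) - 1, tom = NULL),
              class = "coexNetwork")
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' i != j (the sum excluding u = i, j), `TOM_ii = 1`, where
#' `k_i = sum_u != i a_iu`. For adjacencies in \[0,1\] the denominator
#' dominates the numerator, so TOM lies in \[0,1\].
#'
#' @param net a `coexNetwork` from [computeAdjacency()].
#' @return the network with `tom` filled in.
#' @export
computeTOM <- function(net) {
    stopifnot(inherits(net, "coexNetwork"))
    a <- net$adjacency
    a0 <- a; diag(a0) <- 0
    k <- rowSums(a0)
    num <- a0 %*% a0 + a0
    den <- outer(k, k, pmin) + 1 - a0
    tom <- num / den
    diag(tom) <- 1
    dimnames(tom) <- dimnames(a)
    net$tom <- tom
    net
}

#' Detect modules by average-linkage clustering of the TOM dissimilarity
#'
#' Features are clustered by average linkage on `1 - TOM` and the tree is
#' cut statically. The default `"gap"` rule cuts at the midpoint of the
#' largest gap in the sorted merge heights: tight modules assemble at low
#' heights while background features and module-module joins merge near the
#' top, and the widest gap separates the two regimes without any tuned
#' height (a quantile-height cut, kept as `cutMethod = "quantile"`, places
#' the cut among the late noise merges whenever unassigned features
#' dominate, and then dissolves the module structure). Clusters with at
#' least `minSize` members become modules, named by decreasing size along
#' the conventional colour sequence (turquoise largest); everything else is
#' grey.
#'
#' @param net a `coexNetwork` with TOM computed.
#' @param minSize minimum module size (30 is a sensible transcript default,
#'   10 for metabolites).
#' @param cutMethod `"gap"` (largest merge-height gap) or `"quantile"`.
#' @param cutQuantile cut height as a quantile of merge heights, for
#'   `cutMethod = "quantile"`.
#' @return a [ModuleSet] (eigengenes and kME pending).
#' @export
detectModules <- function(net, minSize = 30L,
                          cutMethod = c("gap", "quantile"),
                          cutQuantile = 0.98) {
    cutMethod <- match.arg(cutMethod)
    stopifnot(inherits(net, "coexNetwork"))
    if (is.null(net$tom)) stop("TOM not computed; call computeTOM() first")
    d <- 1 - net$tom
    ids <- rownames(net$tom)
    if (minSize > length(ids)) {
        warning("minSize exceeds the number of features: everything is grey")
        assign <- stats::setNames(rep("grey", length(ids)), ids)
        return(new("ModuleSet", assignment = assign,
                   eigengenes = matrix(numeric(0), 0, 0),
                   kme = matrix(numeric(0), 0, 0),
                   kmeP = matrix(numeric(0), 0, 0),
                   minSize = as.integer(minSize),
                   params = list(beta = net$beta, cutMethod = cutMethod,
                                 cutQuantile = cutQuantile,
                                 cutHeight = NA_real_)))
    }
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    h <- sort(hc$height)
    cutHeight <- if (cutMethod == "gap" && length(h) >= 3L) {
        gaps <- diff(h)
        i <- which.max(gaps)
        rng <- h[length(h)] - h[1L]
        if (rng > 0 && gaps[i] >= 0.25 * rng) (h[i] + h[i + 1L]) / 2
        else if (h[length(h)] < 0.95) h[length(h)] + 1e-9
        else (h[i] + h[i + 1L]) / 2
        # no dominant gap: a coherent tree (all merges well below the ~1
        # dissimilarity of unrelated features) is one module; an incoherent
        # one falls through to the gap cut and dissolves into grey
    } else stats::quantile(h, cutQuantile, names = FALSE)
    cl <- stats::cutree(hc, h = cutHeight)
    sizes <- table(cl)
    big <- names(sizes)[sizes >= minSize]
    ord <- big[order(-sizes[big], as.integer(big))]
    lab <- stats::setNames(.moduleName(seq_along(ord)), ord)
    assign <- ifelse(as.character(cl) %in% big,
                     lab[as.character(cl)], "grey")
    names(assign) <- ids
    new("ModuleSet", assignment = assign,
        eigengenes = matrix(numeric(0), 0, 0),
        kme = matrix(numeric(0), 0, 0),
        kmeP = matrix(numeric(0), 0, 0),
        minSize = as.integer(minSize),
        params = list(beta = net$beta, cutMethod = cutMethod,
                      cutQuantile = cutQuantile,
                      cutHeight = cutHeight))
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component, across
#' samples, of its standardized member profiles, scaled to unit variance
#' and oriented so that the mean correlation with member profiles is
#' non-negative. A single-feature module's eigengene is that standardized
#' profile.
#'
#' @param x the [OmicsSet] or matrix the modules were detected on.
#' @param mset a [ModuleSet].
#' @return the `ModuleSet` with `eigengenes` filled (modules x samples).
#' @export
computeEigengenes <- function(x, mset) {
    stopifnot(is(mset, "ModuleSet"))
    m <- .matInput(x)
    labels <- moduleLabels(mset)
    if (!length(labels)) stop("no non-grey modules to summarize")
    eg <- matrix(NA_real_, length(labels), ncol(m),
                 dimnames = list(labels, colnames(m)))
    for (lab in labels) {
        members <- names(mset@assignment)[mset@assignment == lab]
        sub <- m[members, , drop = FALSE]
        subz <- t(scale(t(sub)))           # per-feature mean 0, sd 1
        if (nrow(subz) == 1L) {
            message("module ", lab, " has a single member; eigengene equals it")
            e <- subz[1L, ]
        } else {
            sv <- svd(t(subz), nu = 1L, nv = 0L)
            e <- sv$u[, 1L]
        }
        e <- e / stats::sd(e)
        if (mean(stats::cor(e, t(subz))) < 0) e <- -e
        eg[lab, ] <- e
    }
    mset@eigengenes <- eg
    validObject(mset)
    mset
}

#' Module membership (kME) and its significance
#'
#' `kME(f, m)` is the Pearson correlation of feature f's profile with
#' module m's eigengene; the p-value is the two-sided t-test with
#' `t = r sqrt(n-2) / sqrt(1-r^2)`, df = n - 2.
#'
#' @param x the [OmicsSet] or matrix.
#' @param mset a [ModuleSet] with eigengenes computed.
#' @return the `ModuleSet` with `kme` and `kmeP` filled
#'   (features x modules).
#' @export
computeKME <- function(x, mset) {
    stopifnot(is(mset, "ModuleSet"))
    if (!nrow(mset@eigengenes))
        stop("eigengenes not computed; call computeEigengenes() first")
    m <- .matInput(x)
    n <- ncol(m)
    if (n < 4L) stop("kME needs at least 4 samples")
    kme <- stats::cor(t(m), t(mset@eigengenes),
                      use = "pairwise.complete.obs")
    kmeP <- matrix(.pearsonP(kme, n), nrow(kme), ncol(kme),
                   dimnames = dimnames(kme))
    mset@kme <- kme
    mset@kmeP <- kmeP
    validObject(mset)
    mset
}

#' Optionally merge modules with highly correlated eigengenes
#'
#' Off by default in the pipeline. Modules whose eigengene correlation
#' exceeds `corThreshold` are merged (the larger module's name wins) and
#' eigengenes are recomputed.
#'
#' @param x the data the modules came from.
#' @param mset a [ModuleSet] with eigengenes.
#' @param corThreshold eigengene correlation above which modules merge.
#' @return a `ModuleSet` with merged assignment and fresh eigengenes.
#' @export
mergeCloseModules <- function(x, mset, corThreshold = 0.9) {
    stopifnot(is(mset, "ModuleSet"))
    if (!nrow(mset@eigengenes)) mset <- computeEigengenes(x, mset)
    repeat {
        labs <- moduleLabels(mset)
        if (length(labs) < 2L) break
        cc <- stats::cor(t(mset@eigengenes[labs, , drop = FALSE]))
        diag(cc) <- 0
        mx <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
        if (cc[mx[1], mx[2]] <= corThreshold) break
        keepLab <- labs[min(mx)]; dropLab <- labs[max(mx)]
        a <- mset@assignment
        a[a == dropLab] <- keepLab
        mset@assignment <- a
        mset@eigengenes <- matrix(numeric(0), 0, 0)
        mset@kme <- matrix(numeric(0), 0, 0)
        mset@kmeP <- matrix(numeric(0), 0, 0)
        mset <- computeEigengenes(x, mset)
    }
    mset
}
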