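#' @include AllClasses.R AllGenerics.R utils.R
NULL

.defaultBins <- function(n) max(2L, floor(n^(1/3) + 1e-9))

.rankBins <- function(v, B) {
    # equal-frequency bins; ties broken by position (deterministic)
    ceiling(rank(v, ties.method = "first") * B / length(v))
}

.miFromCounts <- function(counts, n) {
    pj <- counts / n
    px <- rowSums(pj); py <- colSums(pj)
    nz <- pj > 0
    sum(pj[nz] * log(pj[nz] / outer(px, py)[nz]))
}

#' Plug-in mutual information with equal-frequency binning
#'
#' Both vectors are rank-transformed into `bins` equal-frequency bins
#' (default `floor(n^(1/3))`, at least 2 — the cube-root rule, whose null
#' bias `(B-1)^2 / (2n)` vanishes with n) and the plug-in estimate
#' `sum p(i,j) ln(p(i,j) / (p(i) p(j)))` is returned, in nats. It is
#' symmetric and non-negative; for `y = x` with n divisible by B it equals
#' `ln B` exactly.
#'
#' @param x,y numeric vectors of equal length (>= 8).
#' @param bins number of bins per margin, or NULL for the default.
#' @return mutual information in nats.
#' @export
estimateMI <- function(x, y, bins = NULL) {
    n <- length(x)
    if (length(y) != n) stop("x and y must have equal length")
    if (n < 8L) stop("need at least 8 observations")
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning("constant vector: MI is 0")
        return(0)
    }
    B <- if (is.null(bins)) .defaultBins(n) else as.integer(bins)
    if (B < 2L) stop("bins must be >= 2")
    bx <- .rankBins(x, B); by <- .rankBins(y, B)
    counts <- matrix(tabulate((by - 1L) * B + bx, B * B), B, B)
    .miFromCounts(counts, n)
}

# draw n_perm null MI values for sample size n and B bins: the joint of two
# independent rank-binned variables depends only on a random permutation
.sampleNullMI <- function(n, B, nPerm) {
    bx <- ceiling(seq_len(n) * B / n)
    out <- numeric(nPerm)
    for (i in seq_len(nPerm)) {
        by <- bx[sample.int(n)]
        counts <- matrix(tabulate((by - 1L) * B + bx, B * B), B, B)
        out[i] <- .miFromCounts(counts, n)
    }
    out
}

# generalized Pareto quantile extrapolation fitted to the exceedances over
# the tail threshold u (MLE); shape 0 reduces to the exponential tail
.gpdFit <- function(excess) {
    negll <- function(par) {
        sigma <- exp(par[1]); xi <- par[2]
        z <- 1 + xi * excess / sigma
        if (any(z <= 0)) return(1e10)
        sum(log(sigma) + (1 / xi + 1) * log(z))
    }
    init <- c(log(mean(excess)), 0.01)
    opt <- stats::optim(init, negll, method = "Nelder-Mead")
    list(sigma = exp(opt$par[1]), xi = opt$par[2])
}

.gpdQuantile <- function(u, sigma, xi, pU, pTarget) {
    if (abs(xi) < 1e-8) u + sigma * log(pU / pTarget)
    else u + sigma / xi * ((pU / pTarget)^xi - 1)
}

.gpdTailP <- function(q, u, sigma, xi, pU) {
    z <- pmax(1 + xi * (q - u) / sigma, 0)
    pU * z^(-1 / xi)
}

#' Calibrate an MI significance threshold from the permutation null
#'
#' Draws `nPerm` null MI values (independent random pairings at the given
#' sample size and bin count). Bulk targets (`pTarget >= 0.05`) use the
#' empirical null quantile; tail targets (such as the 1e-8 working
#' threshold) are extrapolated from a generalized Pareto fit to the
#' exceedances over the null 95th percentile, raw permutation counts being
#' hopeless at such depths.
#'
#' @param nSamples sample size the networks will be built at.
#' @param bins bin count (NULL for the default rule).
#' @param pTarget tail probability of the returned threshold.
#' @param nPerm permutation draws (>= 1000).
#' @param seed RNG seed.
#' @return the MI cutoff, with the tail fit attached as attribute
#'   `"tail"` (u, sigma, xi, pU) so edge p-values can be estimated.
#' @export
calibrateMiThreshold <- function(nSamples, bins = NULL, pTarget = 1e-8,
                                 nPerm = 100000L, seed = 1) {
    if (nPerm < 1000L) stop("nPerm must be >= 1000")
    if (pTarget <= 0 || pTarget >= 1) stop("pTarget must lie in (0,1)")
    B <- if (is.null(bins)) .defaultBins(nSamples) else as.integer(bins)
    set.seed(as.integer(seed))
    null <- .sampleNullMI(nSamples, B, nPerm)
    if (all(null == 0)) stop("degenerate null: all permutation MI values are 0")
    u <- stats::quantile(null, 0.95, names = FALSE)
    fit <- .gpdFit(null[null > u] - u)
    thr <- if (pTarget >= 0.05)
        stats::quantile(null, 1 - pTarget, names = FALSE)
    else .gpdQuantile(u, fit$sigma, fit$xi, 0.05, pTarget)
    attr(thr, "tail") <- list(u = u, sigma = fit$sigma, xi = fit$xi,
                              pU = 0.05, n = nSamples, bins = B,
                              nullEcdf = stats::ecdf(null))
    attr(thr, "pTarget") <- pTarget
    thr
}

#' Tail p-value of an observed MI under the calibrated null
#'
#' Below the tail threshold the empirical permutation distribution is used;
#' above it, the fitted generalized Pareto tail.
#'
#' @param mi observed MI value(s).
#' @param threshold result of [calibrateMiThreshold()].
#' @return p-value(s).
#' @export
miTailP <- function(mi, threshold) {
    tail <- attr(threshold, "tail")
    if (is.null(tail)) return(rep(NA_real_, length(mi)))
    p <- 1 - tail$nullEcdf(mi)
    hi <- mi > tail$u
    p[hi] <- .gpdTailP(mi[hi], tail$u, tail$sigma, tail$xi, tail$pU)
    pmax(p, 0)
}

#' Build a regulator-target MI network within one co-expression module
#'
#' MI is computed for every (regulator, feature) pair over the module's
#' feature universe; both orientations collapse to one undirected edge, and
#' edges with MI at or above the threshold are kept. Regulators absent from
#' the matrix are ignored with a message.
#'
#' @param x an [OmicsSet] or matrix restricted to one module's features.
#' @param regulators character vector of regulator feature ids.
#' @param threshold MI cutoff, typically from [calibrateMiThreshold()].
#' @param bins bin count (NULL for the default rule).
#' @param module module label for bookkeeping.
#' @return a [MiNetwork] (DPI pending: `kept_after_dpi` is NA).
#' @export
buildRegulatorNetwork <- function(x, regulators, threshold, bins = NULL,
                                  module = "unknown") {
    m <- .matInput(x)
    regs <- intersect(regulators, rownames(m))
    dropped <- setdiff(regulators, regs)
    if (length(dropped))
        message(length(dropped), " regulator(s) not in the feature universe; ignored")
    pThr <- attr(threshold, "pTarget")
    if (is.null(pThr)) pThr <- NA_real_
    empty <- data.frame(regulator = character(), target = character(),
                        mi = numeric(), p = numeric(),
                        kept_after_dpi = logical())
    if (!length(regs)) {
        warning("no regulators present in the feature universe")
        return(new("MiNetwork", edges = empty, regulators = character(),
                   module = module, miThreshold = as.numeric(threshold),
                   pThreshold = pThr))
    }
    B <- if (is.null(bins)) .defaultBins(ncol(m)) else as.integer(bins)
    seen <- character(0)
    rows <- list()
    for (r in regs) {
        others <- setdiff(rownames(m), c(r, seen))
        for (tg in others) {
            mi <- estimateMI(m[r, ], m[tg, ], bins = B)
            if (mi >= threshold)
                rows[[length(rows) + 1L]] <-
                    data.frame(regulator = r, target = tg, mi = mi,
                               p = NA_real_, kept_after_dpi = NA,
                               stringsAsFactors = FALSE)
        }
        seen <- c(seen, r)                  # collapse reg-reg duplicates
    }
    edges <- if (length(rows)) do.call(rbind, rows) else empty
    if (nrow(edges) && !is.null(attr(threshold, "tail")))
        edges$p <- miTailP(edges$mi, threshold)
    new("MiNetwork", edges = edges, regulators = regs, module = module,
        miThreshold = as.numeric(threshold), pThreshold = pThr)
}

#' Prune indirect edges with the data-processing inequality
#'
#' For every triangle of the original network, the weakest edge is marked
#' removed when its MI is strictly below `(1 - tolerance)` times the
#' smaller of the other two. All triangles are evaluated on the input edge
#' set, so re-application is idempotent; original MI values are retained
#' and `kept_after_dpi` records the outcome.
#'
#' @param net a [MiNetwork].
#' @param tolerance in \[0,1\]; 1 disables the rule.
#' @return the `MiNetwork` with `kept_after_dpi` filled.
#' @export
applyDPI <- function(net, tolerance = 0) {
    stopifnot(is(net, "MiNetwork"))
    e <- net@edges
    if (!nrow(e)) return(net)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    w <- stats::setNames(e$mi, key(e$regulator, e$target))
    nodes <- unique(c(e$regulator, e$target))
    nbr <- lapply(stats::setNames(nodes, nodes), function(v)
        unique(c(e$target[e$regulator == v], e$regulator[e$target == v])))
    removed <- logical(nrow(e))
    for (i in seq_len(nrow(e))) {
        a <- e$regulator[i]; b <- e$target[i]
        common <- intersect(nbr[[a]], nbr[[b]])
        for (k in common) {
            other <- min(w[key(a, k)], w[key(b, k)])
            if (e$mi[i] < (1 - tolerance) * other) {
                removed[i] <- TRUE
                break
            }
        }
    }
    e$kept_after_dpi <- !removed
    net@edges <- e
    net
}
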