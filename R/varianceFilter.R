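#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Per-feature coefficient of variation
#'
#' CV = sample SD / mean across all samples. By default the log2 assay is
#' mapped back to the linear scale (`2^x`) first, where the CV is
#' well-defined and scale-invariant; `cvScale = "log"` computes it on the
#' stored log2 values instead (features with non-positive mean are then
#' rejected).
#'
#' @param x an [OmicsSet] or numeric matrix (features x samples).
#' @param cvScale `"linear"` or `"log"`.
#' @return named numeric vector of CVs.
#' @export
computeCV <- function(x, cvScale = c("linear", "log")) {
    cvScale <- match.arg(cvScale)
    m <- .matInput(x)
    if (ncol(m) < 2L) stop("CV needs at least 2 samples")
    if (cvScale == "linear") m <- 2^m
    mu <- rowMeans(m)
    s <- apply(m, 1L, stats::sd)
    bad <- mu <= 0
    if (any(bad)) {
        zeroVar <- bad & s == 0
        if (any(zeroVar))
            stop("zero-variance feature with non-positive mean: ",
                 paste(rownames(m)[zeroVar], collapse = ", "))
        stop("feature(s) with non-positive mean rejected: ",
             paste(rownames(m)[bad], collapse = ", "))
    }
    s / mu
}

.emLoglik <- function(x, w, mu, sd) {
    d <- w[1] * stats::dnorm(x, mu[1], sd[1]) +
         w[2] * stats::dnorm(x, mu[2], sd[2])
    sum(log(pmax(d, 1e-300)))
}

.emOnce <- function(x, w, mu, sd, tol, maxIter, sdFloor) {
    trace <- numeric(0)
    ll <- -Inf
    for (it in seq_len(maxIter)) {
        d1 <- w[1] * stats::dnorm(x, mu[1], sd[1])
        d2 <- w[2] * stats::dnorm(x, mu[2], sd[2])
        tot <- pmax(d1 + d2, 1e-300)
        g2 <- d2 / tot                       # responsibility of component 2
        g1 <- 1 - g2
        n1 <- sum(g1); n2 <- sum(g2)
        if (n1 < 1e-8 || n2 < 1e-8) return(NULL)
        w <- c(n1, n2) / length(x)
        mu <- c(sum(g1 * x) / n1, sum(g2 * x) / n2)
        sd <- sqrt(c(sum(g1 * (x - mu[1])^2) / n1,
                     sum(g2 * (x - mu[2])^2) / n2))
        if (any(sd < sdFloor)) return(NULL)  # degenerate collapse
        llNew <- .emLoglik(x, w, mu, sd)
        trace <- c(trace, llNew)
        if (is.finite(ll) && abs(llNew - ll) < tol)
            return(list(w = w, mu = mu, sd = sd, loglik = llNew,
                        trace = trace, nIter = it, converged = TRUE,
                        g2 = g2))
        ll <- llNew
    }
    list(w = w, mu = mu, sd = sd, loglik = ll, trace = trace,
         nIter = maxIter, converged = FALSE, g2 = g2)
}

#' Fit a two-component Gaussian mixture by expectation-maximization
#'
#' Decomposes a per-feature statistic (typically the CV distribution) into
#' low- and high-mean Gaussian components. Initialization splits the data at
#' the median; up to `nRestarts` additional random quantile splits are run
#' and the best log-likelihood kept. Components are ordered so
#' `means[1] < means[2]`; `posteriorHigh` is the posterior probability of
#' the high-mean component.
#'
#' @param cv named numeric vector (>= 10 values).
#' @param tol convergence tolerance on the log-likelihood change.
#' @param maxIter maximum EM iterations per start.
#' @param seed RNG seed for the random restarts.
#' @param nRestarts random restarts after the median-split start.
#' @return a [MixtureFit].
#' @export
fitGaussianMixtureEM <- function(cv, tol = 1e-8, maxIter = 500L, seed = 1,
                                 nRestarts = 5L) {
    x <- as.numeric(cv)
    if (length(x) < 10L) stop("need at least 10 values to fit a mixture")
    if (any(!is.finite(x))) stop("non-finite values in input")
    if (tol <= 0) stop("tol must be positive")
    sdAll <- stats::sd(x)
    if (sdAll == 0) stop("degenerate fit: all values identical")
    sdFloor <- 1e-6 * sdAll
    set.seed(as.integer(seed))
    splits <- c(0.5, stats::runif(nRestarts, 0.15, 0.85))
    best <- NULL
    for (q in splits) {
        cut <- stats::quantile(x, q, names = FALSE)
        lo <- x[x <= cut]; hi <- x[x > cut]
        if (length(lo) < 2L || length(hi) < 2L) next
        init <- list(w = c(length(lo), length(hi)) / length(x),
                     mu = c(mean(lo), mean(hi)),
                     sd = pmax(c(stats::sd(lo), stats::sd(hi)), sdFloor * 10))
        fit <- .emOnce(x, init$w, init$mu, init$sd, tol, maxIter, sdFloor)
        if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
            best <- fit
    }
    if (is.null(best))
        stop("degenerate fit: every EM start collapsed a component")
    ord <- order(best$mu)
    postHigh <- if (ord[1] == 1L) best$g2 else 1 - best$g2
    names(postHigh) <- names(cv)
    new("MixtureFit", weights = best$w[ord], means = best$mu[ord],
        sds = best$sd[ord], loglik = best$loglik, loglikTrace = best$trace,
        nIter = as.integer(best$nIter), converged = best$converged,
        posteriorHigh = postHigh)
}

#' Retain features assigned to the high-variability mixture component
#'
#' Keeps features whose posterior probability of the high-mean component is
#' at least `cutoff` (0.5 = maximum a posteriori). Sample order is
#' preserved; kept/total counts are reported.
#'
#' @param x the [OmicsSet] (or matrix) the mixture was fitted on.
#' @param fit a [MixtureFit] whose `posteriorHigh` is named by feature.
#' @param cutoff posterior cutoff in \[0,1\].
#' @return the filtered `OmicsSet` (or matrix).
#' @export
selectHighVariance <- function(x, fit, cutoff = 0.5) {
    stopifnot(is(fit, "MixtureFit"))
    if (!fit@converged) stop("mixture fit did not converge; refit first")
    ph <- fit@posteriorHigh
    m <- .matInput(x)
    ph <- ph[rownames(m)]
    if (any(is.na(ph)))
        stop("posteriorHigh is missing for some features of the matrix")
    keep <- ph >= cutoff
    if (!any(keep))
        stop("no features retained at cutoff ", cutoff,
             "; review the cutoff or the fit")
    message(sprintf("variance filter: retained %d / %d features (cutoff %.2f)",
                    sum(keep), length(keep), cutoff))
    if (is(x, "OmicsSet")) x[keep, ] else m[keep, , drop = FALSE]
}
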