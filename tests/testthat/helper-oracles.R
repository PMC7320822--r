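# Independent brute-force oracles used to pin expected values.

# Classical sequential-projection ANOVA decomposition for balanced full
# factorials: SS of a term is the increase in explained sum of squares when
# its columns enter, computed through explicit hat matrices.
anovaProjectionOracle <- function(y, design) {
    op <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(op))
    forms <- list(
        ~1,
        ~variety,
        ~variety + location,
        ~variety + location + stage,
        ~variety + location + stage + variety:location,
        ~variety + location + stage + variety:location + variety:stage,
        ~variety + location + stage + variety:location + variety:stage +
            location:stage,
        ~variety * location * stage)
    hat <- function(f) {
        X <- stats::model.matrix(f, data = design)
        X %*% MASS::ginv(crossprod(X)) %*% t(X)
    }
    Ps <- lapply(forms, hat)
    fitted <- vapply(Ps, function(P) sum((P %*% y)^2), numeric(1))
    ranks <- vapply(forms, function(f)
        qr(stats::model.matrix(f, data = design))$rank, numeric(1))
    ssTerm <- diff(fitted)
    dfTerm <- diff(ranks)
    ssRes <- sum(y^2) - fitted[length(fitted)]
    dfRes <- length(y) - ranks[length(ranks)]
    Fv <- (ssTerm / dfTerm) / (ssRes / dfRes)
    terms <- c("variety", "location", "stage", "variety:location",
               "variety:stage", "location:stage", "variety:location:stage")
    list(terms = terms, ss = stats::setNames(ssTerm, terms),
         df = stats::setNames(dfTerm, terms),
         F = stats::setNames(Fv, terms),
         p = stats::setNames(stats::pf(Fv, dfTerm, dfRes,
                                       lower.tail = FALSE), terms),
         residual_ss = ssRes, residual_df = dfRes)
}

# topological overlap by direct triple loop
tomTripleLoopOracle <- function(a) {
    n <- nrow(a)
    a0 <- a; diag(a0) <- 0
    k <- rowSums(a0)
    tom <- diag(n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        num <- a0[i, j]
        for (u in seq_len(n)) if (u != i && u != j)
            num <- num + a0[i, u] * a0[u, j]
        tom[i, j] <- num / (min(k[i], k[j]) + 1 - a0[i, j])
    }
    tom
}

# hypergeometric upper tail by direct summation of the pmf
hypergeomTailOracle <- function(ov, m, N, nSel) {
    ks <- ov:min(m, nSel)
    sum(choose(m, ks) * choose(N - m, nSel - ks)) / choose(N, nSel)
}

# chi-square survival by numerical integration of the density formula
chisqSurvivalOracle <- function(x2, df) {
    stats::integrate(function(t) t^(df / 2 - 1) * exp(-t / 2) /
                         (2^(df / 2) * gamma(df / 2)),
                     x2, Inf, rel.tol = 1e-12)$value
}

# two-sided t-test p by numerical integration of the t density
tTwoSidedOracle <- function(tstat, df) {
    dens <- function(u) gamma((df + 1) / 2) /
        (sqrt(df * pi) * gamma(df / 2)) * (1 + u^2 / df)^(-(df + 1) / 2)
    2 * stats::integrate(dens, abs(tstat), Inf, rel.tol = 1e-12)$value
}

# small balanced design builder
makeDesign <- function(nV = 2, nL = 2, nS = 2, nR = 2) {
    simulateDesign(simulationConfig(design = c(nV, nL, nS, nR)))
}

randomBalancedData <- function(seed, nV = 2, nL = 2, nS = 2, nR = 2) {
    set.seed(seed)
    d <- makeDesign(nV, nL, nS, nR)
    y <- rnorm(nrow(d))
    list(design = d, y = y)
}
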