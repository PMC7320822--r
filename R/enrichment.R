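#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Pathway over-representation by the hypergeometric (Fisher) test
#'
#' One row per pathway set: members are intersected with the universe, the
#' one-sided over-representation p-value is the hypergeometric upper tail
#' of the selected/set overlap, p-values are BH-adjusted across all tested
#' sets, and sets with FDR below `fdrThreshold` are flagged. Sets with no
#' members in the universe are skipped with a message. `alternative =
#' "two.sided"` switches to the two-sided Fisher exact test.
#'
#' @param selected character vector of selected feature ids (must be a
#'   subset of `universe`).
#' @param universe character vector of all testable feature ids.
#' @param pathways named list of member-id vectors (see [readGMT()]).
#' @param fdrThreshold FDR significance level.
#' @param alternative `"greater"` (over-representation) or `"two.sided"`.
#' @return data.frame sorted by p with columns set_name, n_universe, n_set,
#'   n_selected, n_overlap, odds_ratio, p, fdr, significant.
#' @export
fisherEnrichment <- function(selected, universe, pathways,
                             fdrThreshold = 0.05,
                             alternative = c("greater", "two.sided")) {
    alternative <- match.arg(alternative)
    selected <- unique(selected); universe <- unique(universe)
    stray <- setdiff(selected, universe)
    if (length(stray))
        stop("selected ids outside the universe: ",
             paste(utils::head(stray, 5), collapse = ", "),
             if (length(stray) > 5) " ..." else "")
    N <- length(universe); nSel <- length(selected)
    rows <- list()
    for (nm in names(pathways)) {
        mem <- intersect(pathways[[nm]], universe)
        if (!length(mem)) {
            message("pathway '", nm, "' has no members in the universe; skipped")
            next
        }
        m <- length(mem)
        ov <- length(intersect(mem, selected))
        p <- if (alternative == "greater")
            stats::phyper(ov - 1L, m, N - m, nSel, lower.tail = FALSE)
        else
            stats::fisher.test(matrix(c(ov, m - ov, nSel - ov,
                                        N - m - nSel + ov), 2L),
                               alternative = "two.sided")$p.value
        orNum <- ov * (N - m - nSel + ov)
        orDen <- (m - ov) * (nSel - ov)
        rows[[nm]] <- data.frame(
            set_name = nm, n_universe = N, n_set = m, n_selected = nSel,
            n_overlap = ov,
            odds_ratio = if (orDen == 0) Inf else orNum / orDen,
            p = p, stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(data.frame(set_name = character(), n_universe = integer(),
                          n_set = integer(), n_selected = integer(),
                          n_overlap = integer(), odds_ratio = numeric(),
                          p = numeric(), fdr = numeric(),
                          significant = logical()))
    out <- do.call(rbind, rows)
    out$fdr <- adjustBH(out$p)
    out$significant <- out$fdr < fdrThreshold
    out <- out[order(out$p, out$set_name), , drop = FALSE]
    rownames(out) <- NULL
    out
}
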