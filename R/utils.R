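#' @include AllClasses.R
NULL

# conventional module colour sequence, largest module first
.MODULE_COLOURS <- c(
    "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue")

.moduleName <- function(i) {
    ifelse(i <= length(.MODULE_COLOURS), .MODULE_COLOURS[i],
           paste0("module", i))
}

# accept either an OmicsSet or a named numeric matrix
.matInput <- function(x) {
    if (is(x, "OmicsSet")) return(abundances(x))
    if (is.matrix(x) && is.numeric(x)) {
        if (is.null(rownames(x)))
            rownames(x) <- sprintf("feature_%04d", seq_len(nrow(x)))
        if (is.null(colnames(x)))
            colnames(x) <- sprintf("sample_%03d", seq_len(ncol(x)))
        return(x)
    }
    stop("expected an OmicsSet or a numeric matrix (features x samples)")
}

.designInput <- function(x, design = NULL) {
    if (!is.null(design)) return(.validateDesign(design))
    if (is(x, "OmicsSet")) return(.validateDesign(designTable(x)))
    stop("a sample design is required (attachDesign() or `design=`)")
}

.validateDesign <- function(d) {
    d <- as.data.frame(d)
    need <- c("sample_id", "variety", "location", "stage", "replicate")
    miss <- setdiff(need, names(d))
    if (length(miss))
        stop("design is missing column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(d$sample_id))
        stop("duplicate sample_id in design: ",
             paste(unique(d$sample_id[duplicated(d$sample_id)]),
                   collapse = ", "))
    for (f in c("variety", "location", "stage"))
        if (!is.factor(d[[f]]))
            d[[f]] <- factor(d[[f]], levels = unique(d[[f]]))
    if (!is.factor(d$stage)) d$stage <- factor(d$stage, levels = unique(d$stage))
    d$replicate <- as.integer(d$replicate)
    if (any(is.na(d$replicate)) || any(d$replicate < 1L))
        stop("replicate must be a positive integer")
    d
}

# deterministic full-precision number formatting for TSV round-trips
.fmtNum <- function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NA"
    out
}

.pearsonP <- function(r, n) {
    # two-sided t-test for a Pearson correlation, df = n - 2
    r <- pmin(pmax(r, -1), 1)
    tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
    p[abs(r) >= 1 - 1e-15] <- 0
    p
}
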