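#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' OmicsSet: a feature-by-sample abundance matrix with its factorial design
#'
#' `OmicsSet` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single `"log2"` assay holding log2-scale abundances (transcript
#' intensities or metabolite levels), and an `omicsKind` tag. The factorial
#' design (variety, location, stage, replicate) lives in `colData`.
#'
#' Validity requires unique feature and sample identifiers, at least 2
#' features and 4 samples, and (unless `metadata(x)$allowMissing` is TRUE)
#' all-finite values.
#'
#' @slot omicsKind either `"transcript"` or `"metabolite"`.
#' @export
setClass("OmicsSet",
         contains = "SummarizedExperiment",
         representation(omicsKind = "character"))

setValidity("OmicsSet", function(object) {
    msg <- character()
    if (length(object@omicsKind) != 1L ||
        !object@omicsKind %in% c("transcript", "metabolite"))
        msg <- c(msg, "omicsKind must be 'transcript' or 'metabolite'")
    if (!"log2" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'log2' is required")
    if (nrow(object) < 2L) msg <- c(msg, "need at least 2 features")
    if (ncol(object) < 4L) msg <- c(msg, "need at least 4 samples")
    fid <- rownames(object); sid <- colnames(object)
    if (is.null(fid) || anyDuplicated(fid))
        msg <- c(msg, sprintf("duplicate or missing feature ids%s",
                 if (!is.null(fid)) paste0(": ",
                     paste(unique(fid[duplicated(fid)]), collapse = ", "))
                 else ""))
    if (is.null(sid) || anyDuplicated(sid))
        msg <- c(msg, sprintf("duplicate or missing sample ids%s",
                 if (!is.null(sid)) paste0(": ",
                     paste(unique(sid[duplicated(sid)]), collapse = ", "))
                 else ""))
    v <- SummarizedExperiment::assay(object, "log2")
    if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
    allowNA <- isTRUE(S4Vectors::metadata(object)$allowMissing)
    if (is.numeric(v) && !allowNA && !all(is.finite(v)))
        msg <- c(msg, "non-finite values present (strict missing-value policy)")
    if (length(msg)) msg else TRUE
})

#' Construct an OmicsSet
#'
#' @param values numeric matrix, features in rows, samples in columns, log2
#'   scale. Row and column names are the feature and sample identifiers.
#' @param omicsKind `"transcript"` or `"metabolite"`.
#' @param design optional data.frame of per-sample factor levels (see
#'   [readSampleDesign()]); when supplied, columns of `values` are reordered
#'   to the design's sample order.
#' @param allowMissing logical; permit NA values (correlation stages then use
#'   pairwise-complete samples, ANOVA still requires complete rows).
#' @return an `OmicsSet`.
#' @export
OmicsSet <- function(values, omicsKind = c("transcript", "metabolite"),
                     design = NULL, allowMissing = FALSE) {
    omicsKind <- match.arg(omicsKind)
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    cd <- S4Vectors::DataFrame(row.names = colnames(values))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2 = values), colData = cd,
        metadata = list(allowMissing = isTRUE(allowMissing)))
    obj <- new("OmicsSet", se, omicsKind = omicsKind)
    validObject(obj)
    if (!is.null(design)) obj <- attachDesign(obj, design)
    obj
}

#' Two-component Gaussian mixture fit of a per-feature statistic
#'
#' Returned by [fitGaussianMixtureEM()]. Components are ordered so that
#' `means[1] < means[2]`; `posteriorHigh` is each feature's posterior
#' probability of belonging to the high-mean component.
#'
#' @slot weights,means,sds length-2 numeric component parameters.
#' @slot loglik final log-likelihood; @slot loglikTrace per-iteration values.
#' @slot nIter iterations used; @slot converged logical.
#' @slot posteriorHigh named numeric in \[0,1\].
#' @export
setClass("MixtureFit",
         representation(weights = "numeric", means = "numeric",
                        sds = "numeric", loglik = "numeric",
                        loglikTrace = "numeric", nIter = "integer",
                        converged = "logical", posteriorHigh = "numeric"))

setValidity("MixtureFit", function(object) {
    msg <- character()
    if (length(object@weights) != 2L || any(object@weights <= 0) ||
        abs(sum(object@weights) - 1) > 1e-9)
        msg <- c(msg, "weights must be two positives summing to 1")
    if (length(object@means) != 2L || object@means[1] > object@means[2])
        msg <- c(msg, "means must be ordered low, high")
    if (length(object@sds) != 2L || any(object@sds <= 0))
        msg <- c(msg, "sds must be two positive reals")
    tr <- object@loglikTrace
    if (length(tr) > 1L && any(diff(tr) < -1e-6 * max(1, abs(tr[1]))))
        msg <- c(msg, "log-likelihood trace must be non-decreasing")
    ph <- object@posteriorHigh
    if (length(ph) && (any(ph < -1e-12) || any(ph > 1 + 1e-12)))
        msg <- c(msg, "posteriorHigh must lie in [0,1]")
    if (length(msg)) msg else TRUE
})

#' Co-expression module set with eigengenes and kME
#'
#' Produced incrementally: [detectModules()] fills the assignment,
#' [computeEigengenes()] the eigengene profiles, [computeKME()] the module
#' membership statistics. Modules are named by decreasing size following the
#' conventional colour sequence (turquoise, blue, brown, ...); features not
#' assigned to any module carry the label `"grey"`.
#'
#' @slot assignment named character, feature id -> module label.
#' @slot eigengenes modules x samples matrix, each row unit variance.
#' @slot kme features x modules matrix of Pearson correlations.
#' @slot kmeP matching two-sided p-values.
#' @slot minSize minimum module size used at detection.
#' @slot params list of detection parameters (beta, cutQuantile, cutHeight).
#' @export
setClass("ModuleSet",
         representation(assignment = "character", eigengenes = "matrix",
                        kme = "matrix", kmeP = "matrix",
                        minSize = "integer", params = "list"))

setValidity("ModuleSet", function(object) {
    msg <- character()
    a <- object@assignment
    if (is.null(names(a))) return("assignment must be named by feature id")
    sz <- table(a[a != "grey"])
    if (length(sz) && length(object@minSize) == 1L &&
        any(sz < object@minSize))
        msg <- c(msg, "non-grey module smaller than minSize")
    eg <- object@eigengenes
    if (nrow(eg)) {
        v <- apply(eg, 1L, stats::var)
        if (any(abs(v - 1) > 1e-6))
            msg <- c(msg, "eigengene profiles must have unit variance")
        if (!all(rownames(eg) %in% unique(a)))
            msg <- c(msg, "eigengene rows must match module labels")
    }
    if (nrow(object@kme) && !identical(dim(object@kme), dim(object@kmeP)))
        msg <- c(msg, "kme and kmeP dimensions differ")
    if (length(msg)) msg else TRUE
})

#' Mutual-information regulator network for one co-expression module
#'
#' Undirected regulator-target edges weighted by mutual information (nats);
#' `kept_after_dpi` marks edges surviving the data-processing-inequality
#' triangle rule. "Regulator -> target" is a labelling of which endpoint was
#' on the supplied regulator list, not a causal direction.
#'
#' @slot edges data.frame with columns regulator, target, mi, p,
#'   kept_after_dpi.
#' @slot regulators character vector of regulator feature ids present.
#' @slot module module label the network was built in.
#' @slot miThreshold MI cutoff used; @slot pThreshold its tail probability.
#' @export
setClass("MiNetwork",
         representation(edges = "data.frame", regulators = "character",
                        module = "character", miThreshold = "numeric",
                        pThreshold = "numeric"))

setValidity("MiNetwork", function(object) {
    msg <- character()
    e <- object@edges
    need <- c("regulator", "target", "mi", "p", "kept_after_dpi")
    if (!all(need %in% names(e)))
        return(paste("edges must have columns:", paste(need, collapse = ", ")))
    if (nrow(e)) {
        if (any(e$mi < 0)) msg <- c(msg, "mi must be non-negative")
        if (any(e$regulator == e$target)) msg <- c(msg, "self-edges present")
        if (!all(e$regulator %in% object@regulators))
            msg <- c(msg, "edge regulator not in regulator set")
    }
    if (length(msg)) msg else TRUE
})
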