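#' @include AllClasses.R
NULL

#' Accessors for OmicsSet and ModuleSet
#'
#' `omicsKind()` returns the omics layer tag; `featureIds()` / `sampleIds()`
#' the identifiers; `values()` the log2 assay matrix; `designTable()` the
#' per-sample factor table. `moduleAssignment()`, `moduleEigengenes()`,
#' `moduleKME()`, `moduleKMEPvalues()`, `moduleSizes()` and `moduleLabels()`
#' access the components of a [ModuleSet]; `miEdges()` the edge table of a
#' [MiNetwork].
#'
#' @param x an `OmicsSet`, `ModuleSet` or `MiNetwork`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("omicsKind", function(x) standardGeneric("omicsKind"))
#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname accessors
#' @export
setGeneric("designTable", function(x) standardGeneric("designTable"))
#' @rdname accessors
#' @export
setGeneric("moduleAssignment", function(x) standardGeneric("moduleAssignment"))
#' @rdname accessors
#' @export
setGeneric("moduleEigengenes", function(x) standardGeneric("moduleEigengenes"))
#' @rdname accessors
#' @export
setGeneric("moduleKME", function(x) standardGeneric("moduleKME"))
#' @rdname accessors
#' @export
setGeneric("moduleKMEPvalues", function(x) standardGeneric("moduleKMEPvalues"))
#' @rdname accessors
#' @export
setGeneric("moduleSizes", function(x) standardGeneric("moduleSizes"))
#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))
#' @rdname accessors
#' @export
setGeneric("miEdges", function(x) standardGeneric("miEdges"))
#' @rdname accessors
#' @export
setGeneric("posteriorHigh", function(x) standardGeneric("posteriorHigh"))

setMethod("omicsKind", "OmicsSet", function(x) x@omicsKind)
setMethod("featureIds", "OmicsSet", function(x) rownames(x))
setMethod("sampleIds", "OmicsSet", function(x) colnames(x))
setMethod("abundances", "OmicsSet",
          function(x) SummarizedExperiment::assay(x, "log2"))
setMethod("designTable", "OmicsSet", function(x) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    if (!nrow(cd) || !"variety" %in% names(cd))
        stop("no design attached; see attachDesign()")
    cd$sample_id <- rownames(cd)
    cd[, c("sample_id", "variety", "location", "stage", "replicate")]
})

setMethod("moduleAssignment", "ModuleSet", function(x) x@assignment)
setMethod("moduleEigengenes", "ModuleSet", function(x) x@eigengenes)
setMethod("moduleKME", "ModuleSet", function(x) x@kme)
setMethod("moduleKMEPvalues", "ModuleSet", function(x) x@kmeP)
setMethod("moduleSizes", "ModuleSet", function(x) {
    a <- x@assignment[x@assignment != "grey"]
    sort(table(factor(a)), decreasing = TRUE)
})
setMethod("moduleLabels", "ModuleSet", function(x)
    setdiff(unique(x@assignment), "grey"))
setMethod("miEdges", "MiNetwork", function(x) x@edges)
setMethod("posteriorHigh", "MixtureFit", function(x) x@posteriorHigh)

setMethod("show", "OmicsSet", function(object) {
    cat(sprintf("OmicsSet (%s): %d features x %d samples\n",
                object@omicsKind, nrow(object), ncol(object)))
    cd <- SummarizedExperiment::colData(object)
    if ("variety" %in% names(cd))
        cat(sprintf("  design: %d varieties x %d locations x %d stages\n",
                    length(unique(cd$variety)), length(unique(cd$location)),
                    length(unique(cd$stage))))
    else cat("  design: none attached\n")
})

setMethod("show", "MixtureFit", function(object) {
    cat("Two-component Gaussian mixture (EM)\n")
    cat(sprintf("  weights: %.3f / %.3f\n", object@weights[1], object@weights[2]))
    cat(sprintf("  means:   %.4f / %.4f\n", object@means[1], object@means[2]))
    cat(sprintf("  sds:     %.4f / %.4f\n", object@sds[1], object@sds[2]))
    cat(sprintf("  loglik %.3f after %d iterations (%s)\n", object@loglik,
                object@nIter,
                if (object@converged) "converged" else "not converged"))
})

setMethod("show", "ModuleSet", function(object) {
    sz <- moduleSizes(object)
    cat(sprintf("ModuleSet: %d modules over %d features (%d grey)\n",
                length(sz), length(object@assignment),
                sum(object@assignment == "grey")))
    if (length(sz))
        cat("  sizes:", paste(sprintf("%s=%d", names(sz), as.integer(sz)),
                              collapse = ", "), "\n")
    cat(sprintf("  eigengenes: %s; kME: %s\n",
                if (nrow(object@eigengenes)) "computed" else "pending",
                if (nrow(object@kme)) "computed" else "pending"))
})

setMethod("show", "MiNetwork", function(object) {
    e <- object@edges
    cat(sprintf("MiNetwork [module %s]: %d edges (%d kept after DPI), %d regulators\n",
                object@module, nrow(e),
                sum(e$kept_after_dpi %in% TRUE), length(object@regulators)))
    cat(sprintf("  MI threshold %.4g (tail p %.3g)\n",
                object@miThreshold, object@pThreshold))
})
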