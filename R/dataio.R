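#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Read a feature-by-sample abundance matrix from TSV
#'
#' Expects a tab-separated file whose first column holds feature identifiers
#' and whose header row holds sample identifiers. Values are parsed as
#' reals. The missing-value policy is strict by default: any non-numeric or
#' empty cell aborts with its (row, column) location. With
#' `allowMissing = TRUE`, `NA` cells are kept and downstream correlation
#' stages use pairwise-complete samples (the ANOVA stage still requires
#' complete rows).
#'
#' @param path TSV file path.
#' @param omicsKind `"transcript"` or `"metabolite"`.
#' @param inputScale `"log2"` (values stored as-is) or `"linear"`
#'   (log2 applied at load; non-positive values are an error).
#' @param allowMissing permit NA cells.
#' @return an [OmicsSet].
#' @export
readFeatureMatrix <- function(path, omicsKind = c("transcript", "metabolite"),
                              inputScale = c("log2", "linear"),
                              allowMissing = FALSE) {
    omicsKind <- match.arg(omicsKind)
    inputScale <- match.arg(inputScale)
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character",
                             na.strings = NULL)
    if (ncol(raw) < 2L) stop("matrix file needs a feature-id column plus samples")
    fid <- raw[[1L]]
    if (anyDuplicated(fid))
        stop("duplicate feature id(s): ",
             paste(unique(fid[duplicated(fid)]), collapse = ", "))
    cells <- as.matrix(raw[, -1L, drop = FALSE])
    vals <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
    isMissTok <- matrix(cells %in% c("NA", "NaN", ""), nrow = nrow(cells))
    bad <- which(is.na(vals) & !isMissTok, arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("non-numeric cell '%s' at row %d (feature %s), column %d (%s)",
                     cells[bad[1, 1], bad[1, 2]], bad[1, 1], fid[bad[1, 1]],
                     bad[1, 2], colnames(cells)[bad[1, 2]]))
    na.cells <- which(is.na(vals), arr.ind = TRUE)
    if (!allowMissing && nrow(na.cells))
        stop(sprintf("missing value at row %d (feature %s), column %d (%s); set allowMissing=TRUE to permit",
                     na.cells[1, 1], fid[na.cells[1, 1]],
                     na.cells[1, 2], colnames(cells)[na.cells[1, 2]]))
    dimnames(vals) <- list(fid, colnames(cells))
    if (inputScale == "linear") {
        if (any(vals <= 0, na.rm = TRUE))
            stop("linear-scale input contains non-positive values; cannot log2")
        vals <- log2(vals)
    }
    OmicsSet(vals, omicsKind, allowMissing = allowMissing)
}

#' Read a sample design table from TSV
#'
#' Requires columns `sample_id`, `variety`, `location`, `stage`,
#' `replicate`. Stage levels are ordered by first appearance unless
#' `stageOrder` supplies an explicit ordering.
#'
#' @param path TSV file path.
#' @param stageOrder optional character vector of stage levels.
#' @return a data.frame with factor columns (stage ordered).
#' @export
readSampleDesign <- function(path, stageOrder = NULL) {
    d <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
    d <- .validateDesign(d)
    if (!is.null(stageOrder)) {
        if (!setequal(stageOrder, levels(d$stage)))
            stop("stageOrder does not match the stage levels present")
        d$stage <- factor(as.character(d$stage), levels = stageOrder)
    }
    d
}

#' Attach (and reorder to) a sample design
#'
#' The design table is the master sample order: the matrix columns are
#' reordered to it. Every matrix sample must appear exactly once in the
#' design.
#'
#' @param x an [OmicsSet].
#' @param design a design data.frame (see [readSampleDesign()]).
#' @return the `OmicsSet` with `colData` populated, columns in design order.
#' @export
attachDesign <- function(x, design) {
    design <- .validateDesign(design)
    miss <- setdiff(sampleIds(x), design$sample_id)
    if (length(miss))
        stop("samples absent from design: ", paste(miss, collapse = ", "))
    design <- design[design$sample_id %in% sampleIds(x), , drop = FALSE]
    x <- x[, design$sample_id]
    cd <- S4Vectors::DataFrame(design[, c("variety", "location", "stage",
                                          "replicate")],
                               row.names = design$sample_id)
    SummarizedExperiment::colData(x) <- cd
    validObject(x)
    x
}

#' Read pathway sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a line are stored once.
#'
#' @param path GMT file path.
#' @return named list of character vectors with a `"description"` attribute
#'   per element.
#' @export
readGMT <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    out <- list()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 3L)
            stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 member",
                         i, length(f)))
        members <- unique(f[-(1:2)])
        members <- members[nzchar(members)]
        if (!length(members))
            stop(sprintf("GMT line %d (%s) has no members", i, f[1]))
        attr(members, "description") <- f[2]
        out[[f[1]]] <- members
    }
    out
}

#' Write pathway sets in GMT format
#' @param sets named list of member vectors (see [readGMT()]).
#' @param path output file.
#' @export
writeGMT <- function(sets, path) {
    lines <- vapply(names(sets), function(nm) {
        d <- attr(sets[[nm]], "description")
        paste(c(nm, if (is.null(d)) nm else d, sets[[nm]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
}

#' Write an abundance matrix to TSV at full precision
#'
#' Values are written with 17 significant digits so that
#' `readFeatureMatrix()` reproduces them bit-identically. Rows are written
#' in feature order, columns in sample order.
#'
#' @param x an [OmicsSet] or numeric matrix.
#' @param path output file.
#' @export
writeFeatureMatrix <- function(x, path) {
    m <- .matInput(x)
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste(c("feature_id", colnames(m)), collapse = "\t"), con)
    body <- vapply(seq_len(nrow(m)), function(i)
        paste(c(rownames(m)[i], .fmtNum(m[i, ])), collapse = "\t"),
        character(1))
    writeLines(body, con)
    invisible(path)
}

#' Write a result table to TSV
#'
#' Generic writer for pipeline tables (DE tables, kME tables, evidence
#' tables, edge lists). Column order is the data.frame's column order; row
#' order is preserved. An empty table yields a header-only file.
#'
#' @param df a data.frame.
#' @param path output file.
#' @export
writeResultTable <- function(df, path) {
    df <- as.data.frame(df)
    num <- vapply(df, is.double, logical(1))
    for (j in which(num)) df[[j]] <- .fmtNum(df[[j]])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Write a mutual-information network edge list
#'
#' Columns: regulator, target, MI, p, kept_after_DPI; rows sorted by
#' decreasing MI then regulator/target id for determinism.
#'
#' @param net a [MiNetwork].
#' @param path output file.
#' @export
writeEdgeList <- function(net, path) {
    e <- miEdges(net)
    if (nrow(e))
        e <- e[order(-e$mi, e$regulator, e$target), , drop = FALSE]
    writeResultTable(e, path)
}

#' Read a design produced by [simulateDesign()] or [readSampleDesign()]
#' together with a feature matrix, returning an aligned OmicsSet.
#' @noRd
.readAligned <- function(matPath, designPath, omicsKind) {
    attachDesign(readFeatureMatrix(matPath, omicsKind),
                 readSampleDesign(designPath))
}
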