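#' Read a cell x gene count matrix with cluster labels
#'
#' Reads a Matrix Market (`.mtx`) sparse matrix or a dense CSV, together with
#' a gene sidecar TSV (column `gene_id`) and a cell sidecar TSV (columns
#' `cell_id` and `cluster`). The default orientation follows the 10x
#' convention of genes as matrix rows; `orientation = "cells-rows"` transposes
#' on load. Dimension mismatches between the matrix and either sidecar raise
#' an error naming the offending axis; duplicated identifiers raise a
#' validation error.
#'
#' @param matrixPath path to `.mtx` or `.csv` matrix.
#' @param genePath path to the gene TSV.
#' @param cellPath path to the cell TSV with the `cluster` column.
#' @param orientation `"genes-rows"` (default) or `"cells-rows"`.
#' @param datasetTag tag stored on the returned object.
#' @return a [CellMatrix-class].
#' @seealso [writeCellMatrix()] for the inverse.
#' @export
readCellMatrix <- function(matrixPath, genePath, cellPath,
                           orientation = c("genes-rows", "cells-rows"),
                           datasetTag = "dataset") {
    orientation <- match.arg(orientation)
    m <- if (grepl("\\.mtx$", matrixPath, ignore.case = TRUE)) {
        methods::as(Matrix::readMM(matrixPath), "CsparseMatrix")
    } else {
        as.matrix(utils::read.csv(matrixPath, header = FALSE))
    }
    if (orientation == "cells-rows") m <- Matrix::t(m)
    genes <- utils::read.delim(genePath, stringsAsFactors = FALSE)
    cells <- utils::read.delim(cellPath, stringsAsFactors = FALSE)
    if (!"gene_id" %in% names(genes)) stop("gene sidecar needs a 'gene_id' column")
    if (!all(c("cell_id", "cluster") %in% names(cells)))
        stop("cell sidecar needs 'cell_id' and 'cluster' columns")
    if (nrow(genes) != nrow(m))
        stop("gene axis mismatch: matrix has ", nrow(m),
             " genes but gene sidecar has ", nrow(genes), " records")
    if (nrow(cells) != ncol(m))
        stop("cell axis mismatch: matrix has ", ncol(m),
             " cells but cell sidecar has ", nrow(cells), " records")
    if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids in sidecar")
    if (anyDuplicated(cells$cell_id)) stop("duplicate cell ids in sidecar")
    dimnames(m) <- list(genes$gene_id, cells$cell_id)
    CellMatrix(m, setNames(cells$cluster, cells$cell_id),
               datasetTag = datasetTag)
}

#' Write a CellMatrix as MTX plus sidecar TSVs
#'
#' Writes `matrix.mtx` (genes as rows), `genes.tsv` and `cells.tsv` into
#' `dir`; the exact inverse of [readCellMatrix()].
#'
#' @param x a [CellMatrix-class].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
writeCellMatrix <- function(x, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cts <- umiCounts(x)
    Matrix::writeMM(methods::as(methods::as(cts, "dMatrix"), "CsparseMatrix"),
                    file.path(dir, "matrix.mtx"))
    write.table(data.frame(gene_id = rownames(x)),
                file.path(dir, "genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(cell_id = colnames(x),
                           cluster = unname(clusterLabels(x))),
                file.path(dir, "cells.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' Read a gene catalog TSV
#'
#' Expects columns `gene_id` and `category`; optional columns
#' `effector_subcategory` and `rbp_function` are carried along. Unknown
#' category strings become `"other"` with a warning (see [GeneCatalog()]).
#'
#' @param path TSV path.
#' @return a [GeneCatalog-class].
#' @export
readGeneCatalog <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "category") %in% names(tab)))
        stop("gene catalog needs 'gene_id' and 'category' columns")
    sub <- if ("effector_subcategory" %in% names(tab)) {
        ok <- !is.na(tab$effector_subcategory) & nzchar(tab$effector_subcategory)
        setNames(tab$effector_subcategory[ok], tab$gene_id[ok])
    } else character()
    rf <- if ("rbp_function" %in% names(tab)) {
        ok <- !is.na(tab$rbp_function) & nzchar(tab$rbp_function)
        setNames(tab$rbp_function[ok], tab$gene_id[ok])
    } else character()
    GeneCatalog(tab$gene_id, tab$category,
                effectorSubcategory = sub, rbpFunction = rf)
}

#' Write a gene catalog TSV
#' @param x a [GeneCatalog-class].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
writeGeneCatalog <- function(x, path) {
    write.table(data.frame(gene_id = names(geneCategory(x)),
                           category = unname(geneCategory(x))),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read an RBP -> target-gene table
#'
#' TSV with columns `rbp_gene_id`, `target_gene_id`, `score`. Scores must be
#' finite and (rbp, target) pairs unique; any motif-score cutoff is assumed to
#' have been applied upstream by the user.
#'
#' @param path TSV path.
#' @return data.frame with the three columns.
#' @export
readRbpTargets <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("rbp_gene_id", "target_gene_id", "score")
    if (!all(need %in% names(tab)))
        stop("RBP target table needs columns: ", paste(need, collapse = ", "))
    if (any(!is.finite(tab$score))) stop("scores must be finite")
    if (anyDuplicated(tab[c("rbp_gene_id", "target_gene_id")]))
        stop("(rbp, target) pairs must be unique")
    tab
}

# -- writeResults methods -----------------------------------------------------

#' @describeIn writeResults square TSV with cluster ids as header.
#' @export
setMethod("writeResults", "PairwiseDistance", function(object, path, ...) {
    write.table(distanceMatrix(object), path, sep = "\t", quote = FALSE,
                col.names = NA)
    invisible(path)
})

#' @describeIn writeResults JSON (with provenance) and a `.tsv` sidecar.
#' @export
setMethod("writeResults", "PatternAssignment", function(object, path, ...) {
    jsonlite::write_json(
        list(provenance = object@provenance,
             assignments = object@assignments),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
})

#' @describeIn writeResults plain TSV table.
#' @export
setMethod("writeResults", "data.frame", function(object, path, ...) {
    write.table(object, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
})

#' @describeIn writeResults dendrogram as newick with merge heights as branch
#'   lengths (via [ape::write.tree]).
#' @export
setMethod("writeResults", "hclust", function(object, path, ...) {
    ape::write.tree(ape::as.phylo(object), file = path)
    invisible(path)
})

#' Read back a pattern-assignment JSON
#' @param path JSON written by [writeResults()] on a [PatternAssignment-class].
#' @return the reconstructed [PatternAssignment-class].
#' @export
readPatterns <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    methods::new("PatternAssignment",
                 assignments = as.data.frame(obj$assignments),
                 provenance = obj$provenance)
}

#' Read a square distance TSV back into a PairwiseDistance
#' @param path TSV written by [writeResults()].
#' @param geneSetTag tag to stamp on the object.
#' @return a [PairwiseDistance-class].
#' @export
readDistances <- function(path, geneSetTag = "custom") {
    m <- as.matrix(utils::read.delim(path, row.names = 1L, check.names = FALSE))
    m[] <- pmin(pmax(m, 0), 1); diag(m) <- 0; m <- (m + t(m)) / 2
    methods::new("PairwiseDistance", d = m, geneSetTag = geneSetTag,
                 nGenesUsed = NA_integer_)
}

#' Read a newick tree
#' @param path newick file.
#' @return an [ape::phylo] tree.
#' @export
readNewick <- function(path) ape::read.tree(path)
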