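#' Read and write gene-by-cell count matrices
#'
#' MatrixMarket (`.mtx`) with gene/cell label sidecar files
#' (`<path>.genes.tsv`, `<path>.cells.tsv`, one label per line), or dense
#' CSV with gene labels as row names and cell labels as header. Round trips
#' are lossless; non-integer entries are an error naming the first offending
#' cell.
#'
#' @param path file path (`.mtx` or `.csv`).
#' @param format `"mtx"` or `"csv"`; default inferred from the extension.
#' @param genes_file,cells_file label files for MTX (defaults are the
#'   sidecar names above).
#' @return `read_counts`: an integer matrix with gene rownames and cell
#'   colnames.
#' @export
read_counts <- function(path, format = NULL, genes_file = NULL,
                        cells_file = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.mtx$", path)) "mtx" else "csv"
  if (format == "mtx") {
    if (is.null(genes_file)) genes_file <- paste0(path, ".genes.tsv")
    if (is.null(cells_file)) cells_file <- paste0(path, ".cells.tsv")
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genes_file)
    cells <- readLines(cells_file)
    if (length(genes) != nrow(m))
      stop(sprintf("gene label count (%d) does not match rows (%d)",
                   length(genes), nrow(m)))
    if (length(cells) != ncol(m))
      stop(sprintf("cell label count (%d) does not match columns (%d)",
                   length(cells), ncol(m)))
    dimnames(m) <- list(genes, cells)
  } else {
    df <- read.csv(path, row.names = 1, check.names = FALSE)
    m <- as.matrix(df)
  }
  bad <- which(m != round(m) | m < 0)
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(m))
    stop(sprintf("non-integer or negative count at gene '%s', cell '%s'",
                 rownames(m)[rc[1]], colnames(m)[rc[2]]))
  }
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts
#' @param matrix gene-by-cell integer matrix with dimnames.
#' @export
write_counts <- function(matrix, path, format = NULL, genes_file = NULL,
                         cells_file = NULL) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            !is.null(colnames(matrix)))
  if (any(matrix < 0) || any(matrix != round(matrix)))
    stop("counts must be nonnegative integers")
  if (is.null(format))
    format <- if (grepl("\\.mtx$", path)) "mtx" else "csv"
  if (format == "mtx") {
    if (is.null(genes_file)) genes_file <- paste0(path, ".genes.tsv")
    if (is.null(cells_file)) cells_file <- paste0(path, ".cells.tsv")
    Matrix::writeMM(Matrix::Matrix(matrix, sparse = TRUE), path)
    writeLines(rownames(matrix), genes_file)
    writeLines(colnames(matrix), cells_file)
  } else {
    write.csv(as.data.frame(matrix), path, quote = FALSE)
  }
  invisible(path)
}

#' Quality-control filtering of a count matrix
#'
#' Two-step QC: (i) cells are removed if fewer than
#' `min_gene_fraction_per_cell` of genes have nonzero counts; (ii) on the
#' surviving cells, genes are removed if expressed (nonzero) in fewer than
#' `min_cell_fraction_per_gene` of cells. Cells are filtered first so gene
#' prevalence is measured on retained cells.
#'
#' @param matrix gene-by-cell integer count matrix.
#' @param min_gene_fraction_per_cell cell-level threshold (default 0.30).
#' @param min_cell_fraction_per_gene gene-level threshold (default 0.01).
#' @return List with the filtered `matrix` and a `report` of removed
#'   cell/gene counts.
#' @export
qc_filter <- function(matrix, min_gene_fraction_per_cell = 0.30,
                      min_cell_fraction_per_gene = 0.01) {
  stopifnot(is.matrix(matrix), nrow(matrix) > 0, ncol(matrix) > 0)
  frac_genes_per_cell <- colMeans(matrix > 0)
  keep_cells <- frac_genes_per_cell >= min_gene_fraction_per_cell
  if (!any(keep_cells)) stop("QC removed all cells")
  m1 <- matrix[, keep_cells, drop = FALSE]
  frac_cells_per_gene <- rowMeans(m1 > 0)
  keep_genes <- frac_cells_per_gene >= min_cell_fraction_per_gene
  m2 <- m1[keep_genes, , drop = FALSE]
  list(matrix = m2,
       report = list(cells_removed = sum(!keep_cells),
                     genes_removed = sum(!keep_genes),
                     cells_kept = ncol(m2), genes_kept = nrow(m2)))
}
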