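#' Construct a CountMatrix
#'
#' A `CountMatrix` holds raw integer UMI/read counts (cells in rows, genes in
#' columns) together with gene names, cell ids, a per-cell batch index and
#' optional per-cell type labels. Batch 0 conventionally denotes the labeled
#' reference ("source") dataset and batch 1 the unlabeled query ("target"),
#' but any number of batches is supported.
#'
#' @param counts numeric matrix of non-negative integer counts, cells x genes.
#'   Entries within 1e-6 of an integer are rounded; anything else is rejected.
#' @param gene_names character vector of unique gene names, one per column.
#' @param cell_ids character vector of unique cell ids, one per row.
#' @param batch integer vector of per-cell batch indices (0-based) or a factor;
#'   defaults to all 0.
#' @param labels optional character vector of per-cell type labels; `NA` marks
#'   an unlabeled cell. Defaults to all `NA`.
#' @return An object of class `CountMatrix`: a list with elements `counts`,
#'   `gene_names`, `cell_ids`, `batch`, `labels`.
#' @export
count_matrix <- function(counts, gene_names = colnames(counts),
                         cell_ids = rownames(counts),
                         batch = integer(nrow(counts)),
                         labels = rep(NA_character_, nrow(counts))) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(ncol(counts)))
  if (is.null(cell_ids)) cell_ids <- paste0("c", seq_len(nrow(counts)))
  if (!all(is.finite(counts))) stop("counts contain non-finite entries")
  if (any(counts < 0)) stop("negative count entries are not allowed")
  rounded <- round(counts)
  if (any(abs(counts - rounded) > 1e-6)) {
    stop("counts contain non-integer entries (beyond 1e-6 rounding tolerance)")
  }
  counts <- rounded
  gene_names <- as.character(gene_names)
  cell_ids <- as.character(cell_ids)
  if (length(gene_names) != ncol(counts)) stop("gene_names length != n_genes")
  if (length(cell_ids) != nrow(counts)) stop("cell_ids length != n_cells")
  if (anyDuplicated(gene_names)) stop("duplicated gene names")
  if (anyDuplicated(cell_ids)) stop("duplicated cell ids")
  if (is.factor(batch)) batch <- as.integer(batch) - 1L
  batch <- as.integer(batch)
  if (length(batch) != nrow(counts)) stop("batch length != n_cells")
  if (any(is.na(batch)) || any(batch < 0L)) stop("batch must be non-negative integers")
  labels <- as.character(labels)
  if (length(labels) != nrow(counts)) stop("labels length != n_cells")
  dimnames(counts) <- list(cell_ids, gene_names)
  structure(
    list(counts = counts, gene_names = gene_names, cell_ids = cell_ids,
         batch = batch, labels = labels),
    class = "CountMatrix"
  )
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "cells x", ncol(x$counts), "genes\n")
  cat("  batches:", paste(sort(unique(x$batch)), collapse = ", "), "\n")
  n_lab <- sum(!is.na(x$labels))
  cat("  labeled cells:", n_lab, "of", nrow(x$counts), "\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Read a count matrix from disk
#'
#' Two layouts are supported. `"dense"`: a delimited text file with a header
#' row of gene names, the first column holding cell ids and one row per cell.
#' `"mtx"`: a MatrixMarket sparse matrix with sidecar one-name-per-line gene
#' and cell-barcode files; by convention the matrix stores genes as rows and
#' cells as columns (the CellRanger layout), which `cells_in_rows = TRUE`
#' flips.
#'
#' @param path path to the count file.
#' @param fmt `"dense"` (CSV/TSV, delimiter auto-detected) or `"mtx"`.
#' @param genes_file,cells_file sidecar name files, required for `fmt = "mtx"`.
#'   Default: `<path>` with extension replaced by `.genes.txt` / `.cells.txt`.
#' @param cells_in_rows for `"mtx"` only: set `TRUE` if the sparse matrix
#'   already stores cells as rows.
#' @param batch,labels optional per-cell batch/labels forwarded to
#'   [count_matrix()].
#' @return A [count_matrix()] object.
#' @export
read_counts <- function(path, fmt = c("dense", "mtx"),
                        genes_file = NULL, cells_file = NULL,
                        cells_in_rows = FALSE,
                        batch = NULL, labels = NULL) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  if (fmt == "dense") {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df)
    cm <- count_matrix(m, gene_names = colnames(m), cell_ids = rownames(m))
  } else {
    if (is.null(genes_file)) genes_file <- sub("\\.[^.]*$", ".genes.txt", path)
    if (is.null(cells_file)) cells_file <- sub("\\.[^.]*$", ".cells.txt", path)
    if (!file.exists(genes_file)) stop("gene name file not found: ", genes_file)
    if (!file.exists(cells_file)) stop("cell id file not found: ", cells_file)
    sm <- Matrix::readMM(path)
    genes <- readLines(genes_file)
    cells <- readLines(cells_file)
    m <- as.matrix(sm)
    if (!cells_in_rows) m <- t(m)
    if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
      stop("matrix dimensions do not match sidecar name files")
    }
    cm <- count_matrix(m, gene_names = genes, cell_ids = cells)
  }
  if (!is.null(batch)) cm$batch <- as.integer(batch)
  if (!is.null(labels)) cm$labels <- as.character(labels)
  count_matrix(cm$counts, cm$gene_names, cm$cell_ids, cm$batch, cm$labels)
}

#' Write a count matrix to disk
#'
#' Inverse of [read_counts()]; `"dense"` writes a CSV with cell ids in the
#' first column, `"mtx"` writes MatrixMarket plus `.genes.txt` / `.cells.txt`
#' sidecars (genes as rows).
#'
#' @param cm a [count_matrix()] object.
#' @param path output file path.
#' @param fmt `"dense"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path, fmt = c("dense", "mtx")) {
  fmt <- match.arg(fmt)
  stopifnot(inherits(cm, "CountMatrix"))
  if (fmt == "dense") {
    df <- data.frame(cell_id = cm$cell_ids, cm$counts, check.names = FALSE)
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(t(cm$counts), sparse = TRUE), path)
    writeLines(cm$gene_names, sub("\\.[^.]*$", ".genes.txt", path))
    writeLines(cm$cell_ids, sub("\\.[^.]*$", ".cells.txt", path))
  }
  invisible(path)
}

#' Merge source and target count matrices on shared genes
#'
#' Restricts both datasets to the intersection of their gene names (kept in
#' source order), stacks source cells above target cells, and assigns batch 0
#' to source cells and batch 1 to target cells. Source labels are carried
#' over; target labels are dropped from the merged object (they are withheld
#' from training and should be kept aside for evaluation only).
#'
#' @param source labeled reference [count_matrix()].
#' @param target query [count_matrix()].
#' @return A merged [count_matrix()].
#' @export
merge_on_shared_genes <- function(source, target) {
  stopifnot(inherits(source, "CountMatrix"), inherits(target, "CountMatrix"))
  shared <- source$gene_names[source$gene_names %in% target$gene_names]
  if (length(shared) == 0L) stop("no shared genes between source and target")
  s_idx <- match(shared, source$gene_names)
  t_idx <- match(shared, target$gene_names)
  counts <- rbind(source$counts[, s_idx, drop = FALSE],
                  target$counts[, t_idx, drop = FALSE])
  cell_ids <- c(source$cell_ids, target$cell_ids)
  if (anyDuplicated(cell_ids)) {
    cell_ids <- c(paste0("src_", source$cell_ids), paste0("tgt_", target$cell_ids))
  }
  count_matrix(
    counts,
    gene_names = shared,
    cell_ids = cell_ids,
    batch = c(rep(0L, nrow(source$counts)), rep(1L, nrow(target$counts))),
    labels = c(source$labels, rep(NA_character_, nrow(target$counts)))
  )
}

#' Drop all cells of the given types
#'
#' Utility for building benchmark scenarios in which cell types are deleted
#' from the reference (novel-type discovery) or from the query.
#'
#' @param cm a [count_matrix()] with labels.
#' @param types_to_drop character vector of type labels to remove.
#' @return A [count_matrix()] without cells of the named types; the gene set
#'   is unchanged.
#' @export
remove_types <- function(cm, types_to_drop) {
  stopifnot(inherits(cm, "CountMatrix"))
  if (length(types_to_drop) == 0L) return(cm)
  keep <- is.na(cm$labels) | !(cm$labels %in% as.character(types_to_drop))
  if (!any(keep)) stop("removing these types would drop all cells")
  count_matrix(cm$counts[keep, , drop = FALSE], cm$gene_names,
               cm$cell_ids[keep], cm$batch[keep], cm$labels[keep])
}
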