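#' Preprocess a merged count matrix into network-ready form
#'
#' Standard scRNA-seq preprocessing, in this order:
#' \enumerate{
#'   \item library-size normalization: each cell's counts are divided by its
#'     size factor, `size_factor_i = total_i / median(total)`, so every cell's
#'     total is scaled to the median library size;
#'   \item `ln(1 + x)` transform;
#'   \item selection of the top `n_hvg` highly variable genes by normalized
#'     dispersion: per-gene dispersion = variance / mean of the log data,
#'     z-scored within `n_bins` equal-count bins of the gene mean;
#'   \item per-gene z-scoring of the selected genes (zero mean, unit sample
#'     variance).
#' }
#' The z-scored matrix is the network input; the raw counts of the same genes
#' are kept as the likelihood target, together with the per-cell size factors
#' that scale the ZINB mean.
#'
#' @param cm a [count_matrix()]; every cell must have a positive total count.
#' @param n_hvg number of highly variable genes to keep (all genes if fewer
#'   are available). Default 1000.
#' @param n_bins number of equal-count mean bins used to normalize dispersion.
#' @param clip optional positive number: clip z-scores to `[-clip, clip]`
#'   after scaling (off by default).
#' @return An object of class `ProcessedData`: list with `x_input` (cells x
#'   n_hvg z-scored matrix), `x_raw` (matching raw counts), `size_factor`,
#'   `batch_onehot`, `hvg_names`, `cell_ids`, `label_index` (0-based integer
#'   or `NA`), `label_levels`, `n_source_types`, and `params` (the choices
#'   made).
#' @export
preprocess <- function(cm, n_hvg = 1000, n_bins = 20, clip = NULL) {
  stopifnot(inherits(cm, "CountMatrix"))
  counts <- cm$counts
  if (nrow(counts) == 0L || ncol(counts) == 0L) stop("empty count matrix")
  totals <- rowSums(counts)
  if (any(totals <= 0)) stop("cell(s) with zero total count: ",
                             paste(utils::head(cm$cell_ids[totals <= 0], 5), collapse = ", "))
  size_factor <- unname(totals / stats::median(totals))
  logx <- log1p(counts / size_factor)

  hvg_idx <- select_hvg(logx, n_hvg = n_hvg, n_bins = n_bins)
  x <- logx[, hvg_idx, drop = FALSE]

  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd < 1e-12] <- 1  # constant genes: center only
  x_input <- sweep(sweep(x, 2, mu, "-"), 2, sd, "/")
  if (!is.null(clip)) {
    stopifnot(clip > 0)
    x_input[x_input > clip] <- clip
    x_input[x_input < -clip] <- -clip
  }

  batches <- sort(unique(cm$batch))
  batch_onehot <- matrix(0, nrow(counts), length(batches),
                         dimnames = list(cm$cell_ids, paste0("batch", batches)))
  batch_onehot[cbind(seq_len(nrow(counts)), match(cm$batch, batches))] <- 1

  label_levels <- sort(unique(cm$labels[!is.na(cm$labels)]))
  label_index <- match(cm$labels, label_levels) - 1L  # 0-based, NA if unlabeled

  structure(
    list(
      x_input = x_input,
      x_raw = counts[, hvg_idx, drop = FALSE],
      size_factor = size_factor,
      batch_onehot = batch_onehot,
      batch = cm$batch,
      hvg_names = cm$gene_names[hvg_idx],
      cell_ids = cm$cell_ids,
      label_index = label_index,
      label_levels = label_levels,
      n_source_types = length(label_levels),
      params = list(n_hvg = n_hvg, n_bins = n_bins, clip = clip)
    ),
    class = "ProcessedData"
  )
}

#' @export
print.ProcessedData <- function(x, ...) {
  cat("ProcessedData:", nrow(x$x_input), "cells x", ncol(x$x_input), "genes (HVG)\n")
  cat("  batches:", ncol(x$batch_onehot), " labeled cells:", sum(!is.na(x$label_index)),
      " reference types:", x$n_source_types, "\n")
  invisible(x)
}

# Top-n HVG indices by bin-normalized dispersion of the log-transformed data.
# Dispersion = var/mean per gene; z-scored within n_bins equal-count bins of
# the gene mean. Ties in the ranking break by ascending gene index so the
# selection is deterministic. Returned indices are in original gene order.
select_hvg <- function(logx, n_hvg, n_bins = 20) {
  n_genes <- ncol(logx)
  if (n_hvg >= n_genes) return(seq_len(n_genes))
  means <- colMeans(logx)
  vars <- apply(logx, 2, stats::var)
  disp <- ifelse(means > 0, vars / means, 0)
  # equal-count bins on the mean; degenerate bins (sd 0) get z-score 0
  n_bins <- max(1L, min(n_bins, n_genes))
  ranks <- rank(means, ties.method = "first")
  bin <- ceiling(ranks / (n_genes / n_bins))
  norm_disp <- disp
  for (b in unique(bin)) {
    in_b <- bin == b
    m <- mean(disp[in_b])
    s <- stats::sd(disp[in_b])
    if (is.na(s) || s < 1e-12) {
      norm_disp[in_b] <- 0
    } else {
      norm_disp[in_b] <- (disp[in_b] - m) / s
    }
  }
  ord <- order(-norm_disp, seq_len(n_genes))
  sort(ord[seq_len(n_hvg)])
}

#' Persist preprocessed data as a directory of delimited files
#'
#' Writes `x_input.tsv`, `x_raw.tsv`, `cells.tsv` (cell id, batch, size
#' factor, label index), `hvg.txt` and a `manifest.json` recording the
#' preprocessing parameters and label levels.
#'
#' @param pd a [preprocess()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_processed <- function(pd, dir) {
  stopifnot(inherits(pd, "ProcessedData"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(data.frame(cell_id = pd$cell_ids, pd$x_input, check.names = FALSE),
                     file.path(dir, "x_input.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(cell_id = pd$cell_ids, pd$x_raw, check.names = FALSE),
                     file.path(dir, "x_raw.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  cells <- data.frame(cell_id = pd$cell_ids, batch = pd$batch,
                      size_factor = pd$size_factor, label_index = pd$label_index)
  utils::write.table(cells, file.path(dir, "cells.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines(pd$hvg_names, file.path(dir, "hvg.txt"))
  manifest <- c(pd$params, list(label_levels = pd$label_levels,
                                n_source_types = pd$n_source_types))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}

#' Load preprocessed data written by [write_processed()]
#'
#' @param dir directory produced by [write_processed()].
#' @return A `ProcessedData` object.
#' @export
read_processed <- function(dir) {
  xi <- utils::read.table(file.path(dir, "x_input.tsv"), header = TRUE, sep = "\t",
                          row.names = 1L, check.names = FALSE)
  xr <- utils::read.table(file.path(dir, "x_raw.tsv"), header = TRUE, sep = "\t",
                          row.names = 1L, check.names = FALSE)
  cells <- utils::read.table(file.path(dir, "cells.tsv"), header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  batches <- sort(unique(cells$batch))
  onehot <- matrix(0, nrow(cells), length(batches),
                   dimnames = list(cells$cell_id, paste0("batch", batches)))
  onehot[cbind(seq_len(nrow(cells)), match(cells$batch, batches))] <- 1
  label_levels <- as.character(manifest$label_levels)
  structure(
    list(
      x_input = as.matrix(xi), x_raw = as.matrix(xr),
      size_factor = cells$size_factor, batch_onehot = onehot,
      batch = cells$batch,
      hvg_names = readLines(file.path(dir, "hvg.txt")),
      cell_ids = cells$cell_id,
      label_index = as.integer(cells$label_index),
      label_levels = label_levels,
      n_source_types = length(label_levels),
      params = manifest[setdiff(names(manifest), c("label_levels", "n_source_types"))]
    ),
    class = "ProcessedData"
  )
}
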