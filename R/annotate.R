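#' Annotate clusters from reference cell-type composition
#'
#' For each cluster and each reference cell type, the capture fraction
#' `f(i, c)` is the share of all type-`c` reference cells that fall in
#' cluster `i`. Types with `f > 0.5` are candidate annotations; the cluster
#' is annotated with the candidate of the largest fraction (ties break to
#' the lexicographically smallest type name) and that fraction is the
#' cluster's clarity score. A cluster with no candidate — in particular any
#' cluster with no reference cells at all — is `"unassigned"`, which is how
#' novel cell types absent from the reference surface. Every query cell
#' inherits its cluster's annotation.
#'
#' @param cluster_labels integer cluster label per cell (reference and query
#'   cells together).
#' @param source_labels character reference type per cell, `NA` for query
#'   cells.
#' @return An object of class `AnnotationResult`: list with `clusters` (one
#'   row per cluster: `cluster`, `annotated_type`, `clarity`, `size`,
#'   `n_source`) and `cells` (per cell: `cluster`, `predicted_type`).
#' @export
annotate_clusters <- function(cluster_labels, source_labels) {
  stopifnot(length(cluster_labels) == length(source_labels))
  if (any(is.na(cluster_labels))) stop("cluster labels must cover all cells")
  if (all(is.na(source_labels))) stop("no labeled reference cells")
  clusters <- sort(unique(cluster_labels))
  types <- sort(unique(source_labels[!is.na(source_labels)]))
  type_totals <- table(factor(source_labels, levels = types))

  ann <- character(length(clusters))
  clarity <- rep(NA_real_, length(clusters))
  size <- integer(length(clusters))
  n_src <- integer(length(clusters))
  for (ci in seq_along(clusters)) {
    in_cl <- cluster_labels == clusters[ci]
    size[ci] <- sum(in_cl)
    src_in <- source_labels[in_cl]
    n_src[ci] <- sum(!is.na(src_in))
    f <- as.numeric(table(factor(src_in, levels = types))) / as.numeric(type_totals)
    f[!is.finite(f)] <- 0
    cand <- which(f > 0.5)
    if (length(cand) == 0L) {
      ann[ci] <- "unassigned"
    } else {
      best <- cand[order(-f[cand], types[cand])][1]
      ann[ci] <- types[best]
      clarity[ci] <- f[best]
    }
  }
  cell_pred <- ann[match(cluster_labels, clusters)]
  structure(
    list(
      clusters = data.frame(cluster = clusters, annotated_type = ann,
                            clarity = clarity, size = size, n_source = n_src,
                            stringsAsFactors = FALSE),
      cells = data.frame(cluster = cluster_labels, predicted_type = cell_pred,
                         stringsAsFactors = FALSE)
    ),
    class = "AnnotationResult"
  )
}

#' @export
print.AnnotationResult <- function(x, ...) {
  cat("Cluster annotation:\n")
  print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Annotate a pipeline fit
#'
#' Convenience wrapper: runs [annotate_clusters()] on the hard cluster labels
#' of a [run_pipeline()] fit, using the reference labels stored with it.
#'
#' @param fit an `scrc_fit`.
#' @return An `AnnotationResult`.
#' @export
annotate_fit <- function(fit) {
  stopifnot(inherits(fit, "scrc_fit"))
  src <- ifelse(is.na(fit$label_index), NA_character_,
                fit$label_levels[fit$label_index + 1L])
  annotate_clusters(fit$cluster, src)
}
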