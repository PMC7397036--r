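#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same cells
#' (Hubert-Arabie form), computed from the contingency table:
#' `ARI = (sum_ij C(n_ij,2) - E) / (M - E)` with
#' `E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2)` and
#' `M = (sum_i C(a_i,2) + sum_j C(b_j,2)) / 2`.
#'
#' @param a,b per-cell labels (any atomic type), equal length >= 2.
#' @return the ARI; 1 for identical partitions, about 0 for independent ones.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  n <- length(a)
  if (n < 2L) stop("need at least 2 cells")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  E <- sum_a * sum_b / choose2(n)
  M <- (sum_a + sum_b) / 2
  if (M == E) return(ifelse(sum_ij == E, 1, 0))
  (sum_ij - E) / (M - E)
}

#' Annotation accuracy on overlapping cell types
#'
#' Fraction of query cells whose predicted type matches the truth, restricted
#' to query cells whose true type also exists in the reference label set
#' (the only cells for which a correct transfer is possible). An
#' `"unassigned"` prediction on such a cell counts as incorrect.
#'
#' @param pred predicted type per query cell (may include `"unassigned"`).
#' @param truth true type per query cell.
#' @param source_types character vector of types present in the reference.
#' @return accuracy in `[0, 1]`, or `NA` if no query cell has an overlapping
#'   type.
#' @export
annotation_accuracy <- function(pred, truth, source_types) {
  if (length(pred) != length(truth)) stop("length mismatch")
  overlap <- !is.na(truth) & truth %in% source_types
  if (!any(overlap)) return(NA_real_)
  mean(pred[overlap] == truth[overlap])
}

#' Evaluate a fit against ground-truth query labels
#'
#' Computes the two benchmark indices on the query (target) cells: the
#' adjusted Rand index of the hard cluster labels against the true types, and
#' the annotation accuracy of the transferred labels on types shared with
#' the reference.
#'
#' @param fit an `scrc_fit` from [run_pipeline()].
#' @param truth_target character vector of true types for the target cells,
#'   in target-cell order (batch 1 cells of the fit).
#' @param annotation optional precomputed [annotate_fit()] result.
#' @return list of class `EvalReport` with `ari`, `annotation_accuracy`,
#'   `n_overlap_cells`, `n_target_cells`.
#' @export
evaluate_fit <- function(fit, truth_target, annotation = NULL) {
  stopifnot(inherits(fit, "scrc_fit"))
  is_target <- fit$batch == max(fit$batch)
  if (length(truth_target) != sum(is_target)) {
    stop("truth_target length does not match number of target cells")
  }
  if (is.null(annotation)) annotation <- annotate_fit(fit)
  pred <- annotation$cells$predicted_type[is_target]
  ari <- adjusted_rand_index(fit$cluster[is_target], truth_target)
  overlap <- !is.na(truth_target) & truth_target %in% fit$label_levels
  acc <- annotation_accuracy(pred, truth_target, fit$label_levels)
  structure(list(ari = ari, annotation_accuracy = acc,
                 n_overlap_cells = sum(overlap),
                 n_target_cells = sum(is_target)),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("ARI (target cells):      %.4f\n", x$ari))
  cat(sprintf("Annotation accuracy:     %s  (on %d overlapping of %d target cells)\n",
              ifelse(is.na(x$annotation_accuracy), "NA",
                     sprintf("%.4f", x$annotation_accuracy)),
              x$n_overlap_cells, x$n_target_cells))
  invisible(x)
}
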