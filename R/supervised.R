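#' Cross-entropy classification loss on labeled reference cells
#'
#' Mean over labeled cells of the negative log-probability assigned to the
#' true reference type. Probabilities are clamped at 1e-8 before taking logs.
#' Only labeled (reference) cells may be passed in; the loss never touches
#' query cells.
#'
#' @param class_probs row-stochastic matrix, labeled cells x k_source.
#' @param label_index 0-based integer vector of true type indices.
#' @return scalar loss.
#' @export
classification_loss <- function(class_probs, label_index) {
  if (any(is.na(label_index))) stop("classification_loss received unlabeled cells")
  label_index <- as.integer(label_index)
  if (any(label_index < 0L) || any(label_index >= ncol(class_probs))) {
    stop("label index out of range")
  }
  if (length(label_index) != nrow(class_probs)) stop("length mismatch")
  p <- class_probs[cbind(seq_len(nrow(class_probs)), label_index + 1L)]
  -mean(log(pmax(p, 1e-8)))
}

# Gradient of the mean cross-entropy w.r.t. classifier logits for a minibatch
# in which only some rows are labeled: (softmax - onehot) / n_labeled on
# labeled rows, 0 elsewhere.
classification_grad_logits <- function(class_probs, label_index) {
  g <- matrix(0, nrow(class_probs), ncol(class_probs))
  lab <- which(!is.na(label_index))
  if (length(lab) == 0L) return(g)
  g[lab, ] <- class_probs[lab, , drop = FALSE]
  g[cbind(lab, as.integer(label_index[lab]) + 1L)] <-
    g[cbind(lab, as.integer(label_index[lab]) + 1L)] - 1
  g / length(lab)
}
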