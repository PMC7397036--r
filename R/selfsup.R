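#' Pairwise cosine similarity of latent codes
#'
#' `S_ij = z_i . z_j / (||z_i|| ||z_j||)` for all cell pairs of a minibatch;
#' the diagonal is exactly 1.
#'
#' @param z latent matrix (cells x d).
#' @return symmetric similarity matrix in `[-1, 1]`.
#' @export
cosine_similarity <- function(z) {
  nrm <- sqrt(rowSums(z * z))
  if (any(nrm < 1e-12)) stop("zero-norm latent vector")
  zn <- z / nrm
  S <- tcrossprod(zn)
  diag(S) <- 1
  S
}

#' Dynamic similarity thresholds
#'
#' The linear schedules `u(t) = 0.95 - 0.0045 t` and
#' `l(t) = 0.455 + 0.00045 t` for fusion epoch `t = 1, 2, ...`. The upper
#' threshold falls and the lower threshold rises until they meet at 0.5 at
#' `t = 100`; fusion stops once `u(t) < l(t)`.
#'
#' @param t fusion epoch (>= 1).
#' @return list with `u`, `l`, and `active` (`u >= l`).
#' @export
threshold_schedule <- function(t) {
  stopifnot(t >= 1)
  u <- 0.95 - 0.0045 * t
  l <- 0.455 + 0.00045 * t
  list(u = u, l = l, active = u >= l)
}

#' Build pairwise pseudo-labels from similarities and known labels
#'
#' For each off-diagonal pair: if both cells carry a reference label, the
#' pair is positive iff the labels agree (label knowledge overrides the
#' thresholds). Otherwise the pair is positive if `S_ij > u`, negative if
#' `S_ij < l`, and not selected when it falls between the thresholds.
#' Self-pairs are never selected.
#'
#' @param S similarity matrix from [cosine_similarity()].
#' @param labels per-cell labels within the minibatch (`NA` = unlabeled);
#'   any atomic type.
#' @param u,l current thresholds (`u >= l`).
#' @return list with 0/1 matrices `R_hat` and `selected` (`R_hat` is
#'   meaningful only where `selected == 1`).
#' @export
build_pseudo_labels <- function(S, labels, u, l) {
  n <- nrow(S)
  stopifnot(length(labels) == n, u >= l)
  R <- (S > u) * 1
  selected <- (S > u | S < l) * 1
  lab <- which(!is.na(labels))
  if (length(lab) > 1L) {
    same <- outer(labels[lab], labels[lab], "==") * 1
    R[lab, lab] <- same
    selected[lab, lab] <- 1
  }
  diag(selected) <- 0
  diag(R) <- 1
  list(R_hat = R, selected = selected)
}

#' Self-supervised pairwise binary cross-entropy loss
#'
#' Mean over selected pairs of `-R ln S - (1 - R) ln(1 - S)`, treating the
#' cosine similarity (clamped to `[1e-6, 1 - 1e-6]`) as the probability that
#' the pair is similar.
#'
#' @param S similarity matrix.
#' @param R_hat,selected pseudo-label and selection masks from
#'   [build_pseudo_labels()].
#' @return scalar loss (0 with a warning if no pair is selected).
#' @export
self_supervised_loss <- function(S, R_hat, selected) {
  n_sel <- sum(selected)
  if (n_sel == 0) {
    warning("no selected pairs; self-supervised loss is 0")
    return(0)
  }
  eps <- 1e-6
  Sc <- pmin(pmax(S, eps), 1 - eps)
  bce <- -R_hat * log(Sc) - (1 - R_hat) * log(1 - Sc)
  sum(bce * selected) / n_sel
}

# Gradient of the pairwise BCE w.r.t. the raw latent z of the minibatch.
# S = Zn Zn^T with Zn the row-normalized z. d loss / d S_ij is zero where the
# similarity is clamped or the pair unselected; G is symmetric, so
# d loss / d Zn = 2 G Zn, then the normalization is backpropagated.
# The gradient path clamps S at eps_grad (not the loss's 1e-6): d BCE/dS
# grows like 1/(1-S) and a single mislabeled near-duplicate pair would
# otherwise dominate the whole minibatch update.
selfsup_grad_z <- function(z, R_hat, selected, eps_grad = 1e-2) {
  n_sel <- sum(selected)
  if (n_sel == 0) return(matrix(0, nrow(z), ncol(z)))
  nrm <- sqrt(rowSums(z * z))
  zn <- z / nrm
  S <- tcrossprod(zn)
  eps <- eps_grad
  inside <- (S > eps & S < 1 - eps) * 1
  Sc <- pmin(pmax(S, eps), 1 - eps)
  G <- (-R_hat / Sc + (1 - R_hat) / (1 - Sc)) * selected * inside / n_sel
  dZn <- 2 * (G %*% zn)
  # through row normalization: dz = (g - (g.zn) zn) / ||z||
  proj <- rowSums(dZn * zn)
  (dZn - proj * zn) / nrm
}
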