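#' Closed-form soft cluster memberships on the unit sphere
#'
#' Entropy-regularized soft k-means memberships. For unit-norm latent rows
#' `z_i` and centers `v_j`,
#' `w_ij = exp(-2 (1 - z_i.v_j) / sigma) / sum_l exp(-2 (1 - z_i.v_l) / sigma)`
#' (computed with max-subtraction for stability). `2 (1 - z.v)` equals the
#' squared Euclidean distance on the unit sphere, and this closed form is the
#' exact minimizer of the entropy-regularized clustering objective for fixed
#' `z` and `v`.
#'
#' @param z latent matrix; rows are renormalized to unit length with a
#'   warning if needed.
#' @param v center matrix (k x d), rows renormalized likewise.
#' @param sigma positive entropy weight; default 1. Smaller values approach
#'   hard nearest-center assignment.
#' @return row-stochastic membership matrix (cells x k).
#' @export
soft_assignments <- function(z, v, sigma = 1) {
  stopifnot(sigma > 0)
  z <- ensure_unit_rows(z, "z")
  v <- ensure_unit_rows(v, "v")
  logits <- -2 * (1 - tcrossprod(z, v)) / sigma
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

ensure_unit_rows <- function(m, what) {
  nrm <- sqrt(rowSums(m * m))
  if (any(nrm < 1e-12)) stop("zero-norm row in ", what)
  if (any(abs(nrm - 1) > 1e-6)) {
    warning(what, " rows are not unit-norm; renormalizing")
    m <- m / nrm
  }
  m
}

#' Spherical soft k-means clustering loss
#'
#' Mean over cells of `sum_j 2 w_ij (1 - z_i.v_j)` with the memberships `w`
#' held fixed (no gradient flows through them during training).
#'
#' @param z unit-norm latent matrix.
#' @param v unit-norm center matrix.
#' @param w_fixed memberships from [soft_assignments()], treated as constant.
#' @return scalar loss.
#' @export
clustering_loss <- function(z, v, w_fixed) {
  if (nrow(w_fixed) != nrow(z) || ncol(w_fixed) != nrow(v)) stop("shape mismatch")
  d <- 2 * (1 - tcrossprod(z, v))
  mean(rowSums(w_fixed * d))
}

# Gradients of clustering_loss w.r.t. unit-norm z rows and centers v.
cluster_grad <- function(z, v, w_fixed) {
  n <- nrow(z)
  dZn <- -(2 / n) * (w_fixed %*% v)
  dV <- -(2 / n) * crossprod(w_fixed, z)
  list(dZn = dZn, dV = dV)
}

# Backpropagate a gradient on normalized rows to the raw (pre-normalization)
# matrix.
normalize_backprop <- function(z_raw, dZn) {
  nrm <- sqrt(rowSums(z_raw * z_raw))
  zn <- z_raw / nrm
  proj <- rowSums(dZn * zn)
  (dZn - proj * zn) / nrm
}

#' Initialize cluster centers by k-means
#'
#' Runs Lloyd's k-means with k-means++ seeding and multiple restarts on the
#' unit-normalized latent codes; the best solution's centroids are returned,
#' renormalized to the unit sphere.
#'
#' @param z latent matrix (rows renormalized internally).
#' @param k number of clusters (`k <= nrow(z)`).
#' @param seed integer seed; fixed seed gives bit-identical centers.
#' @param nstart number of restarts.
#' @return k x d matrix of unit-norm centers.
#' @export
init_centers <- function(z, k, seed = 0L, nstart = 20L) {
  if (nrow(z) < k) stop("fewer cells than clusters")
  nrm <- sqrt(rowSums(z * z))
  zn <- z / pmax(nrm, 1e-12)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(nstart)) {
    init <- kmeanspp_init(zn, k)
    km <- suppressWarnings(stats::kmeans(zn, centers = zn[init, , drop = FALSE],
                                         iter.max = 100L, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  v <- best$centers
  vn <- sqrt(rowSums(v * v))
  v / pmax(vn, 1e-12)
}

# k-means++ seeding: indices of k rows, first uniform, the rest sampled with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 <= 0)) {
      idx[j + 1L] <- sample.int(n, 1L)
    } else {
      idx[j + 1L] <- sample.int(n, 1L, prob = d2 / sum(d2))
    }
    dn <- rowSums((x - matrix(x[idx[j + 1L], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dn)
  }
  idx
}

#' Hard cluster labels from soft memberships
#'
#' Argmax over clusters, ties broken by the smallest cluster index.
#'
#' @param w membership matrix from [soft_assignments()].
#' @return integer vector of 1-based cluster labels.
#' @export
hard_labels <- function(w) {
  max.col(w, ties.method = "first")
}
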