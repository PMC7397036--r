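#' Network and training configuration
#'
#' Hyperparameters of the batch-conditional ZINB autoencoder and its training
#' schedule. Defaults follow the method's standard setting: encoder hidden
#' layers of 256 and 64 units, a 32-dimensional latent bottleneck, minibatch
#' size 256, Adam with learning rate 1e-4, 500 pretraining epochs and 100
#' similarity-fusion epochs.
#'
#' @param encoder_sizes integer vector of encoder hidden-layer widths; the
#'   decoder mirrors them in reverse.
#' @param d_latent latent dimension.
#' @param minibatch minibatch size.
#' @param learning_rate Adam learning rate.
#' @param epochs_pretrain,epochs_fuse,epochs_cluster_max epochs for the
#'   pretraining, similarity-fusion and clustering-refinement stages (the
#'   fusion stage is additionally capped by the threshold schedule, and the
#'   clustering stage stops early on label convergence).
#' @param sigma entropy weight of the soft k-means (see
#'   [soft_assignments()]).
#' @param use_size_factor multiply the ZINB mean head by the per-cell size
#'   factor (recommended; set `FALSE` to model unscaled counts).
#' @param input_noise_sd standard deviation of the Gaussian noise added to
#'   the (z-scored) encoder input during the pretraining and fusion stages;
#'   the denoising regularizer. 0 disables corruption.
#' @param grad_clip global gradient-norm clip.
#' @param seed integer seed controlling weight initialization, minibatch
#'   shuffling and center initialization.
#' @return A `network_config` list.
#' @export
network_config <- function(encoder_sizes = c(256L, 64L), d_latent = 32L,
                           minibatch = 256L, learning_rate = 1e-4,
                           epochs_pretrain = 500L, epochs_fuse = 100L,
                           epochs_cluster_max = 200L, sigma = 1,
                           use_size_factor = TRUE, input_noise_sd = 0,
                           grad_clip = 5, seed = 0L) {
  stopifnot(all(encoder_sizes > 0), d_latent > 0, minibatch > 0,
            learning_rate > 0, sigma > 0)
  structure(list(encoder_sizes = as.integer(encoder_sizes),
                 d_latent = as.integer(d_latent),
                 minibatch = as.integer(minibatch),
                 learning_rate = learning_rate,
                 epochs_pretrain = as.integer(epochs_pretrain),
                 epochs_fuse = as.integer(epochs_fuse),
                 epochs_cluster_max = as.integer(epochs_cluster_max),
                 sigma = sigma, use_size_factor = use_size_factor,
                 input_noise_sd = input_noise_sd,
                 grad_clip = grad_clip, seed = as.integer(seed)),
            class = "network_config")
}

# Glorot-uniform weight matrix, U(-a, a) with a = sqrt(6/(fan_in + fan_out)).
glorot <- function(fan_in, fan_out) {
  a <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -a, a), fan_in, fan_out)
}

#' Initialize the autoencoder network
#'
#' Builds the encoder (input `[x || batch]`), the linear latent layer, the
#' softmax classification head on the latent code, the mirrored decoder
#' (input `[z || batch]`) and the three ZINB parameter heads (dropout
#' probability via logistic, mean via exponential scaled by the cell size
#' factor, inverse-dispersion via softplus). Weights are Glorot-uniform draws
#' from the configured seed; biases start at zero.
#'
#' @param cfg a [network_config()].
#' @param n_genes number of (HVG) gene features.
#' @param n_batches number of batches (one-hot width).
#' @param k_source number of reference cell types (classifier width).
#' @return A `zinb_network` object holding all weight matrices.
#' @export
init_network <- function(cfg, n_genes, n_batches, k_source) {
  set.seed(cfg$seed)
  enc_dims <- c(n_genes + n_batches, cfg$encoder_sizes, cfg$d_latent)
  dec_dims <- c(cfg$d_latent + n_batches, rev(cfg$encoder_sizes))
  W <- list(); b <- list()
  for (i in seq_len(length(enc_dims) - 1L)) {
    W[[paste0("enc", i)]] <- glorot(enc_dims[i], enc_dims[i + 1])
    b[[paste0("enc", i)]] <- numeric(enc_dims[i + 1])
  }
  W[["cls"]] <- glorot(cfg$d_latent, k_source)
  b[["cls"]] <- numeric(k_source)
  for (i in seq_len(length(dec_dims) - 1L)) {
    W[[paste0("dec", i)]] <- glorot(dec_dims[i], dec_dims[i + 1])
    b[[paste0("dec", i)]] <- numeric(dec_dims[i + 1])
  }
  d_last <- dec_dims[length(dec_dims)]
  for (h in c("pi", "mu", "theta")) {
    W[[h]] <- glorot(d_last, n_genes)
    b[[h]] <- numeric(n_genes)
  }
  structure(list(W = W, b = b, cfg = cfg, n_genes = n_genes,
                 n_batches = n_batches, k_source = k_source,
                 n_enc = length(enc_dims) - 1L, n_dec = length(dec_dims) - 1L),
            class = "zinb_network")
}

relu <- function(x) { x[x < 0] <- 0; x }
# numerically stable softplus without ifelse copies
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
sigmoid <- function(x) 1 / (1 + exp(-x))

row_softmax <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

MU_LO <- 1e-5; MU_HI <- 1e6

#' Forward pass of the autoencoder
#'
#' Runs a set of cells through encoder, classifier head and decoder, returning
#' the latent code, the ZINB parameter heads and the classification
#' probabilities. With `cache = TRUE` the intermediate activations needed by
#' backpropagation are attached.
#'
#' @param net a [init_network()] object.
#' @param x z-scored input matrix (cells x genes).
#' @param b batch one-hot matrix (cells x n_batches).
#' @param sf per-cell size factors (ignored when the config disables size
#'   factors).
#' @param cache keep intermediate activations for the backward pass.
#' @return list with `z`, `params` (list `pi`, `mu`, `theta`), `class_probs`,
#'   and (if cached) internals.
#' @export
net_forward <- function(net, x, b, sf, cache = FALSE) {
  stopifnot(inherits(net, "zinb_network"))
  if (ncol(x) != net$n_genes || ncol(b) != net$n_batches) stop("input width mismatch")
  H <- list(cbind(x, b))
  for (i in seq_len(net$n_enc)) {
    A <- addbias_cpp(H[[i]] %*% net$W[[paste0("enc", i)]], net$b[[paste0("enc", i)]])
    H[[i + 1]] <- if (i < net$n_enc) relu(A) else A  # latent layer is linear
  }
  z <- H[[net$n_enc + 1]]
  cls_logits <- addbias_cpp(z %*% net$W$cls, net$b$cls)
  class_probs <- row_softmax(cls_logits)

  D <- list(cbind(z, b))
  for (i in seq_len(net$n_dec)) {
    D[[i + 1]] <- relu(addbias_cpp(D[[i]] %*% net$W[[paste0("dec", i)]], net$b[[paste0("dec", i)]]))
  }
  hid <- D[[net$n_dec + 1]]
  sf_cell <- if (is.matrix(sf)) sf[, 1] else sf
  hd <- heads_cpp(addbias_cpp(hid %*% net$W$pi, net$b$pi),
                  addbias_cpp(hid %*% net$W$mu, net$b$mu),
                  addbias_cpp(hid %*% net$W$theta, net$b$theta),
                  sf_cell, isTRUE(net$cfg$use_size_factor))
  out <- list(z = z, params = list(pi = hd$pi, mu = hd$mu, theta = hd$theta),
              class_probs = class_probs)
  if (cache) {
    out$cache <- list(H = H, D = D, a_th = hd$a_th,
                      mu_free = hd$mu_free, th_free = hd$th_free,
                      cls_probs = class_probs)
  }
  out
}

# Backward pass. Inputs:
#   fwd        — net_forward(..., cache = TRUE) result
#   x_raw      — raw counts of the minibatch (for the ZINB loss), or NULL to
#                skip the reconstruction term
#   d_cls      — gradient of the loss w.r.t. the classifier logits, or NULL
#   d_z        — extra gradient w.r.t. z from pairwise/cluster losses, or NULL
#   head_grads — optional precomputed ZINB head gradients (list pi/mu/theta,
#                e.g. from the fused C++ kernel); overrides x_raw
# Returns a list of gradients parallel to net$W / net$b.
net_backward <- function(net, fwd, x_raw = NULL, d_cls = NULL, d_z = NULL,
                         head_grads = NULL) {
  ca <- fwd$cache
  gW <- lapply(net$W, function(w) NULL)
  gb <- lapply(net$b, function(bb) NULL)
  nb <- nrow(ca$H[[1]])
  hid <- ca$D[[net$n_dec + 1]]

  dZ <- matrix(0, nb, net$cfg$d_latent)
  if (!is.null(d_z)) dZ <- dZ + d_z

  if (!is.null(x_raw) || !is.null(head_grads)) {
    g <- if (is.null(head_grads)) {
      zinb_grad_preact(x_raw, fwd$params$pi, fwd$params$mu, fwd$params$theta,
                       ca$a_th, ca$mu_free, ca$th_free)
    } else head_grads
    Gpi <- matrix(g$pi, nb); Gmu <- matrix(g$mu, nb); Gth <- matrix(g$theta, nb)
    gW$pi <- crossprod(hid, Gpi);    gb$pi <- colSums(Gpi)
    gW$mu <- crossprod(hid, Gmu);    gb$mu <- colSums(Gmu)
    gW$theta <- crossprod(hid, Gth); gb$theta <- colSums(Gth)
    dH <- tcrossprod(Gpi, net$W$pi) + tcrossprod(Gmu, net$W$mu) +
      tcrossprod(Gth, net$W$theta)
    # back through decoder hidden layers (all ReLU)
    for (i in rev(seq_len(net$n_dec))) {
      dA <- dH * (ca$D[[i + 1]] > 0)
      gW[[paste0("dec", i)]] <- crossprod(ca$D[[i]], dA)
      gb[[paste0("dec", i)]] <- colSums(dA)
      dH <- tcrossprod(dA, net$W[[paste0("dec", i)]])
    }
    dZ <- dZ + dH[, seq_len(net$cfg$d_latent), drop = FALSE]
  }

  if (!is.null(d_cls)) {
    z <- ca$H[[net$n_enc + 1]]
    gW$cls <- crossprod(z, d_cls)
    gb$cls <- colSums(d_cls)
    dZ <- dZ + tcrossprod(d_cls, net$W$cls)
  }

  dH <- dZ  # latent layer is linear
  for (i in rev(seq_len(net$n_enc))) {
    dA <- if (i < net$n_enc) dH * (ca$H[[i + 1]] > 0) else dH
    gW[[paste0("enc", i)]] <- crossprod(ca$H[[i]], dA)
    gb[[paste0("enc", i)]] <- colSums(dA)
    dH <- tcrossprod(dA, net$W[[paste0("enc", i)]])
  }
  list(W = gW, b = gb)
}

# ---- Adam optimizer on arbitrary named lists of arrays --------------------

adam_init <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  zeros <- lapply(params, function(p) if (is.null(p)) NULL else p * 0)
  list(m = zeros, v = zeros, t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

# One Adam step; grads may contain NULL entries (parameter untouched this
# step). Gradients are jointly clipped to global L2 norm `clip` first.
adam_step <- function(opt, params, grads, clip = NULL) {
  if (!is.null(clip)) {
    sq <- sum(vapply(grads, function(g) if (is.null(g)) 0 else sum(g * g), 0))
    gn <- sqrt(sq)
    if (is.finite(gn) && gn > clip) grads <- lapply(grads, function(g) if (is.null(g)) NULL else g * (clip / gn))
  }
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    opt$m[[k]] <- opt$beta1 * opt$m[[k]] + (1 - opt$beta1) * g
    opt$v[[k]] <- opt$beta2 * opt$v[[k]] + (1 - opt$beta2) * g * g
    mhat <- opt$m[[k]] / bc1
    vhat <- opt$v[[k]] / bc2
    params[[k]] <- params[[k]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  list(opt = opt, params = params)
}

# Fast Adam: state kept in an environment, parameter arrays updated in place
# by the C++ kernel (the trainer owns every reference to them).
fast_adam_init <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st$t <- 0L
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

fast_adam_step <- function(st, grads, clip = 0) {
  grads <- grads[names(st$params)]
  st$t <- adam_update_cpp(st$params, st$m, st$v, grads, st$t,
                          st$lr, st$beta1, st$beta2, st$eps,
                          if (is.null(clip)) 0 else clip)
  invisible(st)
}

# Flatten/apply helpers so a network's W and b share one optimizer.
net_params <- function(net) c(stats::setNames(net$W, paste0("W.", names(net$W))),
                              stats::setNames(net$b, paste0("b.", names(net$b))))
net_grads <- function(gr) c(stats::setNames(gr$W, paste0("W.", names(gr$W))),
                            stats::setNames(gr$b, paste0("b.", names(gr$b))))
net_set_params <- function(net, params) {
  for (k in names(net$W)) net$W[[k]] <- params[[paste0("W.", k)]]
  for (k in names(net$b)) net$b[[k]] <- params[[paste0("b.", k)]]
  net
}

#' Save / load a trained network
#'
#' Checkpoints the full network (weights and config) to an RDS file.
#'
#' @param net a `zinb_network`.
#' @param path file path.
#' @return `save_model`: `path` invisibly; `load_model`: the network.
#' @export
save_model <- function(net, path) { saveRDS(net, path); invisible(path) }

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
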