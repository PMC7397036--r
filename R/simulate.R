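#' Simulation configuration for two-batch count data
#'
#' Parameters of the two-batch negative-binomial scRNA-seq count simulator
#' (a Splat-style generative model). Gene base means are Gamma draws; each
#' cell group perturbs a random subset of genes by multiplicative
#' differential-expression factors; each batch perturbs every gene by a
#' batch factor; counts are negative binomial around the cell-gene mean and
#' are then thinned by mean-dependent logistic dropout.
#'
#' @param n_genes number of genes.
#' @param n_groups number of cell groups (types), labeled "0", "1", ...
#' @param source_cells,target_cells cells per batch. The benchmark design
#'   uses 3600/3600 ("equal") or 3600/1800 ("unequal").
#' @param balance `"balanced"` (equal group sizes) or `"imbalanced"` (group
#'   sizes in geometric proportion with ratio `imbalance_ratio`).
#' @param imbalance_ratio geometric ratio of the imbalanced design.
#' @param dropout_mid midpoint of the logistic dropout curve on the log-mean
#'   scale; the benchmark grid uses -1, -0.5, 0, 0.5, larger = more zeros.
#' @param dropout_shape slope of the logistic dropout curve (negative so
#'   that lowly expressed genes drop out more).
#' @param de_prob fraction of genes differentially expressed per group.
#' @param de_facLoc location of the log DE factors (the Splat default 0.1);
#'   factors are `exp(sign * |N(de_facLoc, de_facScale)|)` with a random
#'   up/down sign per gene.
#' @param de_facScale standard deviation of the log DE factors.
#' @param batch_effect standard deviation of the per-batch log gene factors
#'   (0 disables batch effects).
#' @param bcv biological coefficient of variation; NB inverse-dispersion is
#'   `1 / bcv^2`.
#' @param lib_loc,lib_scale meanlog / sdlog of the log-normal expected
#'   library size.
#' @param mean_shape,mean_rate Gamma parameters of the gene base means.
#' @param seed random seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2500L, n_groups = 6L,
                       source_cells = 3600L, target_cells = 3600L,
                       balance = c("balanced", "imbalanced"),
                       imbalance_ratio = 0.8,
                       dropout_mid = 0, dropout_shape = -1,
                       de_prob = 0.1, de_facLoc = 0.1, de_facScale = 0.2,
                       batch_effect = 0.1, bcv = 0.2,
                       lib_loc = 11, lib_scale = 0.2,
                       mean_shape = 0.6, mean_rate = 0.3,
                       seed = 1L) {
  balance <- match.arg(balance)
  stopifnot(n_genes > 0, n_groups > 0, source_cells > 0, target_cells > 0,
            de_prob >= 0, de_prob <= 1, bcv > 0, imbalance_ratio > 0)
  structure(as.list(environment()), class = "sim_config")
}

# Group proportions: equal, or geometric with the given ratio, normalized.
group_proportions <- function(cfg) {
  p <- if (cfg$balance == "balanced") rep(1, cfg$n_groups)
       else cfg$imbalance_ratio^(seq_len(cfg$n_groups) - 1)
  p / sum(p)
}

# Integer group sizes summing exactly to n (largest-remainder rounding).
apportion <- function(n, prop) {
  raw <- n * prop
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(-(raw - base))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate a two-batch labeled scRNA-seq dataset
#'
#' Draws a source and a target batch from the generative model described in
#' [sim_config()]. Both batches share the same groups, gene base means and DE
#' factors, and differ by batch-specific gene factors, so the batches emulate
#' the same tissue profiled twice. Group labels are attached to both batches;
#' callers benchmarking annotation typically keep the target labels aside as
#' ground truth.
#'
#' @param cfg a [sim_config()].
#' @return list with `source` and `target` [count_matrix()] objects (labels
#'   on both) and `de_factors` (genes x groups matrix of the drawn factors,
#'   for generator diagnostics).
#' @export
simulate_two_batch <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  g <- cfg$n_genes
  base_mean <- stats::rgamma(g, shape = cfg$mean_shape, rate = cfg$mean_rate)
  base_mean <- pmax(base_mean, 1e-8)

  de_fac <- matrix(1, g, cfg$n_groups)
  for (grp in seq_len(cfg$n_groups)) {
    is_de <- stats::runif(g) < cfg$de_prob
    n_de <- sum(is_de)
    if (n_de > 0) {
      sgn <- sample(c(-1, 1), n_de, replace = TRUE)
      de_fac[is_de, grp] <- exp(sgn * abs(stats::rnorm(n_de, cfg$de_facLoc, cfg$de_facScale)))
    }
  }
  batch_fac <- sapply(1:2, function(b) {
    if (cfg$batch_effect > 0) exp(stats::rnorm(g, 0, cfg$batch_effect)) else rep(1, g)
  })

  prop <- group_proportions(cfg)
  sim_batch <- function(n_cells, b, prefix) {
    sizes <- apportion(n_cells, prop)
    group <- rep(seq_len(cfg$n_groups), sizes)
    lib <- stats::rlnorm(n_cells, cfg$lib_loc, cfg$lib_scale)
    counts <- matrix(0L, n_cells, g)
    gene_mean <- base_mean * batch_fac[, b]          # genes
    for (grp in seq_len(cfg$n_groups)) {
      rows <- which(group == grp)
      if (length(rows) == 0L) next
      m <- gene_mean * de_fac[, grp]
      p <- m / sum(m)
      lam <- outer(lib[rows], p)                     # cells x genes
      x <- matrix(stats::rnbinom(length(lam), mu = lam, size = 1 / cfg$bcv^2),
                  nrow(lam), ncol(lam))
      p_drop <- stats::plogis(cfg$dropout_shape * (log(lam) - cfg$dropout_mid))
      keep <- matrix(stats::runif(length(lam)) >= p_drop, nrow(lam), ncol(lam))
      counts[rows, ] <- x * keep
    }
    count_matrix(counts,
                 gene_names = paste0("gene", seq_len(g)),
                 cell_ids = paste0(prefix, seq_len(n_cells)),
                 batch = rep(b - 1L, n_cells),
                 labels = as.character(group - 1L))
  }
  source <- sim_batch(cfg$source_cells, 1L, "s")
  target <- sim_batch(cfg$target_cells, 2L, "t")
  list(source = source, target = target, de_factors = de_fac)
}

#' The 16 benchmark simulation scenarios
#'
#' Cross product of batch sizing (`equal`: 3600/3600, `unequal`: 3600/1800),
#' group balance (`balanced`, `imbalanced` with ratio 0.8) and dropout
#' midpoint (-1, -0.5, 0, 0.5) — 16 configurations, each replicable under
#' any number of seeds.
#'
#' @param source_cells source batch size (default 3600).
#' @param target_cells_equal,target_cells_unequal target batch sizes of the
#'   two sizing arms (defaults 3600 and 1800). Smaller values give
#'   down-scaled versions of the same designs.
#' @param n_genes number of genes (default 2500).
#' @param seed base seed stored in every config.
#' @return named list of 16 [sim_config()] objects; names are
#'   `<sizing>_<balance>_mid<dropout_mid>`.
#' @export
paper_scenarios <- function(source_cells = 3600L, target_cells_equal = 3600L,
                            target_cells_unequal = 1800L, n_genes = 2500L,
                            seed = 1L) {
  out <- list()
  for (sizing in c("equal", "unequal")) {
    for (bal in c("balanced", "imbalanced")) {
      for (mid in c(-1, -0.5, 0, 0.5)) {
        tc <- if (sizing == "equal") target_cells_equal else target_cells_unequal
        nm <- paste0(sizing, "_", bal, "_mid", mid)
        out[[nm]] <- sim_config(n_genes = n_genes, source_cells = source_cells,
                                target_cells = tc, balance = bal,
                                dropout_mid = mid, seed = seed)
      }
    }
  }
  out
}
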