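# Shared fixture builders; everything is generated in code at test time.

# tiny deterministic CountMatrix
tiny_counts <- function() {
  count_matrix(matrix(c(0, 5, 1, 0, 2, 2), nrow = 3, byrow = TRUE),
               gene_names = c("g1", "g2"),
               cell_ids = c("c1", "c2", "c3"))
}

# small labeled two-batch dataset for pipeline smoke tests: clearly separated
# NB populations so short training runs succeed
small_sim <- function(n_per_batch = 240, n_genes = 400, dropout_mid = -1,
                      seed = 7) {
  cfg <- sim_config(n_genes = n_genes, n_groups = 3,
                    source_cells = n_per_batch, target_cells = n_per_batch,
                    dropout_mid = dropout_mid, de_facScale = 0.5,
                    lib_loc = 9, seed = seed)
  simulate_two_batch(cfg)
}

# independent log-space NB pmf via lgamma, used as oracle against the package
nb_log_pmf_oracle <- function(x, mu, theta) {
  lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    theta * log(theta / (theta + mu)) + x * log(mu / (mu + theta))
}
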