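test_that("simulated batches have the configured sizes and group structure", {
  cfg <- sim_config(n_genes = 200, source_cells = 360, target_cells = 180,
                    balance = "balanced", seed = 2)
  sim <- simulate_two_batch(cfg)
  expect_equal(dim(sim$source$counts), c(360L, 200L))
  expect_equal(dim(sim$target$counts), c(180L, 200L))
  # balanced: exactly equal group sizes in each batch
  expect_true(all(table(sim$source$labels) == 60))
  expect_true(all(table(sim$target$labels) == 30))
  expect_equal(sim$source$batch, rep(0L, 360))
  expect_equal(sim$target$batch, rep(1L, 180))
  # counts are valid: non-negative integers
  expect_true(all(sim$source$counts >= 0))
  expect_true(all(sim$source$counts == round(sim$source$counts)))
})

test_that("imbalanced group sizes follow the geometric 0.8 progression", {
  cfg <- sim_config(n_genes = 100, source_cells = 500, target_cells = 500,
                    balance = "imbalanced", seed = 3)
  sim <- simulate_two_batch(cfg)
  sizes <- as.numeric(table(factor(sim$source$labels, levels = as.character(0:5))))
  expected <- 0.8^(0:5) / sum(0.8^(0:5)) * 500
  expect_true(all(abs(sizes - expected) <= 1))  # integer apportionment
  expect_equal(sum(sizes), 500)
  expect_true(all(diff(sizes) <= 0))
})

test_that("raising dropout_mid strictly increases the zero fraction", {
  zf <- sapply(c(-1, -0.5, 0, 0.5), function(mid) {
    cfg <- sim_config(n_genes = 300, source_cells = 200, target_cells = 200,
                      dropout_mid = mid, seed = 4)
    sim <- simulate_two_batch(cfg)
    mean(cbind(sim$source$counts, sim$target$counts) == 0)
  })
  expect_true(all(diff(zf) > 0))
})

test_that("simulation is seed-deterministic", {
  cfg <- sim_config(n_genes = 80, source_cells = 50, target_cells = 50, seed = 5)
  s1 <- simulate_two_batch(cfg)
  s2 <- simulate_two_batch(cfg)
  expect_identical(s1$source$counts, s2$source$counts)
  expect_identical(s1$target$counts, s2$target$counts)
  s3 <- simulate_two_batch(sim_config(n_genes = 80, source_cells = 50,
                                      target_cells = 50, seed = 6))
  expect_false(identical(s1$source$counts, s3$source$counts))
})

test_that("group log fold-changes recover the drawn DE factors", {
  # no batch effect, dropout pushed far off: observed group means should
  # concentrate around the drawn DE factors
  cfg <- sim_config(n_genes = 400, n_groups = 2, source_cells = 2000,
                    target_cells = 50, balance = "balanced",
                    batch_effect = 0, dropout_mid = -30, de_facScale = 0.5,
                    seed = 7)
  sim <- simulate_two_batch(cfg)
  counts <- sim$source$counts
  lab <- sim$source$labels
  m0 <- colMeans(counts[lab == "0", ])
  m1 <- colMeans(counts[lab == "1", ])
  keep <- m0 > 1 & m1 > 1
  lfc_obs <- log(m1[keep] / m0[keep])
  lfc_true <- log(sim$de_factors[keep, 2] / sim$de_factors[keep, 1])
  expect_gt(cor(lfc_obs, lfc_true), 0.9)
  expect_lt(mean(abs(lfc_obs - lfc_true)), 0.15)
})

test_that("NB count moments follow mean and bcv dispersion", {
  cfg <- sim_config(n_genes = 60, n_groups = 1, source_cells = 4000,
                    target_cells = 50, batch_effect = 0, dropout_mid = -30,
                    lib_scale = 1e-8, bcv = 0.3, seed = 8)
  sim <- simulate_two_batch(cfg)
  mu_hat <- colMeans(sim$source$counts)
  v_hat <- apply(sim$source$counts, 2, var)
  keep <- mu_hat > 5
  # var = mu + bcv^2 mu^2
  v_exp <- mu_hat[keep] + 0.3^2 * mu_hat[keep]^2
  expect_lt(median(abs(v_hat[keep] / v_exp - 1)), 0.15)
})

test_that("remove_types drops exactly the named groups", {
  cfg <- sim_config(n_genes = 50, source_cells = 360, target_cells = 60, seed = 9)
  sim <- simulate_two_batch(cfg)
  cut <- remove_types(sim$source, c("0", "1"))
  expect_equal(nrow(cut$counts), 240L)
  expect_equal(sort(unique(cut$labels)), as.character(2:5))
  expect_equal(cut$gene_names, sim$source$gene_names)
  expect_identical(remove_types(sim$source, character(0)), sim$source)
  expect_error(remove_types(sim$source, as.character(0:5)), "all cells")
})

test_that("the benchmark grid enumerates all 16 scenario combinations", {
  sc <- paper_scenarios()
  expect_length(sc, 16L)
  expect_true(all(vapply(sc, inherits, TRUE, "sim_config")))
  mids <- vapply(sc, function(s) s$dropout_mid, 1)
  expect_equal(sort(unique(mids)), c(-1, -0.5, 0, 0.5))
  sizes <- vapply(sc, function(s) s$target_cells, 1)
  expect_equal(sort(unique(sizes)), c(1800, 3600))
  expect_true(all(vapply(sc, function(s) s$source_cells, 1) == 3600))
  bals <- vapply(sc, function(s) s$balance, "")
  expect_equal(sort(unique(bals)), c("balanced", "imbalanced"))
  # the Sankey/novel-type illustration configuration is present
  expect_true("equal_balanced_mid0.5" %in% names(sc))
  # distinct seeds give distinct replicable datasets of the same scenario
  expect_equal(sc$equal_balanced_mid0.5$dropout_mid, 0.5)
  expect_equal(sc$equal_balanced_mid0.5$balance, "balanced")
})
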