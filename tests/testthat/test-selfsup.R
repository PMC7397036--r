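test_that("cosine similarity matches a double-loop oracle", {
  z <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 2, 0))
  S <- cosine_similarity(z)
  expect_equal(S[1, 2], 1)
  expect_equal(S[1, 3], 0)
  expect_equal(diag(S), rep(1, 3))

  set.seed(10)
  z <- matrix(rnorm(6 * 32), 6, 32)
  S <- cosine_similarity(z)
  for (i in 1:6) for (j in 1:6) {
    expect_equal(S[i, j],
                 sum(z[i, ] * z[j, ]) / sqrt(sum(z[i, ]^2) * sum(z[j, ]^2)),
                 tolerance = 1e-10)
  }
  expect_error(cosine_similarity(rbind(c(0, 0, 0), c(1, 0, 0))), "zero-norm")
})

test_that("threshold schedule reproduces the printed linear formulas", {
  t1 <- threshold_schedule(1)
  expect_equal(t1$u, 0.9455)
  expect_equal(t1$l, 0.45545)
  expect_true(t1$active)
  t100 <- threshold_schedule(100)
  expect_equal(t100$u, 0.5)
  expect_equal(t100$l, 0.5)
  expect_true(t100$active)   # u = l is still active; the last fusion epoch
  expect_false(threshold_schedule(101)$active)
  # monotone: u strictly decreasing, l strictly increasing
  us <- sapply(1:100, function(t) threshold_schedule(t)$u)
  ls <- sapply(1:100, function(t) threshold_schedule(t)$l)
  expect_true(all(diff(us) < 0))
  expect_true(all(diff(ls) > 0))
})

test_that("pseudo-labels follow the label-override and threshold rules", {
  S <- diag(4)
  S[1, 2] <- S[2, 1] <- 0.1    # both labeled "A": label rule wins
  S[1, 3] <- S[3, 1] <- 0.7    # labeled/unlabeled, inside the band: dropped
  S[3, 4] <- S[4, 3] <- 0.96   # unlabeled pair above u: positive
  S[2, 3] <- S[3, 2] <- 0.40   # mixed pair below l: negative
  S[2, 4] <- S[4, 2] <- 0.50   # inside band: dropped
  labels <- c("A", "A", NA, NA)
  pl <- build_pseudo_labels(S, labels, u = 0.9455, l = 0.45545)
  expect_equal(pl$R_hat[1, 2], 1)          # label override despite S = 0.1
  expect_equal(pl$selected[1, 2], 1)
  expect_equal(pl$selected[1, 3], 0)       # in-band mixed pair not selected
  expect_equal(pl$R_hat[3, 4], 1)
  expect_equal(pl$selected[3, 4], 1)
  expect_equal(pl$R_hat[2, 3], 0)
  expect_equal(pl$selected[2, 3], 1)
  expect_equal(diag(pl$selected), rep(0, 4))  # self-pairs excluded
  # disagreeing labels are negative pairs regardless of similarity
  pl2 <- build_pseudo_labels(S, c("A", "B", NA, NA), u = 0.9455, l = 0.45545)
  expect_equal(pl2$R_hat[1, 2], 0)
  expect_equal(pl2$selected[1, 2], 1)
})

test_that("the selected pair set grows as thresholds tighten", {
  set.seed(13)
  z <- matrix(rnorm(30 * 8), 30, 8)
  S <- cosine_similarity(z)
  labels <- rep(NA_character_, 30)
  n_sel <- sapply(c(1, 25, 50, 75, 100), function(t) {
    th <- threshold_schedule(t)
    sum(build_pseudo_labels(S, labels, th$u, th$l)$selected)
  })
  expect_true(all(diff(n_sel) >= 0))
})

test_that("self-supervised loss is the mean BCE over selected pairs", {
  S1 <- matrix(c(1, 1 - 1e-6, 1 - 1e-6, 1), 2)
  sel <- matrix(c(0, 1, 1, 0), 2)
  expect_lt(self_supervised_loss(S1, matrix(1, 2, 2), sel), 1e-5)
  S2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(self_supervised_loss(S2, matrix(1, 2, 2), sel), log(2),
               tolerance = 1e-9)
  # warning and zero when nothing is selected
  expect_warning(l0 <- self_supervised_loss(S2, matrix(1, 2, 2), matrix(0, 2, 2)),
                 "no selected")
  expect_equal(l0, 0)

  set.seed(14)
  z <- matrix(rnorm(8 * 5), 8, 5)
  S <- cosine_similarity(z)
  pl <- build_pseudo_labels(S, rep(NA_character_, 8), u = 0.3, l = 0.1)
  loss <- self_supervised_loss(S, pl$R_hat, pl$selected)
  # double-loop oracle with the same clamping
  acc <- 0; nsel <- 0
  for (i in 1:8) for (j in 1:8) {
    if (pl$selected[i, j] == 1) {
      s <- min(max(S[i, j], 1e-6), 1 - 1e-6)
      acc <- acc - pl$R_hat[i, j] * log(s) - (1 - pl$R_hat[i, j]) * log(1 - s)
      nsel <- nsel + 1
    }
  }
  expect_equal(loss, acc / nsel, tolerance = 1e-8)
  # symmetric in (i, j) and invariant to cell permutation
  perm <- sample(8)
  expect_equal(self_supervised_loss(S[perm, perm], pl$R_hat[perm, perm],
                                    pl$selected[perm, perm]), loss,
               tolerance = 1e-12)
})

test_that("fusion on data with source-absent populations separates them", {
  # two target-only populations: after fusion their within-population cosine
  # similarity should exceed the across-population similarity
  sim <- small_sim(150, 300, seed = 21)
  src <- remove_types(sim$source, c("0", "1"))
  pd <- preprocess(merge_on_shared_genes(src, sim$target), n_hvg = 150)
  cfg <- network_config(epochs_pretrain = 40, epochs_fuse = 100,
                        epochs_cluster_max = 1, seed = 2)
  fit <- run_pipeline(pd, k = 3, plan = train_plan(cfg, use_cluster = FALSE))
  is_t <- pd$batch == 1
  zt <- fit$z_norm[is_t, ]
  lab_t <- sim$target$labels
  S <- tcrossprod(zt)
  in0 <- lab_t == "0"; in1 <- lab_t == "1"
  within <- mean(c(S[in0, in0][upper.tri(S[in0, in0])],
                   S[in1, in1][upper.tri(S[in1, in1])]))
  across <- mean(S[in0, in1])
  expect_gt(within, across)
})
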