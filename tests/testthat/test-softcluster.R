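unit <- function(x) x / sqrt(sum(x^2))

test_that("soft assignments follow the closed form", {
  z <- rbind(unit(c(1, 1, 0)), unit(c(0, 1, 1)))
  # k = 1: every membership is 1
  w1 <- soft_assignments(z, matrix(unit(c(1, 0, 0)), 1))
  expect_equal(unname(w1), matrix(1, 2, 1))
  # equidistant centers: uniform memberships
  v <- rbind(c(1, 0, 0), c(0, 0, 1))
  weq <- soft_assignments(rbind(unit(c(0, 1, 0))), v)
  expect_equal(unname(weq), matrix(0.5, 1, 2), tolerance = 1e-12)
  # z.v1 = 1, z.v2 = 0, sigma = 1: w1 = 1/(1 + e^-2)
  z3 <- rbind(c(1, 0, 0))
  v3 <- rbind(c(1, 0, 0), c(0, 1, 0))
  w3 <- soft_assignments(z3, v3, sigma = 1)
  expect_equal(w3[1, 1], 1 / (1 + exp(-2)), tolerance = 1e-12)
  # rows always sum to one
  set.seed(15)
  z4 <- t(apply(matrix(rnorm(40), 10, 4), 1, unit))
  v4 <- t(apply(matrix(rnorm(12), 3, 4), 1, unit))
  w4 <- soft_assignments(z4, v4)
  expect_equal(unname(rowSums(w4)), rep(1, 10), tolerance = 1e-9)
  expect_warning(soft_assignments(z4 * 2, v4), "renormalizing")
})

test_that("closed-form memberships minimize the entropy-regularized objective", {
  # one cell, two centers: grid search over the probability simplex
  z <- rbind(unit(c(1, 0.3, 0)))
  v <- rbind(unit(c(1, 0, 0)), unit(c(0, 1, 1)))
  sigma <- 1
  d <- as.numeric(2 * (1 - tcrossprod(z, v)))
  objective <- function(w1) {
    w <- c(w1, 1 - w1)
    sum(w * d) + sigma * sum(w * log(w))
  }
  grid <- seq(1e-6, 1 - 1e-6, length.out = 200001)
  w_grid <- grid[which.min(sapply(grid, objective))]
  w_closed <- soft_assignments(z, v, sigma)[1, 1]
  expect_equal(w_closed, w_grid, tolerance = 1e-4)
  # and for a 3-cell instance, cell by cell
  set.seed(16)
  z3 <- t(apply(matrix(rnorm(9), 3, 3), 1, unit))
  w3 <- soft_assignments(z3, v, sigma)
  for (i in 1:3) {
    d <- as.numeric(2 * (1 - tcrossprod(z3[i, , drop = FALSE], v)))
    w_grid <- grid[which.min(sapply(grid, function(w1) {
      w <- c(w1, 1 - w1); sum(w * d) + sigma * sum(w * log(w))
    }))]
    expect_equal(w3[i, 1], w_grid, tolerance = 1e-4)
  }
})

test_that("sigma -> 0 approaches hard nearest-center assignment", {
  set.seed(17)
  z <- t(apply(matrix(rnorm(20), 5, 4), 1, unit))
  v <- t(apply(matrix(rnorm(8), 2, 4), 1, unit))
  w <- soft_assignments(z, v, sigma = 1e-4)
  nearest <- max.col(tcrossprod(z, v))
  expect_equal(hard_labels(w), nearest)
  expect_true(all(w[cbind(1:5, nearest)] > 1 - 1e-6))
})

test_that("spherical distance identity 2(1 - z.v) = ||z - v||^2 holds", {
  set.seed(18)
  for (i in 1:20) {
    z <- unit(rnorm(6)); v <- unit(rnorm(6))
    expect_equal(2 * (1 - sum(z * v)), sum((z - v)^2), tolerance = 1e-12)
  }
})

test_that("clustering loss matches its double-loop oracle", {
  # all cells at their centers with (near) one-hot memberships: loss ~ 0
  v <- rbind(c(1, 0), c(0, 1))
  z <- v
  w <- diag(2)
  w <- w * (1 - 1e-9) + 1e-9 / 2
  expect_lt(clustering_loss(z, v, w), 1e-8)
  # k = 1, z = -v: loss = 2 * 1 * (1 - (-1)) = 4
  expect_equal(clustering_loss(matrix(c(-1, 0), 1), matrix(c(1, 0), 1),
                               matrix(1, 1, 1)), 4, tolerance = 1e-12)
  set.seed(19)
  z <- t(apply(matrix(rnorm(24), 6, 4), 1, unit))
  v <- t(apply(matrix(rnorm(12), 3, 4), 1, unit))
  w <- soft_assignments(z, v)
  acc <- 0
  for (i in 1:6) for (j in 1:3) acc <- acc + 2 * w[i, j] * (1 - sum(z[i, ] * v[j, ]))
  expect_equal(clustering_loss(z, v, w), acc / 6, tolerance = 1e-8)
  expect_error(clustering_loss(z, v, w[, 1:2]), "shape mismatch")
})

test_that("center initialization is deterministic and finds separated clouds", {
  set.seed(20)
  centers_true <- rbind(c(5, 0, 0), c(0, 5, 0), c(0, 0, 5))
  z <- do.call(rbind, lapply(1:3, function(g) {
    sweep(matrix(rnorm(30 * 3, sd = 0.1), 30, 3), 2, centers_true[g, ], "+")
  }))
  v1 <- init_centers(z, 3, seed = 1)
  v2 <- init_centers(z, 3, seed = 1)
  expect_identical(v1, v2)
  expect_equal(unname(sqrt(rowSums(v1^2))), rep(1, 3), tolerance = 1e-9)
  # each true (normalized) cloud mean is close to exactly one center
  d <- tcrossprod(t(apply(centers_true, 1, unit)), v1)
  expect_true(all(apply(d, 1, max) > 0.99))
  expect_equal(sort(apply(d, 1, which.max)), 1:3)
  # degenerate k = n: every center is a data point
  z5 <- t(apply(matrix(rnorm(15), 5, 3), 1, unit))
  v5 <- init_centers(z5, 5, seed = 2)
  d5 <- tcrossprod(z5, v5)
  expect_true(all(apply(d5, 1, max) > 1 - 1e-9))
  expect_error(init_centers(z5, 6), "fewer cells")
})

test_that("hard labels take the argmax with first-index tie-breaking", {
  expect_equal(hard_labels(matrix(c(0.7, 0.3), 1)), 1L)
  expect_equal(hard_labels(matrix(c(0.5, 0.5), 1)), 1L)
  set.seed(22)
  z <- t(apply(matrix(rnorm(40), 10, 4), 1, unit))
  v <- t(apply(matrix(rnorm(12), 3, 4), 1, unit))
  w <- soft_assignments(z, v)
  expect_equal(hard_labels(w), hard_labels(soft_assignments(z, v)))
})

test_that("alternating membership/center updates do not increase the objective", {
  set.seed(23)
  sigma <- 1
  z <- t(apply(matrix(rnorm(60), 15, 4), 1, unit))
  v <- init_centers(z, 3, seed = 1)
  objective <- function(v, w) {
    sum(w * (2 * (1 - tcrossprod(z, v)))) + sigma * sum(w * log(w))
  }
  w <- soft_assignments(z, v, sigma)
  obj <- objective(v, w)
  for (step in 1:10) {
    w <- soft_assignments(z, v, sigma)            # exact minimizer in w
    g <- scRefCluster:::cluster_grad(z, v, w)$dV  # gradient step in v
    v_new <- v - 0.05 * g * nrow(z)
    v_new <- v_new / sqrt(rowSums(v_new^2))
    if (objective(v_new, w) <= objective(v, w)) v <- v_new
    obj_new <- objective(v, soft_assignments(z, v, sigma))
    expect_lte(obj_new, obj + 1e-10)
    obj <- obj_new
  }
})
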