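test_that("dense CSV counts round-trip through read_counts", {
  cm <- tiny_counts()
  path <- withr::local_tempfile(fileext = ".csv")
  write_counts(cm, path, fmt = "dense")
  back <- read_counts(path, fmt = "dense")
  expect_equal(unname(back$counts), unname(cm$counts))
  expect_equal(back$gene_names, cm$gene_names)
  expect_equal(back$cell_ids, cm$cell_ids)
})

test_that("MatrixMarket counts round-trip and match the dense reader", {
  cm <- tiny_counts()
  path <- withr::local_tempfile(fileext = ".mtx")
  write_counts(cm, path, fmt = "mtx")
  back <- read_counts(path, fmt = "mtx")
  expect_equal(unname(back$counts), unname(cm$counts))
  expect_equal(back$gene_names, cm$gene_names)
  expect_equal(back$cell_ids, cm$cell_ids)
})

test_that("invalid counts are rejected", {
  expect_error(count_matrix(matrix(c(-1, 2), 1)), "negative")
  expect_error(count_matrix(matrix(c(0.5, 2), 1)), "non-integer")
  expect_error(count_matrix(matrix(c(NA_real_, 2), 1)), "non-finite")
  expect_error(count_matrix(matrix(0:3, 2), gene_names = c("a", "a")), "duplicated gene")
  expect_error(count_matrix(matrix(0:3, 2), cell_ids = c("c", "c")), "duplicated cell")
  # near-integers within 1e-6 are rounded, not rejected
  cm <- count_matrix(matrix(c(1 + 1e-8, 2), 1))
  expect_identical(cm$counts[1, 1], 1)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell,g1,g2", "c1,-1,2"), path)
  expect_error(read_counts(path), "negative")
})

test_that("merge_on_shared_genes intersects genes in source order", {
  src <- count_matrix(matrix(1:6, 2, 3), gene_names = c("a", "b", "c"),
                      cell_ids = c("s1", "s2"), labels = c("T", "B"))
  tgt <- count_matrix(matrix(1:6, 2, 3), gene_names = c("b", "c", "d"),
                      cell_ids = c("t1", "t2"))
  merged <- merge_on_shared_genes(src, tgt)
  expect_equal(merged$gene_names, c("b", "c"))
  expect_equal(merged$batch, c(0L, 0L, 1L, 1L))
  expect_equal(merged$labels, c("T", "B", NA, NA))
  expect_equal(unname(merged$counts[1:2, ]), unname(src$counts[, 2:3]))

  # identical gene sets: everything kept, source order
  merged2 <- merge_on_shared_genes(src, count_matrix(matrix(1:6, 2, 3),
                                                     gene_names = c("a", "b", "c"),
                                                     cell_ids = c("u1", "u2")))
  expect_equal(merged2$gene_names, c("a", "b", "c"))
  expect_equal(nrow(merged2$counts), 4L)

  # disjoint gene sets error
  expect_error(merge_on_shared_genes(src, count_matrix(matrix(1:4, 2, 2),
                                                       gene_names = c("x", "y"),
                                                       cell_ids = c("t1", "t2"))),
               "no shared genes")
})

test_that("merging is invariant to target gene permutation", {
  set.seed(1)
  a <- count_matrix(matrix(rpois(24, 4), 4, 6),
                    gene_names = paste0("g", 1:6), cell_ids = paste0("c", 1:4))
  perm <- sample(6)
  b <- count_matrix(a$counts[, perm], gene_names = a$gene_names[perm],
                    cell_ids = paste0("d", 1:4))
  merged <- merge_on_shared_genes(a, b)
  expect_equal(merged$gene_names, a$gene_names)
  expect_equal(unname(merged$counts[5:8, ]), unname(a$counts))
})

test_that("size factors follow total/median and x_input is z-scored", {
  cm <- count_matrix(matrix(c(60, 40, 100, 200), 2, 2, byrow = TRUE),
                     gene_names = c("g1", "g2"), cell_ids = c("c1", "c2"))
  pd <- preprocess(cm, n_hvg = 2)
  # totals (100, 300), median 200 -> size factors (0.5, 1.5)
  expect_equal(pd$size_factor, c(0.5, 1.5))

  set.seed(3)
  cm2 <- count_matrix(matrix(rpois(300, 5) + 1, 20, 15))
  pd2 <- preprocess(cm2, n_hvg = 10)
  expect_lt(max(abs(colMeans(pd2$x_input))), 1e-6)
  expect_lt(max(abs(apply(pd2$x_input, 2, stats::var) - 1)), 1e-6)
  expect_equal(colnames(pd2$x_raw), pd2$hvg_names)
  expect_true(all(rowSums(pd2$batch_onehot) == 1))
  expect_error(preprocess(count_matrix(matrix(c(0, 0, 1, 2), 2, 2, byrow = TRUE))), "zero total")
})

test_that("preprocess matches a brute-force reimplementation", {
  set.seed(11)
  counts <- matrix(rpois(40, 6) + 1, 5, 8)
  cm <- count_matrix(counts)
  pd <- preprocess(cm, n_hvg = 8)  # all genes kept
  # independent step-by-step oracle
  totals <- rowSums(counts)
  sf <- totals / median(totals)
  logx <- log1p(counts / sf)
  zx <- apply(logx, 2, function(col) (col - mean(col)) / sd(col))
  expect_equal(unname(pd$x_input), unname(zx), tolerance = 1e-12)
  expect_equal(unname(pd$x_raw), unname(counts))
  # selecting n_hvg = n_genes then z-scoring equals skipping selection
  expect_equal(pd$hvg_names, cm$gene_names)
})

test_that("preprocess is deterministic and HVG ranking honors dispersion", {
  set.seed(5)
  counts <- matrix(rpois(600, 8) + 1, 20, 30)
  # make a known gene clearly bimodal so it must be selected
  counts[1:10, 7] <- counts[1:10, 7] + 300L
  cm <- count_matrix(counts)
  a <- preprocess(cm, n_hvg = 5)
  b <- preprocess(cm, n_hvg = 5)
  expect_identical(a, b)
  expect_true("g7" %in% a$hvg_names)
  expect_equal(ncol(a$x_input), 5L)
})

test_that("processed data survives a write/read round-trip", {
  sim <- small_sim(40, 60)
  pd <- preprocess(merge_on_shared_genes(sim$source, sim$target), n_hvg = 20)
  dir <- withr::local_tempdir()
  write_processed(pd, dir)
  back <- read_processed(dir)
  expect_equal(back$x_input, pd$x_input, tolerance = 1e-8)
  expect_equal(unname(back$x_raw), unname(pd$x_raw))
  expect_equal(back$size_factor, pd$size_factor, tolerance = 1e-12)
  expect_equal(back$label_index, pd$label_index)
  expect_equal(back$label_levels, pd$label_levels)
})
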