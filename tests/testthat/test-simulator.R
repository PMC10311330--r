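# Synthetic data generator: manifolds, polynomial gene programs,
# standardization, mixtures and the calibrated noise model.

test_that("cell locations follow the named distribution and seed", {
  u <- sample_cell_locations(manifold_spec("uniform", 1), 500, seed = 4)
  expect_true(all(u$c1 >= 0 & u$c1 <= 1))
  expect_false("c2" %in% names(u))

  g <- sample_cell_locations(manifold_spec("gaussian", 2), 10000, seed = 5)
  expect_lt(abs(mean(g$c1)), 0.05)
  expect_lt(abs(mean(g$c2)), 0.05)
  expect_lt(abs(var(g$c1) - 1), 0.1)
  expect_lt(abs(var(g$c2) - 1), 0.1)

  again <- sample_cell_locations(manifold_spec("gaussian", 2), 10000, seed = 5)
  expect_identical(g, again)
  expect_error(manifold_spec("uniform", 3), "dimension")
})

test_that("generated genes are standardized polynomials of their locations", {
  d <- generate_single_manifold_dataset(manifold_spec("uniform", 1), 20, 3,
                                        400, seed = 8)
  v <- d$X$values
  expect_lt(max(abs(rowMeans(v))), 1e-6)
  expect_lt(max(abs(rowMeans(v^2) - 1)), 1e-2)

  # each gene is exactly a cubic in its true location (refit oracle)
  c1 <- d$locations$c1
  for (g in c(1, 7, 20)) {
    fit <- lm(v[g, ] ~ poly(c1, 3, raw = TRUE))
    expect_lt(max(abs(residuals(fit))), 1e-8)
  }
})

test_that("degree-1 genes on a 1-D manifold correlate perfectly with location", {
  d <- generate_single_manifold_dataset(manifold_spec("uniform", 1), 10, 1,
                                        200, seed = 2)
  r <- apply(d$X$values, 1, cor, y = d$locations$c1)
  expect_equal(unname(abs(r)), rep(1, 10), tolerance = 1e-10)
})

test_that("2-D degree-3 genes are not cubics of an unrelated manifold", {
  d <- generate_single_manifold_dataset(manifold_spec("uniform", 2), 10, 3,
                                        500, seed = 31)
  other <- sample_cell_locations(manifold_spec("uniform", 2), 500, seed = 99)
  v <- d$X$values
  own <- cbind(d$locations$c1, d$locations$c2)
  for (g in 1:5) {
    fit_own <- lm(v[g, ] ~ polym(own[, 1], own[, 2], degree = 3, raw = TRUE))
    fit_other <- lm(v[g, ] ~ polym(other$c1, other$c2, degree = 3, raw = TRUE))
    expect_lt(sum(residuals(fit_own)^2), 1e-12)
    expect_gt(sum(residuals(fit_other)^2), 1)
  }
})

test_that("mixing stacks genes, shuffles reproducibly and keeps labels", {
  d1 <- generate_single_manifold_dataset(manifold_spec("uniform", 1), 12, 2,
                                         100, seed = 1, block_label = "S1")
  d2 <- generate_single_manifold_dataset(manifold_spec("gaussian", 2), 8, 3,
                                         100, seed = 2, block_label = "S2")
  m <- mix_datasets(d1, d2, seed = 3)
  expect_equal(n_genes(m$X), 20)
  expect_equal(sort(table(m$truth$block), decreasing = TRUE),
               sort(table(c(rep("S1", 12), rep("S2", 8))), decreasing = TRUE))
  # unshuffling by the recorded permutation recovers the block-ordered stack
  stacked <- rbind(d1$X$values, d2$X$values)
  expect_equal(unname(m$X$values), unname(stacked[m$gene_order_permutation, ]))
  expect_equal(m$truth$gene_id, m$X$gene_ids)
  expect_error(mix_datasets(d1, generate_single_manifold_dataset(
    manifold_spec("uniform", 1), 3, 1, 50, seed = 9)), "cell counts")
})

test_that("noise mixing preserves per-gene standardization at any beta", {
  d <- generate_single_manifold_dataset(manifold_spec("gaussian", 1), 15, 2,
                                        2000, seed = 12)
  for (beta in c(0, 0.5, 1)) {
    nd <- add_noise(d, beta, seed = 77)
    v <- nd$X$values
    expect_lt(max(abs(rowMeans(v))), 1e-6)
    expect_lt(max(abs(rowMeans(v^2) - 1)), 1e-2)
    expect_equal(nd$truth, d$truth)
  }
  expect_identical(add_noise(d, 0, seed = 1)$X$values, d$X$values)
  expect_error(add_noise(d, 1.3, seed = 1), "beta")
})

test_that("beta = 1 wipes out the signal, intermediate beta attenuates it", {
  d <- generate_single_manifold_dataset(manifold_spec("uniform", 1), 20, 3,
                                        10000, seed = 21)
  pure_noise <- add_noise(d, 1, seed = 5)
  r1 <- vapply(seq_len(20), function(g) {
    abs(cor(d$X$values[g, ], pure_noise$X$values[g, ]))
  }, numeric(1))
  expect_lt(mean(r1), 0.05)

  half <- add_noise(d, 0.5, seed = 5)
  r05 <- vapply(seq_len(20), function(g) {
    cor(d$X$values[g, ], half$X$values[g, ])
  }, numeric(1))
  # correlation should be near sqrt(1 - beta)
  expect_equal(mean(r05), sqrt(0.5), tolerance = 0.05)
})

test_that("benchmark recipes compose blocks as documented", {
  d2 <- make_benchmark("D2", n_genes_per_block = 6, N = 80, beta = 0, seed = 3)
  expect_true(all(d2$truth$family == "gaussian"))
  expect_equal(sort(unique(d2$truth$degree)), c(2L, 3L))
  expect_equal(unique(d2$truth$degree[d2$truth$informative]), 2L)

  d4 <- make_benchmark("D4", n_genes_per_block = 6, N = 80, beta = 0, seed = 3)
  expect_equal(sort(unique(d4$truth$degree)), c(1L, 2L))
  expect_equal(unique(d4$truth$dimension[d4$truth$degree == 1L]), 2L)
  expect_equal(unique(d4$truth$degree[d4$truth$informative]), 1L)

  d3 <- make_benchmark("D3", n_genes_per_block = 5, N = 60, beta = 0.75, seed = 4)
  expect_lt(max(abs(rowMeans(d3$X$values^2) - 1)), 1e-2)
  expect_equal(unique(d3$truth$dimension[d3$truth$informative]), 1L)

  d1 <- make_benchmark("D1", n_genes_per_block = 4, N = 50, beta = 0.25, seed = 5)
  expect_setequal(unique(d1$truth$family), c("uniform", "gaussian"))
  expect_true(all(d1$truth$degree == 3L))
  expect_equal(sum(truth_mask(d1)), 4)
})

test_that("benchmarks are byte-reproducible under the same seed", {
  a <- make_benchmark("D1", n_genes_per_block = 5, N = 64, beta = 0.3, seed = 10)
  b <- make_benchmark("D1", n_genes_per_block = 5, N = 64, beta = 0.3, seed = 10)
  expect_identical(a$X$values, b$X$values)
  expect_identical(a$truth, b$truth)
  c_ <- make_benchmark("D1", n_genes_per_block = 5, N = 64, beta = 0.3, seed = 11)
  expect_false(identical(a$X$values, c_$X$values))
})
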