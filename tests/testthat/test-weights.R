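# Gene weight distributions: constructors, relative entropy, the
# multiplicative update, capped-simplex projection and threshold
# classification.

test_that("uniform and indicator constructors give the stated distributions", {
  expect_equal(as.numeric(uniform_weights(4)), rep(0.25, 4))
  expect_equal(as.numeric(uniform_weights(1)), 1)
  u <- uniform_weights(1000)
  expect_equal(as.numeric(u), rep(0.001, 1000))
  expect_lt(abs(sum(u) - 1), 1e-9)
  expect_error(uniform_weights(0), "positive")

  expect_equal(as.numeric(indicator_weights(c(1, 2), 4)), c(0.5, 0.5, 0, 0))
  expect_equal(as.numeric(indicator_weights(3, 3)), c(0, 0, 1))
  expect_equal(as.numeric(indicator_weights(1:7, 7)),
               as.numeric(uniform_weights(7)))
  expect_error(indicator_weights(integer(0), 5), "nonempty")
})

test_that("gene_weights validates simplex and cap invariants", {
  expect_error(gene_weights(c(0.5, 0.6)), "sum to 1")
  expect_error(gene_weights(c(-0.1, 1.1)), "nonnegative")
  expect_error(gene_weights(c(0.9, 0.1), cap = 0.5), "exceeds cap")
  expect_error(gene_weights(rep(0.25, 4), cap = 0.1), "infeasible")
  p <- gene_weights(c(0.4, 0.6), cap = 0.6, gene_ids = c("a", "b"))
  expect_named(p, c("a", "b"))
})

test_that("relative entropy matches direct summation and closed forms", {
  p <- gene_weights(c(0.3, 0.2, 0.5))
  expect_equal(relative_entropy(p, p), 0)
  # chi_S vs uniform with |S| = n/2 is ln 2
  expect_equal(relative_entropy(indicator_weights(1:5, 10), uniform_weights(10)),
               log(2))
  expect_equal(relative_entropy(c(0.8, 0.2), c(0.5, 0.5)),
               0.8 * log(1.6) + 0.2 * log(0.4), tolerance = 1e-12)
  expect_error(relative_entropy(c(0.5, 0.5), c(1, 0)), "support")
})

test_that("mwu_step matches hand arithmetic and fixed points", {
  expect_equal(as.numeric(mwu_step(c(0.5, 0.5), c(0, log(4)), 1)), c(0.8, 0.2),
               tolerance = 1e-12)
  p <- gene_weights(c(0.1, 0.3, 0.6))
  expect_equal(as.numeric(mwu_step(p, c(2, 7, 0.5), 0)), as.numeric(p))
  expect_equal(as.numeric(mwu_step(p, rep(3.7, 3), 1.4)), as.numeric(p),
               tolerance = 1e-12)
  expect_error(mwu_step(p, c(1, 2, 3), -1), "nonnegative")
})

test_that("mwu_step equals the numeric minimizer of the proximal objective", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    p <- as.numeric(rand_simplex(n))
    m <- runif(n, 0, 3)
    eta <- runif(1, 0.1, 3)
    got <- as.numeric(mwu_step(gene_weights(p), m, eta))
    want <- oracle_mwu(p, m, eta)
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("project_capped matches hand cases and is the KL projection", {
  expect_equal(as.numeric(project_capped(c(0.2, 0.3, 0.5), 0.6)),
               c(0.2, 0.3, 0.5))
  expect_equal(as.numeric(project_capped(c(0.9, 0.05, 0.05), 0.5)),
               c(0.5, 0.25, 0.25), tolerance = 1e-12)
  # second pass needed: rescaling pushes entry 2 over the cap
  expect_equal(as.numeric(project_capped(c(0.6, 0.35, 0.05), 0.4)),
               c(0.4, 0.4, 0.2), tolerance = 1e-12)
  expect_error(project_capped(c(0.5, 0.5), 0.3), "infeasible")

  set.seed(7)
  for (rep in 1:15) {
    n <- sample(3:5, 1)
    p <- as.numeric(rand_simplex(n))
    cap <- runif(1, 1 / n + 0.02, 0.9)
    got <- as.numeric(project_capped(p, cap))
    want <- oracle_capped_projection(p, cap)
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("projection is idempotent and never raises the maximum entry", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(2:40, 1)
    p <- as.numeric(rand_simplex(n))
    cap <- runif(1, 1 / n, 1)
    q <- project_capped(p, cap)
    expect_true(all(as.numeric(q) <= cap + 1e-12))
    expect_lte(max(q), max(p) + 1e-12)
    expect_equal(as.numeric(project_capped(q, cap)), as.numeric(q),
                 tolerance = 1e-12)
  }
})

test_that("update and projection always return simplex vectors", {
  set.seed(5)
  for (rep in 1:50) {
    n <- sample(2:100, 1)
    p <- as.numeric(rand_simplex(n))
    m <- rexp(n)
    eta <- runif(1, 0, 5)
    q <- mwu_step(p, m, eta)
    expect_true(all(as.numeric(q) >= 0))
    expect_lt(abs(sum(q) - 1), 1e-9)
    r <- project_capped(q, runif(1, 1 / n, 1))
    expect_true(all(as.numeric(r) >= 0))
    expect_lt(abs(sum(r) - 1), 1e-9)
  }
})

test_that("marginal on S is non-decreasing when S has uniformly smaller errors", {
  set.seed(13)
  ok <- vapply(seq_len(10000), function(rep) {
    n <- sample(2:12, 1)
    p <- as.numeric(rand_simplex(n))
    s_size <- sample(seq_len(n - 1), 1)
    S <- sample.int(n, s_size)
    m <- numeric(n)
    cut <- runif(1, 0.2, 2)
    m[S] <- runif(s_size, 0, cut)
    m[-S] <- runif(n - s_size, cut, cut + 2)
    q <- mwu_step(p, m, runif(1, 0, 3))
    sum(as.numeric(q)[S]) >= sum(p[S]) - 1e-12
  }, logical(1))
  expect_true(all(ok))
})

test_that("classify_genes thresholds at (1 - delta)/n with strict inequality", {
  expect_true(all(classify_genes(uniform_weights(10), 0.2)))
  expect_equal(unname(classify_genes(gene_weights(c(0.5, 0.3, 0.1, 0.05, 0.05)),
                                     0.2)),
               c(TRUE, TRUE, FALSE, FALSE, FALSE))
  chi <- indicator_weights(c(2, 4), 6)
  expect_equal(unname(classify_genes(chi, 0.5)), seq_len(6) %in% c(2, 4))
  # a gene exactly at the threshold is not informative
  n <- 4; delta <- 0.2
  p <- c((1 - delta) / n, rep((1 - (1 - delta) / n) / 3, 3))
  expect_false(classify_genes(gene_weights(p), delta)[1])
  expect_error(classify_genes(uniform_weights(3), 1.2), "delta")
})
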