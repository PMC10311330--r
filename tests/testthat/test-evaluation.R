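# Evaluation metrics: entropy traces, AUC, classification rates, mutual
# information, profile correlation and zonation labelling.

make_toy_traj <- function(W, gene_ids = NULL) {
  n <- ncol(W)
  gene_ids <- gene_ids %||% paste0("g", seq_len(n))
  structure(list(
    weights = W, gradients = W * 0,
    summary = tibble::tibble(round = seq_len(nrow(W)) - 1L,
                             loss = rev(seq_len(nrow(W))) / nrow(W),
                             entropy_to_uniform = 0),
    final_fit = NULL, fits = NULL,
    config = reweight_config(), gene_ids = gene_ids),
    class = "reweight_trajectory")
}

test_that("entropy trace equals closed forms at uniform and truth", {
  n <- 8
  truth <- seq_len(n) <= 4
  W <- rbind(rep(1 / n, n),
             as.numeric(indicator_weights(truth, n)))
  tr <- entropy_trace(make_toy_traj(W), truth)
  expect_equal(tr$entropy_to_truth[1], log(n / 4))  # ln(n/|S|) = ln 2
  expect_equal(tr$entropy_to_truth[2], 0)
  # zero weight on a truth gene is flagged as Inf
  W3 <- rbind(rep(1 / n, n), c(0, rep(1 / (n - 1), n - 1)))
  expect_equal(entropy_trace(make_toy_traj(W3), truth)$entropy_to_truth[2], Inf)
})

test_that("AUC matches hand cases and the pair-counting oracle", {
  expect_equal(auc_informative(c(0.4, 0.3, 0.2, 0.1), c(TRUE, FALSE, TRUE, FALSE)),
               0.75)
  expect_equal(auc_informative(c(3, 2, 1), c(TRUE, TRUE, FALSE)), 1)
  expect_equal(auc_informative(c(1, 2, 3), c(TRUE, TRUE, FALSE)), 0)
  expect_error(auc_informative(1:3, c(TRUE, TRUE, TRUE)), "single class")

  set.seed(17)
  for (rep in 1:40) {
    n <- sample(3:12, 1)
    scores <- sample(seq(0.1, 1, 0.1), n, replace = TRUE)  # force ties
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(truth) || all(truth)) next
    expect_equal(auc_informative(scores, truth),
                 oracle_auc_pairs(scores, truth))
  }
})

test_that("tpr_fpr counts the confusion table", {
  expect_equal(as.numeric(tpr_fpr(c(T, F, T, F), c(T, F, T, F))), c(1, 0))
  expect_equal(as.numeric(tpr_fpr(rep(TRUE, 4), c(T, F, T, F))), c(1, 1))
  expect_equal(as.numeric(tpr_fpr(c(T, T, F, F), c(T, F, T, F))), c(0.5, 0.5))
  expect_error(tpr_fpr(c(T, F), c(T, T)), "degenerate")
})

test_that("histogram MI hits the discrete identity and independence limits", {
  set.seed(23)
  enc <- rnorm(6400)
  X <- rbind(identical_gene = enc,
             indep_gene = rnorm(6400),
             monotone_gene = exp(2 * enc))
  out <- mutual_information_blocks(enc, X, c("same", "noise", "same"),
                                   bins = 16)
  mi <- out$per_gene$mi
  expect_equal(mi[1], log(16), tolerance = 0.05 * log(16))
  expect_lt(mi[2], 0.05)
  # invariant under strictly monotone transform of the gene
  expect_equal(mi[3], mi[1], tolerance = 1e-12)
  expect_true(all(mi >= 0))
  # block aggregation is the plain mean/sd
  same <- out$by_block[out$by_block$block == "same", ]
  expect_equal(same$mean_mi, mean(mi[c(1, 3)]))
  expect_equal(same$n_genes, 2L)
})

test_that("profile correlations match closed-form Pearson", {
  rec <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(5, 5, 5))
  ref <- rbind(a = c(1, 2, 3), b = c(-1, -2, -3), c = c(1, 2, 3))
  r <- pearson_profiles(rec, ref)$r
  expect_equal(r[1], 1)
  expect_equal(r[2], -1)
  expect_true(is.na(r[3]))
  expect_equal(pearson_profiles(rbind(c(1, 2, 3)), rbind(c(2, 4, 6.1)))$r,
               cor(c(1, 2, 3), c(2, 4, 6.1)))
  expect_error(pearson_profiles(rec[, 1:2], ref[, 1:2]), "3 locations")
})

test_that("zonation labelling follows the R2-and-slope rule", {
  h <- 8
  j <- 0:(h - 1)
  # centre-symmetric sinusoid: oscillates but has no linear trend
  profiles <- rbind(line = j,
                    flat = rep(2, h),
                    sine = cos(2 * pi * (j - (h - 1) / 2) / h),
                    descending = 10 - 0.5 * j)
  lab <- label_zonated(profiles)
  expect_true(lab$zonated[lab$gene_id == "line"])
  expect_false(lab$zonated[lab$gene_id == "flat"])
  # a pure sinusoid has no linear trend: R^2 below threshold
  expect_lt(lab$r_squared[lab$gene_id == "sine"], 0.1)
  expect_false(lab$zonated[lab$gene_id == "sine"])
  expect_true(lab$zonated[lab$gene_id == "descending"])

  # reversing location order flips slope sign, never the label
  rev_lab <- label_zonated(profiles[, h:1])
  expect_equal(rev_lab$slope, -lab$slope)
  expect_equal(rev_lab$zonated, lab$zonated)
})

test_that("evaluate_trajectory bundles metrics consistently", {
  n <- 10
  truth <- seq_len(n) <= 5
  W <- rbind(rep(1 / n, n),
             c(rep(0.15, 5), rep(0.05, 5)))
  traj <- make_toy_traj(W)
  rep_ <- evaluate_trajectory(traj, truth, delta = 0.2)
  expect_equal(rep_$auc, 1)
  expect_equal(rep_$rates$tpr, 1)
  expect_equal(rep_$rates$fpr, 0)
  expect_equal(rep_$entropy$entropy_to_truth[1], log(2))
  expect_equal(nrow(rep_$labels), n)
})
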