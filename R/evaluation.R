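# Evaluation: relative-entropy traces against the ground-truth gene set,
# threshold classification rates, rank AUC, histogram mutual information,
# mean-profile correlation, and the linear-fit zonation labeller.

#' Relative-entropy trace against the true informative set
#'
#' For every recorded round `t`, computes \eqn{D(\chi_S, p_t)} — the
#' divergence of the uniform distribution on the true informative gene set
#' `S` from the learned weights. A decreasing trace indicates the weights are
#' concentrating on the right genes; at round 0 it equals `ln(n/|S|)`
#' exactly. Rounds where some gene of `S` carries zero weight are recorded as
#' `Inf` (the weight floor of the update makes this unreachable after round
#' 0 unless `S` is mislabelled).
#'
#' @param traj A `reweight_trajectory`.
#' @param truth_mask Logical vector (length `n`) marking the true set `S`.
#' @return Tibble with columns `round` and `entropy_to_truth`.
#' @export
entropy_trace <- function(traj, truth_mask) {
  truth_mask <- as.logical(truth_mask)
  n <- length(traj$gene_ids)
  stopifnot(length(truth_mask) == n)
  if (!any(truth_mask)) stop("truth_mask must be nonempty", call. = FALSE)
  chi <- indicator_weights(truth_mask, n)
  vals <- apply(traj$weights, 1L, function(p) {
    if (any(p[truth_mask] <= 0)) return(Inf)
    relative_entropy(chi, p)
  })
  tibble::tibble(round = traj$summary$round, entropy_to_truth = vals)
}

#' Rank AUC of gene weights for predicting the informative set
#'
#' The probability that a uniformly chosen true-informative gene outranks a
#' uniformly chosen uninformative one under the weight score, ties counted
#' half (midranks).
#'
#' @param p_final Gene weights (or any numeric score vector).
#' @param truth_mask Logical truth labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc_informative <- function(p_final, truth_mask) {
  s <- as.numeric(p_final)
  y <- as.logical(truth_mask)
  stopifnot(length(s) == length(y))
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L) {
    stop("undefined-metric: truth labels contain a single class", call. = FALSE)
  }
  r <- rank(s, ties.method = "average")
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' True- and false-positive rate of a gene classification
#'
#' @param mask_pred,mask_true Logical vectors of equal length; `mask_true`
#'   must contain at least one positive and one negative.
#' @return Tibble with columns `tpr` and `fpr`.
#' @export
tpr_fpr <- function(mask_pred, mask_true) {
  p <- as.logical(mask_pred); y <- as.logical(mask_true)
  stopifnot(length(p) == length(y))
  if (!any(y) || all(y)) {
    stop("undefined-metric: degenerate truth labels", call. = FALSE)
  }
  tibble::tibble(tpr = sum(p & y) / sum(y), fpr = sum(p & !y) / sum(!y))
}

# Equal-frequency bin ids (rank-based, so invariant to strictly monotone
# transforms).
equal_freq_bins <- function(x, bins) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * bins / length(x)))
}

# Plug-in histogram MI (nats) between two numeric vectors.
histogram_mi <- function(x, y, bins) {
  bx <- equal_freq_bins(x, bins)
  by <- equal_freq_bins(y, bins)
  joint <- table(bx, by) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
}

#' Mutual information between the cell encoding and each gene, by truth block
#'
#' Estimates, per gene, the plug-in histogram mutual information (natural
#' log, equal-frequency bins on both marginals) between the first coordinate
#' of the cell encoding and that gene's expression across cells, then
#' aggregates mean and standard deviation within each truth block. High MI
#' for a block means the encoding captured that block's manifold.
#'
#' @param encoding k-by-cells code matrix (first row used) or numeric vector.
#' @param X `expression_matrix` or genes-by-cells matrix.
#' @param blocks Character/factor of per-gene block labels (or logical mask;
#'   `TRUE`/`FALSE` become blocks).
#' @param bins Number of bins per marginal (default 16).
#' @return List with `per_gene` (tibble: gene_id, block, mi) and `by_block`
#'   (tibble: block, mean_mi, sd_mi, n_genes).
#' @export
mutual_information_blocks <- function(encoding, X, blocks, bins = 16L) {
  stopifnot(bins >= 2)
  Xv <- if (inherits(X, "expression_matrix")) X$values else as.matrix(X)
  enc <- if (is.matrix(encoding)) encoding[1L, ] else as.numeric(encoding)
  stopifnot(length(enc) == ncol(Xv))
  blocks <- as.character(blocks)
  stopifnot(length(blocks) == nrow(Xv))
  if (stats::sd(enc) == 0) {
    warning("constant encoding: all MI values are 0", call. = FALSE)
  }
  mi <- vapply(seq_len(nrow(Xv)), function(g) histogram_mi(enc, Xv[g, ], bins),
               numeric(1))
  per_gene <- tibble::tibble(
    gene_id = rownames(Xv) %||% paste0("gene_", seq_len(nrow(Xv))),
    block = blocks, mi = mi)
  by_block <- per_gene |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(mean_mi = mean(.data$mi), sd_mi = stats::sd(.data$mi),
                     n_genes = dplyr::n(), .groups = "drop")
  list(per_gene = per_gene, by_block = by_block)
}

#' Per-gene Pearson correlation between mean-profile matrices
#'
#' Correlates each gene's reconstructed location profile with its reference
#' profile across locations; the standard summary of reconstruction quality
#' for spatially resolved tissues. Genes with a zero-variance profile on
#' either side get `NA`.
#'
#' @param reconstructed,reference Genes-by-locations matrices of equal shape
#'   with at least 3 locations.
#' @return Tibble with columns `gene_id` and `r`.
#' @export
pearson_profiles <- function(reconstructed, reference) {
  A <- as.matrix(reconstructed); B <- as.matrix(reference)
  if (!all(dim(A) == dim(B))) stop("shape mismatch", call. = FALSE)
  if (ncol(A) < 3L) stop("need at least 3 locations", call. = FALSE)
  r <- vapply(seq_len(nrow(A)), function(g) {
    if (stats::sd(A[g, ]) == 0 || stats::sd(B[g, ]) == 0) return(NA_real_)
    stats::cor(A[g, ], B[g, ])
  }, numeric(1))
  tibble::tibble(gene_id = rownames(A) %||% paste0("gene_", seq_len(nrow(A))),
                 r = r)
}

#' Label zonated genes from mean expression profiles
#'
#' Ordinary least squares of each gene's location profile against the integer
#' location grid `0..h-1`; a gene is labelled zonated (spatially informative)
#' when the fit explains enough variance (`R^2 > r2_min`) and the trend is
#' non-negligible (`|slope| > slope_min`). Reversing the location order flips
#' the slope sign but never the label.
#'
#' @param profiles Genes-by-locations matrix (>= 3 locations).
#' @param r2_min Coefficient-of-determination threshold (default 0.1).
#' @param slope_min Absolute-slope threshold (default 0.001).
#' @return Tibble with `gene_id`, `slope`, `r_squared`, `zonated`.
#' @export
label_zonated <- function(profiles, r2_min = 0.1, slope_min = 0.001) {
  P <- as.matrix(profiles)
  h <- ncol(P)
  if (h < 3L) stop("need at least 3 locations", call. = FALSE)
  s <- 0:(h - 1)
  sc <- s - mean(s)
  ssx <- sum(sc^2)
  res <- t(apply(P, 1L, function(y) {
    slope <- sum(sc * (y - mean(y))) / ssx
    fitted <- mean(y) + slope * sc
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst == 0) 0 else 1 - sum((y - fitted)^2) / sst
    c(slope = slope, r_squared = r2)
  }))
  tibble::tibble(
    gene_id = rownames(P) %||% paste0("gene_", seq_len(nrow(P))),
    slope = res[, "slope"], r_squared = res[, "r_squared"],
    zonated = res[, "r_squared"] > r2_min & abs(res[, "slope"]) > slope_min)
}

#' Evaluate a reweighting trajectory against ground truth
#'
#' Bundles the per-round relative-entropy trace, the final-weight AUC, and
#' the threshold-classification TPR/FPR into one report.
#'
#' @param traj A `reweight_trajectory`.
#' @param truth_mask Logical ground-truth informative mask.
#' @param delta Classification slack (default from the trajectory's config).
#' @return List of class `evaluation_report` with `entropy` (tibble), `auc`,
#'   `rates` (tibble tpr/fpr), `labels` (tibble gene_id, weight, informative,
#'   truth).
#' @export
evaluate_trajectory <- function(traj, truth_mask, delta = NULL) {
  delta <- delta %||% traj$config$delta
  truth_mask <- as.logical(truth_mask)
  p_final <- final_weights(traj)
  pred <- classify_genes(p_final, delta)
  structure(list(
    entropy = entropy_trace(traj, truth_mask),
    auc = auc_informative(p_final, truth_mask),
    rates = tpr_fpr(pred, truth_mask),
    labels = tibble::tibble(gene_id = traj$gene_ids,
                            weight = as.numeric(p_final),
                            informative = unname(pred),
                            truth = truth_mask),
    delta = delta),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  e <- x$entropy
  cat("<evaluation_report>\n")
  cat(sprintf("  D(chi_S, p_t): %.4g (round 0) -> %.4g (round %d)\n",
              e$entropy_to_truth[1], e$entropy_to_truth[nrow(e)],
              max(e$round)))
  cat(sprintf("  AUC = %.3f, TPR = %.3f, FPR = %.3f (delta = %g)\n",
              x$auc, x$rates$tpr, x$rates$fpr, x$delta))
  invisible(x)
}
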