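# Reconstruction-error functionals and their per-gene gradients. The weighted
# MSE loss is linear in the gene weights, l(p) = <m, p>, so the per-gene error
# vector m doubles as the exact gradient driving the multiplicative update.

#' Per-gene mean squared reconstruction error
#'
#' Entry `g` is the mean over cells of the squared residual of gene `g`,
#' \eqn{m[g] = (1/N) \sum_j (X[g,j] - Y[g,j])^2}. This vector is the gradient
#' of the weighted MSE loss with respect to the gene weights.
#'
#' @param X Observed matrix (`expression_matrix` or genes-by-cells matrix).
#' @param Y Reconstruction, same shape.
#' @return Nonnegative numeric vector of length `n_genes`.
#' @export
per_gene_mse <- function(X, Y) {
  Xv <- if (inherits(X, "expression_matrix")) X$values else as.matrix(X)
  Yv <- if (inherits(Y, "expression_matrix")) Y$values else as.matrix(Y)
  if (!all(dim(Xv) == dim(Yv))) stop("X and Y shapes differ", call. = FALSE)
  m <- rowMeans((Xv - Yv)^2)
  names(m) <- rownames(Xv)
  m
}

#' Weighted mean squared reconstruction loss
#'
#' \eqn{l(p, X, Y) = (1/N) \sum_i p[i] \sum_j (X[i,j] - Y[i,j])^2}, identically
#' equal to the inner product of [per_gene_mse()] with the weight vector.
#'
#' @param p Gene weights.
#' @param X,Y Observed and reconstructed matrices, same shape.
#' @return Nonnegative scalar.
#' @export
weighted_mse <- function(p, X, Y) {
  m <- per_gene_mse(X, Y)
  pv <- as.numeric(p)
  if (length(pv) != length(m)) stop("p length != gene count", call. = FALSE)
  sum(m * pv)
}

#' Spatial variance loss for location-distribution baselines
#'
#' For a baseline that outputs per-location cell distributions
#' \eqn{\mu_1, \dots, \mu_h} (rows of `mu`), the per-gene penalty interpolates
#' two terms: the average within-location variance of the gene's expression
#' under each \eqn{\mu_j} (low when cells mapped to the same location agree),
#' and the empirical variance of the increments of location-mean expression
#' (low when the mean profile changes smoothly along the 1-D axis):
#' \deqn{m[i] = (1-\lambda)\frac{1}{h}\sum_j Var_{\mu_j}(X[i]) +
#'       \lambda\, Var_j(E_{\mu_j}[X[i]] - E_{\mu_{j-1}}[X[i]]).}
#' The loss is \eqn{\sum_i p[i]\, m[i]}.
#'
#' @param p Gene weights.
#' @param X Expression (`expression_matrix` or matrix).
#' @param mu h-by-N matrix; each row a distribution over cells (sums to 1).
#' @param lambda_smooth Interpolation \eqn{\lambda \in [0,1]}.
#' @param variance_agg Aggregate within-location variances by their `"mean"`
#'   (default, scale-free in `h`) or `"sum"` over locations.
#' @return List with `loss` (scalar) and `gradient` (per-gene vector `m`).
#' @export
spatial_variance_loss <- function(p, X, mu, lambda_smooth = 0,
                                  variance_agg = c("mean", "sum")) {
  variance_agg <- match.arg(variance_agg)
  Xv <- if (inherits(X, "expression_matrix")) X$values else as.matrix(X)
  mu <- as.matrix(mu)
  h <- nrow(mu)
  if (ncol(mu) != ncol(Xv)) stop("mu columns != cell count", call. = FALSE)
  if (any(abs(rowSums(mu) - 1) > 1e-9) || any(mu < -1e-12)) {
    stop("mu rows must be distributions over cells", call. = FALSE)
  }
  if (lambda_smooth < 0 || lambda_smooth > 1) {
    stop("lambda_smooth must lie in [0, 1]", call. = FALSE)
  }
  if (h < 2 && lambda_smooth > 0) {
    stop("smoothness term needs h >= 2 locations", call. = FALSE)
  }
  # location means E_{mu_j}[X[i]]: n x h
  means <- Xv %*% t(mu)
  # within-location variance under probability weights mu_j
  ex2 <- (Xv^2) %*% t(mu)
  within <- pmax(ex2 - means^2, 0)                     # n x h
  within_term <- if (variance_agg == "mean") rowMeans(within) else rowSums(within)
  m <- (1 - lambda_smooth) * within_term
  if (lambda_smooth > 0) {
    incr <- means[, -1L, drop = FALSE] - means[, -h, drop = FALSE]  # n x (h-1)
    inc_var <- apply(incr, 1L, function(v) mean((v - mean(v))^2))
    m <- m + lambda_smooth * inc_var
  }
  names(m) <- rownames(Xv)
  pv <- as.numeric(p)
  if (length(pv) != length(m)) stop("p length != gene count", call. = FALSE)
  list(loss = sum(pv * m), gradient = m)
}

#' Mean expression profile per location
#'
#' Entry `(i, j)` is \eqn{E_{\mu_j}[X[i]] = \sum_c \mu_j(c) X[i, c]}, the
#' expected expression of gene `i` at location `j` under the cell
#' distribution of that location.
#'
#' @param mu h-by-N location-distribution matrix (rows sum to 1).
#' @param X Expression (`expression_matrix` or matrix).
#' @return Genes-by-locations numeric matrix.
#' @export
location_mean_profiles <- function(mu, X) {
  Xv <- if (inherits(X, "expression_matrix")) X$values else as.matrix(X)
  mu <- as.matrix(mu)
  if (ncol(mu) != ncol(Xv)) stop("mu columns != cell count", call. = FALSE)
  P <- Xv %*% t(mu)
  rownames(P) <- rownames(Xv)
  colnames(P) <- paste0("loc_", seq_len(nrow(mu)))
  P
}
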