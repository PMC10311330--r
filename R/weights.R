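# Weight distributions over genes: construction, relative entropy, the
# multiplicative weights update (MWU) step, and KL projection onto the capped
# simplex. All logarithms are natural.

#' Construct a gene weight distribution
#'
#' A `gene_weights` object is a probability vector over `n` genes, optionally
#' constrained to the capped simplex (no entry above `cap`). It is the state
#' the iterative reweighting algorithm updates each round.
#'
#' @param weights Numeric vector of nonnegative weights summing to 1.
#' @param cap Either `NULL` (no cap) or a real in (0, 1] bounding every entry.
#'   Feasibility requires `cap * length(weights) >= 1`.
#' @param gene_ids Optional character vector of gene identifiers.
#' @return A numeric vector of class `gene_weights` with attributes `cap` and
#'   (optionally) `gene_ids`.
#' @export
gene_weights <- function(weights, cap = NULL, gene_ids = NULL) {
  weights <- as.numeric(weights)
  n <- length(weights)
  if (n < 1L) stop("weights must have length >= 1", call. = FALSE)
  if (anyNA(weights) || any(!is.finite(weights))) {
    stop("weights must be finite", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("weights must sum to 1 (within 1e-9); got ", format(sum(weights)),
         call. = FALSE)
  }
  if (!is.null(cap)) {
    stopifnot(is.numeric(cap), length(cap) == 1L)
    if (cap <= 0 || cap > 1) stop("cap must lie in (0, 1]", call. = FALSE)
    if (cap * n < 1 - 1e-12) {
      stop("infeasible cap: cap * n = ", format(cap * n), " < 1", call. = FALSE)
    }
    if (any(weights > cap + 1e-12)) {
      stop("weight exceeds cap ", format(cap), call. = FALSE)
    }
  }
  if (!is.null(gene_ids)) {
    stopifnot(length(gene_ids) == n)
    names(weights) <- gene_ids
  }
  structure(weights, cap = cap, class = "gene_weights")
}

#' @export
print.gene_weights <- function(x, ...) {
  cap <- attr(x, "cap")
  cat(sprintf("<gene_weights> n = %d, cap = %s, max = %.4g, min = %.4g\n",
              length(x), if (is.null(cap)) "none" else format(cap),
              max(x), min(x)))
  invisible(x)
}

#' Uniform distribution over n genes
#'
#' The starting point of the reweighting loop: every gene gets weight `1/n`.
#'
#' @param n Gene count (positive integer).
#' @param gene_ids Optional gene identifiers.
#' @return A `gene_weights` vector with all entries `1/n` and no cap.
#' @export
uniform_weights <- function(n, gene_ids = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("n must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  gene_weights(rep(1 / n, n), gene_ids = gene_ids)
}

#' Uniform distribution over a gene subset
#'
#' The indicator distribution \eqn{\chi_S}: weight `1/|S|` on every gene in
#' `S`, zero elsewhere. Used as the ground-truth reference when evaluating how
#' well learned weights concentrate on the informative set.
#'
#' @param S Integer indices (in `1..n`) or a logical mask of length `n`.
#' @param n Gene count.
#' @return A `gene_weights` vector supported on `S`.
#' @export
indicator_weights <- function(S, n) {
  n <- as.integer(n)
  if (is.logical(S)) {
    stopifnot(length(S) == n)
    S <- which(S)
  }
  S <- unique(as.integer(S))
  if (length(S) == 0L) stop("S must be nonempty", call. = FALSE)
  if (any(S < 1L | S > n)) stop("S out of range 1..n", call. = FALSE)
  w <- numeric(n)
  w[S] <- 1 / length(S)
  gene_weights(w)
}

#' Relative entropy (Kullback-Leibler divergence) between two weight vectors
#'
#' \eqn{D(p, q) = \sum_i p_i \log(p_i / q_i)} with natural logarithm and the
#' convention \eqn{0 \log(0/q) = 0}. Requires `q > 0` wherever `p > 0`.
#'
#' @param p,q Probability vectors of equal length (`gene_weights` or plain
#'   numeric summing to 1).
#' @return Nonnegative scalar divergence in nats; `Inf` never occurs because a
#'   support violation is an error.
#' @export
relative_entropy <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q)) stop("p and q must have equal length", call. = FALSE)
  on_p <- p > 0
  if (any(q[on_p] <= 0)) {
    stop("support violation: q is zero where p is positive", call. = FALSE)
  }
  # clamp tiny negatives from floating point, the sum is >= 0 analytically
  max(sum(p[on_p] * log(p[on_p] / q[on_p])), 0)
}

#' One multiplicative weights update step
#'
#' Computes \eqn{p'[g] \propto p[g] \exp(-\eta m[g])}, the closed-form
#' minimizer of the linearized loss plus relative-entropy proximity term
#' \eqn{\eta m^T q + D(q, p)} over the simplex. Genes with lower per-gene
#' reconstruction error `m` gain relative weight.
#'
#' @param p Current weights (`gene_weights` or numeric simplex vector).
#' @param m Nonnegative per-gene loss gradient, same length as `p`.
#' @param eta Nonnegative step size.
#' @return A `gene_weights` vector (cap attribute not applied; project with
#'   [project_capped()] afterwards).
#' @export
mwu_step <- function(p, m, eta) {
  pv <- as.numeric(p); m <- as.numeric(m)
  if (length(pv) != length(m)) stop("p and m must have equal length", call. = FALSE)
  if (!is.numeric(eta) || length(eta) != 1L || is.na(eta) || eta < 0) {
    stop("eta must be a nonnegative scalar", call. = FALSE)
  }
  if (any(m < 0)) stop("gradient entries must be nonnegative", call. = FALSE)
  if (all(pv <= 0)) stop("p must have positive mass", call. = FALSE)
  # subtract min(m) before exponentiating: invariant to the update (cancels in
  # the normalization) and avoids underflow for large eta * m
  w <- pv * exp(-eta * (m - min(m)))
  w <- pmax(w, 1e-300)
  gene_weights(w / sum(w), gene_ids = names(pv))
}

#' KL projection onto the capped simplex
#'
#' Projects a probability vector onto \eqn{\Pi_n^c}, the set of distributions
#' with no entry above `cap`, in the relative-entropy sense: entries above the
#' cap are clipped to it and the remaining entries rescaled pro rata to absorb
#' the freed mass. The cap-and-rescale pass is iterated to a fixed point,
#' because rescaling can push a previously feasible entry over the cap; the
#' fixed point is the exact KL projection.
#'
#' @param p Probability vector (`gene_weights` or numeric).
#' @param cap Per-entry bound; needs `cap * length(p) >= 1`.
#' @return A `gene_weights` vector in the capped simplex, with `cap` recorded.
#' @export
project_capped <- function(p, cap) {
  pv <- as.numeric(p)
  n <- length(pv)
  if (!is.numeric(cap) || length(cap) != 1L || is.na(cap) || cap <= 0) {
    stop("cap must be a positive scalar", call. = FALSE)
  }
  if (cap * n < 1 - 1e-12) {
    stop("infeasible cap: cap * n = ", format(cap * n), " < 1", call. = FALSE)
  }
  capped <- rep(FALSE, n)
  for (iter in seq_len(n + 1L)) {
    over <- !capped & pv > cap + 1e-15
    if (!any(over)) break
    capped <- capped | over
    pv[capped] <- cap
    free <- !capped
    free_mass <- 1 - cap * sum(capped)
    if (any(free)) {
      s <- sum(pv[free])
      if (s > 0) {
        pv[free] <- pv[free] * (free_mass / s)
      } else {
        pv[free] <- free_mass / sum(free)
      }
    }
  }
  pv <- pmin(pv, cap)
  pv <- pv / sum(pv)
  gene_weights(pv, cap = min(cap, 1), gene_ids = names(p))
}

#' Threshold gene weights into an informative-gene mask
#'
#' A gene is labelled informative when its final weight strictly exceeds
#' \eqn{(1 - \delta)/n}, i.e. it has retained at least (almost) its initial
#' uniform share after the reweighting rounds. `delta` absorbs round-to-round
#' jitter; genes exactly at the threshold are not informative.
#'
#' @param p Final weights.
#' @param delta Slack in (0, 1); default 0.2.
#' @return Logical mask, `TRUE` for informative genes.
#' @export
classify_genes <- function(p, delta = 0.2) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta >= 1) {
    stop("delta must lie in (0, 1)", call. = FALSE)
  }
  pv <- as.numeric(p)
  mask <- pv > (1 - delta) / length(pv)
  names(mask) <- names(pv)
  mask
}

#' Reweighting configuration
#'
#' Bundles the hyperparameters of the iterative reweighting loop.
#'
#' @param eta Positive MWU step size; gradients are max-normalized before the
#'   update (see `gradient_scale` in the losses), so `eta` is scale-free.
#' @param epsilon Cap parameter in (0, 1]; the per-gene weight cap is
#'   `1/(epsilon * s_size)`.
#' @param s_size Assumed size of the informative gene set; `NULL` means `n/2`
#'   at run time.
#' @param max_rounds Number of weight-update rounds (default 10).
#' @param loss_improvement_tol Early-stop when the per-round loss improvement
#'   falls below this value; `0` (default) disables the criterion.
#' @param entropy_tol Early-stop when `D(p_t, u_n)` exceeds this value
#'   (weights have concentrated); `Inf` (default) disables it.
#' @param seed Integer master seed for all stochastic components.
#' @param gradient_scale `"reweighted"` (per-gene errors measured on the
#'   reweighted matrix the baseline actually saw) or `"original"` (residuals
#'   rescaled back to the original expression scale).
#' @param lambda_smooth Interpolation in `[0,1]` between the within-location
#'   variance penalty and the smoothness (increment-variance) penalty of the
#'   spatial variance loss.
#' @param delta Classification slack for [classify_genes()].
#' @return A list of class `reweight_config`.
#' @export
reweight_config <- function(eta = 1.0, epsilon = 0.5, s_size = NULL,
                            max_rounds = 10L, loss_improvement_tol = 0,
                            entropy_tol = Inf, seed = 1L,
                            gradient_scale = c("reweighted", "original"),
                            lambda_smooth = 0, delta = 0.2) {
  gradient_scale <- match.arg(gradient_scale)
  stopifnot(eta > 0, epsilon > 0, epsilon <= 1, max_rounds >= 0,
            loss_improvement_tol >= 0, entropy_tol >= 0,
            lambda_smooth >= 0, lambda_smooth <= 1, delta > 0, delta < 1)
  if (!is.null(s_size)) stopifnot(s_size >= 1)
  structure(
    list(eta = eta, epsilon = epsilon, s_size = s_size,
         max_rounds = as.integer(max_rounds),
         loss_improvement_tol = loss_improvement_tol,
         entropy_tol = entropy_tol, seed = as.integer(seed),
         gradient_scale = gradient_scale, lambda_smooth = lambda_smooth,
         delta = delta),
    class = "reweight_config")
}

#' @export
print.reweight_config <- function(x, ...) {
  cat("<reweight_config>\n")
  cat(sprintf("  eta = %g, epsilon = %g, s_size = %s, max_rounds = %d\n",
              x$eta, x$epsilon,
              if (is.null(x$s_size)) "auto (n/2)" else x$s_size, x$max_rounds))
  cat(sprintf("  gradient_scale = %s, lambda_smooth = %g, delta = %g, seed = %d\n",
              x$gradient_scale, x$lambda_smooth, x$delta, x$seed))
  invisible(x)
}

# Resolve the per-gene weight cap 1/(epsilon * |S|) for n genes.
resolve_cap <- function(cfg, n) {
  s <- if (is.null(cfg$s_size)) max(1L, floor(n / 2)) else cfg$s_size
  cap <- 1 / (cfg$epsilon * s)
  if (cap * n < 1) {
    stop("infeasible cap 1/(epsilon*|S|): cap * n < 1", call. = FALSE)
  }
  min(cap, 1)
}
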