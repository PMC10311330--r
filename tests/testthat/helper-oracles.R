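# Independent numeric oracles used by the unit tests. These deliberately take
# slow, generic routes (generic optimizers, pair enumeration) so they cannot
# share a code path with the implementation they check.

# Symmetric Dirichlet draw (normalized exponentials), for random simplex
# points without extra dependencies.
rand_simplex <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}

# Numeric minimizer of eta * m' q + D(q, p) over the simplex, via unconstrained
# optimization in softmax coordinates.
oracle_mwu <- function(p, m, eta) {
  n <- length(p)
  obj <- function(z) {
    q <- exp(z - max(z)); q <- q / sum(q)
    keep <- q > 0
    eta * sum(m * q) + sum(q[keep] * log(q[keep] / p[keep]))
  }
  fit <- stats::optim(rep(0, n), obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  q <- exp(fit$par - max(fit$par))
  q / sum(q)
}

# KL projection of p onto the capped simplex via the KKT characterization:
# q_i = min(cap, lambda * p_i) with the scalar lambda found by bisection so
# the entries sum to 1. Independent of the iterated cap-and-rescale route.
oracle_capped_projection <- function(p, cap) {
  total <- function(lambda) sum(pmin(cap, lambda * p))
  lo <- 1; hi <- 1 / min(p[p > 0]) * cap + 1
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (total(mid) < 1) lo <- mid else hi <- mid
  }
  q <- pmin(cap, ((lo + hi) / 2) * p)
  q / sum(q)
}

# AUC by brute-force enumeration of positive-negative pairs, ties count half.
oracle_auc_pairs <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  wins <- 0
  for (a in pos) for (b in neg) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  wins / (length(pos) * length(neg))
}

# Tiny deterministic two-cluster expression fixture: genes respond to cluster
# identity, used by the OT baseline tests.
two_cluster_matrix <- function(n_genes = 6, per_cluster = 20, gap = 6,
                               seed = 1) {
  set.seed(seed)
  lab <- rep(c(0, 1), each = per_cluster)
  vals <- t(vapply(seq_len(n_genes), function(g) {
    gap * lab * sample(c(-1, 1), 1) + rnorm(length(lab), sd = 0.1)
  }, numeric(length(lab))))
  list(X = expression_matrix(vals), labels = lab)
}
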