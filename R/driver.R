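# The alternate-minimization loop: fit baseline on reweighted data, measure
# per-gene reconstruction error, multiplicative weight update, project onto
# the capped simplex, repeat.

#' Run the iterative gene-reweighting loop
#'
#' Starting from uniform weights, each round `t` the baseline is refit from
#' scratch on the reweighted matrix `diag(n p_t) X` (weights are applied
#' relative to uniform so round 0 sees the original standardized data), the
#' per-gene reconstruction error `m_t` is computed by the selected loss,
#' recorded together with the round loss `<m_t, p_t>`, and the weights are
#' updated by [mwu_step()] (with `m_t` normalized by its maximum so `eta` is
#' scale-free) and projected by [project_capped()] onto the capped simplex
#' with cap `1/(epsilon * |S|)`. A baseline fit is also performed at the
#' final weights, so the trajectory carries `max_rounds + 1` loss values.
#'
#' @param X `expression_matrix` (standardized; a non-standardized matrix is
#'   z-scored first with a message) or plain genes-by-cells matrix.
#' @param baseline `"ae"`, `"ot"`, a function `(Xw_matrix, seed) ->
#'   baseline_fit`, or a callable to wrap with [adapter_external()] via
#'   `baseline = list(external = fn)`.
#' @param loss `"mse"` (weighted per-gene MSE; default) or
#'   `"spatial_variance"` (requires a location-distribution baseline).
#' @param config A [reweight_config()].
#' @param baseline_spec Optional [autoencoder_spec()] / [ot_spatial_spec()]
#'   overriding the defaults (its seed field is ignored; per-round seeds are
#'   derived from `config$seed`).
#' @param keep_fits Keep every round's `baseline_fit` in the result (memory
#'   heavy); default keeps only the final fit.
#' @return A `reweight_trajectory`: list with `weights` (rounds+1 x n matrix),
#'   `gradients` (rounds+1 x n), `summary` tibble (round, loss,
#'   entropy_to_uniform), `final_fit`, `config`, `gene_ids`.
#' @export
run_reweighting <- function(X, baseline = "ae", loss = c("mse", "spatial_variance"),
                            config = reweight_config(), baseline_spec = NULL,
                            keep_fits = FALSE) {
  loss <- match.arg(loss)
  X <- as_expression_matrix(X, standardized = inherits(X, "expression_matrix"))
  if (!X$standardized) {
    message("input not flagged standardized; z-scoring gene rows")
    X <- standardize(X)
  }
  n <- n_genes(X)
  cap <- resolve_cap(config, n)
  fit_fun <- make_baseline_factory(baseline, baseline_spec, config)

  p <- uniform_weights(n, gene_ids = X$gene_ids)
  rounds <- config$max_rounds
  W <- matrix(NA_real_, rounds + 1L, n, dimnames = list(NULL, X$gene_ids))
  G <- matrix(NA_real_, rounds + 1L, n, dimnames = list(NULL, X$gene_ids))
  losses <- numeric(rounds + 1L)
  entropies <- numeric(rounds + 1L)
  fits <- if (keep_fits) vector("list", rounds + 1L) else NULL
  fit <- NULL

  for (t in 0:rounds) {
    W[t + 1L, ] <- as.numeric(p)
    Xw <- X$values * (n * as.numeric(p))   # diag(n p) X, row scaling
    fit <- tryCatch(fit_fun(Xw, round = t),
                    error = function(e) {
                      stop("baseline fit failed at round ", t, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    grad <- round_gradient(fit, X, Xw, p, loss, config)
    G[t + 1L, ] <- grad
    losses[t + 1L] <- sum(grad * as.numeric(p))
    entropies[t + 1L] <- relative_entropy(p, uniform_weights(n))
    if (keep_fits) fits[[t + 1L]] <- fit

    partial <- make_trajectory(W, G, losses, entropies, t, X$gene_ids, config,
                               fit, fits)
    if (t == rounds || check_termination(partial, config)) break

    m_scaled <- if (max(grad) > 0) grad / max(grad) else grad
    p <- project_capped(mwu_step(p, m_scaled, config$eta), cap)
  }
  make_trajectory(W, G, losses, entropies, t, X$gene_ids, config, fit, fits)
}

# Per-gene gradient for the configured loss at this round.
round_gradient <- function(fit, X, Xw, p, loss, config) {
  if (loss == "spatial_variance") {
    if (fit$kind != "location_distribution") {
      stop("spatial_variance loss needs a location-distribution baseline",
           call. = FALSE)
    }
    return(spatial_variance_loss(p, Xw, fit$mu, config$lambda_smooth)$gradient)
  }
  if (config$gradient_scale == "reweighted") {
    per_gene_mse(Xw, fit$reconstruction)
  } else {
    scale <- n_genes(X) * pmax(as.numeric(p), 1e-300)
    per_gene_mse(Xw / scale, fit$reconstruction / scale)
  }
}

make_baseline_factory <- function(baseline, baseline_spec, config) {
  if (is.function(baseline)) {
    return(function(Xw, round) baseline(Xw, seed = config$seed + round))
  }
  if (is.list(baseline) && !is.null(baseline$external)) {
    fn <- baseline$external
    return(function(Xw, round) adapter_external(fn, Xw))
  }
  baseline <- match.arg(baseline, c("ae", "ot"))
  if (baseline == "ae") {
    spec <- if (is.null(baseline_spec)) autoencoder_spec() else baseline_spec
    function(Xw, round) {
      spec$seed <- config$seed + 1000L * round
      fit_autoencoder(Xw, spec)
    }
  } else {
    spec <- if (is.null(baseline_spec)) ot_spatial_spec() else baseline_spec
    function(Xw, round) {
      spec$seed <- config$seed + 1000L * round
      fit_ot_spatial(Xw, spec)
    }
  }
}

make_trajectory <- function(W, G, losses, entropies, t_last, gene_ids, config,
                            final_fit, fits) {
  idx <- seq_len(t_last + 1L)
  structure(list(
    weights = W[idx, , drop = FALSE],
    gradients = G[idx, , drop = FALSE],
    summary = tibble::tibble(round = idx - 1L, loss = losses[idx],
                             entropy_to_uniform = entropies[idx]),
    final_fit = final_fit,
    fits = if (!is.null(fits)) fits[idx] else NULL,
    config = config,
    gene_ids = gene_ids),
    class = "reweight_trajectory")
}

#' Termination test for the reweighting loop
#'
#' Returns `TRUE` when any configured stopping condition holds: the per-round
#' loss improvement `loss[t-1] - loss[t]` has fallen below
#' `loss_improvement_tol` (only checked when the tolerance is positive and at
#' least two rounds exist), the concentration `D(p_t, u_n)` has exceeded
#' `entropy_tol`, or `max_rounds` has been reached.
#'
#' @param traj A `reweight_trajectory` (possibly partial).
#' @param config A [reweight_config()].
#' @return Logical.
#' @export
check_termination <- function(traj, config) {
  s <- traj$summary
  t_now <- max(s$round)
  if (t_now >= config$max_rounds) return(TRUE)
  if (config$loss_improvement_tol > 0 && nrow(s) >= 2L) {
    improvement <- s$loss[nrow(s) - 1L] - s$loss[nrow(s)]
    if (improvement < config$loss_improvement_tol) return(TRUE)
  }
  if (is.finite(config$entropy_tol) &&
      s$entropy_to_uniform[nrow(s)] > config$entropy_tol) {
    return(TRUE)
  }
  FALSE
}

#' Final weights of a trajectory
#' @param traj A `reweight_trajectory`.
#' @return A `gene_weights` vector.
#' @export
final_weights <- function(traj) {
  gene_weights(traj$weights[nrow(traj$weights), ],
               gene_ids = traj$gene_ids)
}

#' @export
print.reweight_trajectory <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<reweight_trajectory> %d genes, rounds 0..%d\n",
              length(x$gene_ids), max(s$round)))
  cat(sprintf("  loss: %.4g -> %.4g; D(p_t, u_n): %.4g -> %.4g\n",
              s$loss[1], s$loss[nrow(s)],
              s$entropy_to_uniform[1], s$entropy_to_uniform[nrow(s)]))
  invisible(x)
}

#' Tidy a reweighting trajectory into a long tibble
#'
#' @param x A `reweight_trajectory`.
#' @param ... Unused.
#' @return Tibble with columns `round`, `gene_id`, `weight`, `gradient`.
#' @export
tidy.reweight_trajectory <- function(x, ...) {
  rounds <- nrow(x$weights)
  tibble::tibble(
    round = rep(0:(rounds - 1L), each = length(x$gene_ids)),
    gene_id = rep(x$gene_ids, times = rounds),
    weight = as.numeric(t(x$weights)),
    gradient = as.numeric(t(x$gradients)))
}

#' One-row summary of a reweighting trajectory
#'
#' @param x A `reweight_trajectory`.
#' @param ... Unused.
#' @return Tibble with gene count, rounds run, first/last loss and
#'   concentration, and the number of genes classified informative at the
#'   configured `delta`.
#' @export
glance.reweight_trajectory <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_genes = length(x$gene_ids),
    rounds = max(s$round),
    loss_first = s$loss[1], loss_last = s$loss[nrow(s)],
    entropy_to_uniform_last = s$entropy_to_uniform[nrow(s)],
    n_informative = sum(classify_genes(final_weights(x), x$config$delta)))
}

#' Plot a reweighting trajectory
#'
#' Draws per-gene weight paths over rounds together with the loss curve.
#'
#' @param object A `reweight_trajectory`.
#' @param truth_mask Optional logical vector colouring genes by ground-truth
#'   informativeness.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reweight_trajectory <- function(object, truth_mask = NULL, ...) {
  d <- tidy(object)
  if (!is.null(truth_mask)) {
    d$informative <- rep(truth_mask, times = nrow(object$weights))
  } else {
    d$informative <- NA
  }
  n <- length(object$gene_ids)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$round, y = .data$weight,
                                  group = .data$gene_id,
                                  colour = .data$informative)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 1 / n, linetype = "dashed") +
    ggplot2::labs(x = "round", y = "gene weight", colour = "informative") +
    ggplot2::theme_minimal()
}
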