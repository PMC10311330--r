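# Pluggable baseline reconstructors. A baseline consumes the gene-reweighted
# expression matrix and returns either an encoder/decoder pair with a
# reconstruction Y (autoencoder family) or an h x N cell-distribution matrix
# mu over a 1-D grid of locations (optimal-transport family). Both are wrapped
# in a common `baseline_fit` object the driver consumes.

#' Autoencoder hyperparameters
#'
#' A shallow feed-forward autoencoder `n -> max_width -> code_dim` with tanh
#' hidden layers, a linear code and a linear output, mirrored in the decoder,
#' trained with minibatch Adam on the mean squared reconstruction error.
#'
#' @param code_dim Bottleneck dimension `k`; set it to the (minimum) latent
#'   manifold dimension of the process being reconstructed. Default 1.
#' @param max_width Width of the hidden layers, 64-128 typical. Default 64.
#' @param epochs Training epochs, 70-100 typical. Default 70.
#' @param learning_rate Adam step size. Default 1e-3.
#' @param batch_size Minibatch size. Default 128.
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @return A list of class `autoencoder_spec`.
#' @export
autoencoder_spec <- function(code_dim = 1L, max_width = 64L, epochs = 70L,
                             learning_rate = 1e-3, batch_size = 128L,
                             seed = NULL) {
  stopifnot(code_dim >= 1, max_width >= code_dim, epochs >= 1,
            learning_rate > 0, batch_size >= 1)
  structure(list(code_dim = as.integer(code_dim),
                 max_width = as.integer(max_width),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "autoencoder_spec")
}

#' OT spatial embedder hyperparameters
#'
#' A simplified entropic Gromov-Wasserstein matcher between the cell-cell
#' expression-distance geometry and a 1-D grid of `n_locations` positions.
#' It stands in for published optimal-transport tissue-reconstruction tools
#' behind the same baseline contract.
#'
#' @param n_locations Number of grid locations `h` (>= 2). Default 8.
#' @param entropic_reg Entropic regularization of the transport plan. Default
#'   5e-3 (distance matrices are rescaled to max 1 first; larger values blur
#'   the coupling toward uniform and lose the ordering).
#' @param structure_weight Interpolation in `[0,1]` between raw Euclidean
#'   expression distances (0) and k-NN-graph geodesic distances (1, default),
#'   the structural-smoothness geometry.
#' @param n_neighbors Neighbourhood size of the k-NN graph. Default 5.
#' @param max_iter Outer Gromov-Wasserstein iterations. Default 200.
#' @param seed Integer seed for the initial transport-plan jitter that breaks
#'   the symmetric stationary point of the solver.
#' @return A list of class `ot_spatial_spec`.
#' @export
ot_spatial_spec <- function(n_locations = 8L, entropic_reg = 5e-3,
                            structure_weight = 1, n_neighbors = 5L,
                            max_iter = 200L, seed = NULL) {
  stopifnot(n_locations >= 2, entropic_reg > 0,
            structure_weight >= 0, structure_weight <= 1,
            n_neighbors >= 1, max_iter >= 1)
  structure(list(n_locations = as.integer(n_locations),
                 entropic_reg = entropic_reg,
                 structure_weight = structure_weight,
                 n_neighbors = as.integer(n_neighbors),
                 max_iter = as.integer(max_iter),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "ot_spatial_spec")
}

new_baseline_fit <- function(kind, reconstruction, code = NULL,
                             encoder = NULL, decoder = NULL, mu = NULL,
                             code_dim = NULL, train_loss = NULL) {
  kind <- match.arg(kind, c("encoder_decoder", "location_distribution"))
  if (kind == "encoder_decoder") {
    stopifnot(is.function(encoder), is.function(decoder), is.null(mu))
  } else {
    stopifnot(is.matrix(mu), is.null(encoder), is.null(decoder))
    if (any(abs(rowSums(mu) - 1) > 1e-9)) stop("mu rows must sum to 1", call. = FALSE)
  }
  structure(list(kind = kind, reconstruction = reconstruction, code = code,
                 encoder = encoder, decoder = decoder, mu = mu,
                 code_dim = code_dim, train_loss = train_loss),
            class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("<baseline_fit> kind = %s, reconstruction %d x %d\n",
              x$kind, nrow(x$reconstruction), ncol(x$reconstruction)))
  invisible(x)
}

glorot <- function(n_out, n_in) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
}

#' Fit the shallow tanh autoencoder baseline
#'
#' Trains the autoencoder described by `spec` on the (already reweighted)
#' genes-by-cells matrix `Xw` and returns a `baseline_fit` carrying the
#' encoder/decoder functions, the full-data reconstruction `Y` and the
#' `code_dim`-by-cells latent code. Training is deterministic given
#' `spec$seed`.
#'
#' @param Xw `expression_matrix` or genes-by-cells matrix (the baseline's
#'   actual input, typically `diag(n p) X`).
#' @param spec An [autoencoder_spec()].
#' @return A `baseline_fit` of kind `encoder_decoder`.
#' @export
fit_autoencoder <- function(Xw, spec = autoencoder_spec()) {
  Xv <- if (inherits(Xw, "expression_matrix")) Xw$values else as.matrix(Xw)
  if (anyNA(Xv) || any(!is.finite(Xv))) stop("non-finite input", call. = FALSE)
  n <- nrow(Xv); N <- ncol(Xv)
  k <- spec$code_dim; w <- spec$max_width
  if (k >= n) stop("code_dim must be smaller than the gene count", call. = FALSE)
  if (is.null(spec$seed)) stop("autoencoder fit requires a seed", call. = FALSE)

  set.seed(spec$seed)
  init <- list(W1 = glorot(w, n), b1 = numeric(w),
               W2 = glorot(k, w), b2 = numeric(k),
               W3 = glorot(w, k), b3 = numeric(w),
               W4 = glorot(n, w), b4 = numeric(n))
  batch_order <- vapply(seq_len(spec$epochs), function(e) sample.int(N),
                        integer(N))
  storage.mode(batch_order) <- "integer"

  fit <- .ae_train_cpp(Xv, init, batch_order, spec$batch_size,
                       spec$learning_rate)

  weights <- fit[c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")]
  for (b in c("b1", "b2", "b3", "b4")) weights[[b]] <- as.numeric(weights[[b]])
  encoder <- function(x) {
    x <- as.matrix(x)
    h1 <- tanh(weights$W1 %*% x + weights$b1)
    weights$W2 %*% h1 + weights$b2
  }
  decoder <- function(z) {
    z <- as.matrix(z)
    h2 <- tanh(weights$W3 %*% z + weights$b3)
    weights$W4 %*% h2 + weights$b4
  }
  Y <- fit$Y
  dimnames(Y) <- dimnames(Xv)
  new_baseline_fit("encoder_decoder", reconstruction = Y, code = fit$code,
                   encoder = encoder, decoder = decoder, code_dim = k,
                   train_loss = as.numeric(fit$epoch_loss))
}

# Geodesic (k-NN-graph shortest path) distances between columns of Xv,
# blended with raw Euclidean distances by structure_weight. The k-NN graph is
# augmented with the Euclidean minimum spanning tree so it is always
# connected and geodesics are well defined.
cell_distances <- function(Xv, n_neighbors, structure_weight) {
  D <- as.matrix(stats::dist(t(Xv)))
  dimnames(D) <- NULL
  if (structure_weight <= 0) return(D)
  N <- nrow(D)
  kn <- min(n_neighbors, N - 1L)
  edges <- NULL
  wts <- NULL
  for (i in seq_len(N)) {
    nb <- order(D[i, ])[2:(kn + 1L)]
    edges <- c(edges, rbind(i, nb))
    wts <- c(wts, D[i, nb])
  }
  g <- igraph::make_graph(edges, n = N, directed = FALSE)
  igraph::E(g)$weight <- wts
  full <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                              weighted = TRUE)
  g <- igraph::union(g, igraph::mst(full))
  w1 <- igraph::edge_attr(g, "weight_1")
  w2 <- igraph::edge_attr(g, "weight_2")
  igraph::E(g)$weight <- ifelse(is.na(w1), w2, w1)
  G <- igraph::distances(g)
  (1 - structure_weight) * D + structure_weight * G
}

# Entropic Gromov-Wasserstein coupling (square loss) between geometry C1
# (N x N) and C2 (h x h) with uniform marginals; projected-gradient scheme
# with Sinkhorn inner loop. The product coupling is a symmetric stationary
# point (exactly so for h = 2), so the initial plan gets a small seeded
# multiplicative jitter to break the symmetry.
entropic_gw <- function(C1, C2, reg, max_iter = 200L, seed = 1L, tol = 1e-7) {
  N <- nrow(C1); h <- nrow(C2)
  p <- rep(1 / N, N); q <- rep(1 / h, h)
  constC <- (C1^2 %*% p) %*% t(rep(1, h)) + rep(1, N) %*% t(C2^2 %*% q)
  set.seed(seed)
  T_ <- (p %*% t(q)) * matrix(1 + 0.05 * stats::rnorm(N * h), N, h)
  T_ <- T_ / sum(T_)
  for (it in seq_len(max_iter)) {
    L <- constC - 2 * (C1 %*% T_ %*% t(C2))
    # Sinkhorn on kernel exp(-L/reg)
    K <- exp(-(L - min(L)) / reg)
    u <- rep(1, N); v <- rep(1, h)
    for (s in seq_len(200L)) {
      u_new <- p / as.numeric(K %*% v)
      v <- q / as.numeric(t(K) %*% u_new)
      if (max(abs(u_new - u)) < 1e-12) { u <- u_new; break }
      u <- u_new
    }
    T_new <- (u * K) * rep(v, each = N)
    if (max(abs(T_new - T_)) < tol) { T_ <- T_new; break }
    T_ <- T_new
  }
  T_
}

#' Fit the simplified optimal-transport spatial baseline
#'
#' Embeds cells onto a 1-D grid of `h` locations by entropically regularized
#' Gromov-Wasserstein matching between the cells' expression-space geometry
#' (k-NN-graph geodesics by default) and the grid's line geometry, under
#' uniform marginals. Returns the per-location cell distributions
#' \eqn{\mu_1..\mu_h} and a reconstruction in which each cell is replaced by
#' the mean expression profile of its modal location.
#'
#' @param Xw `expression_matrix` or genes-by-cells matrix.
#' @param spec An [ot_spatial_spec()].
#' @return A `baseline_fit` of kind `location_distribution`; `$mu` is the
#'   h-by-N location-distribution matrix, `$code` the 1-by-N expected grid
#'   position of each cell.
#' @export
fit_ot_spatial <- function(Xw, spec = ot_spatial_spec()) {
  Xv <- if (inherits(Xw, "expression_matrix")) Xw$values else as.matrix(Xw)
  N <- ncol(Xv); h <- spec$n_locations
  if (N < h) stop("need at least as many cells as locations", call. = FALSE)
  if (is.null(spec$seed)) stop("ot spatial fit requires a seed", call. = FALSE)
  C1 <- cell_distances(Xv, spec$n_neighbors, spec$structure_weight)
  if (max(C1) <= 0) stop("degenerate distance matrix (all zeros)", call. = FALSE)
  C1 <- C1 / max(C1)
  C2 <- abs(outer(seq_len(h), seq_len(h), "-"))
  C2 <- C2 / max(C2)
  T_ <- entropic_gw(C1, C2, spec$entropic_reg, spec$max_iter,
                    seed = spec$seed)                           # N x h
  mu <- t(T_)
  mu <- mu / rowSums(mu)                                        # h x N
  profiles <- Xv %*% t(mu)                                      # n x h
  modal <- max.col(T_, ties.method = "first")
  Y <- profiles[, modal, drop = FALSE]
  dimnames(Y) <- dimnames(Xv)
  expected_pos <- as.numeric(T_ %*% seq_len(h)) / rowSums(T_)
  new_baseline_fit("location_distribution", reconstruction = Y,
                   code = matrix(expected_pos, nrow = 1L), mu = mu,
                   code_dim = 1L)
}

#' Wrap an external reconstruction routine as a baseline
#'
#' Lets any user-supplied callable serve as the baseline. The callable
#' receives the reweighted genes-by-cells matrix and must return either a
#' list with `encoder` and `decoder` functions (and optionally `Y`), a
#' reconstruction matrix of the input's shape, or an h-by-N location
#' matrix (rows are renormalized to sum to 1 with a warning if needed).
#'
#' @param fn Callable taking a genes-by-cells matrix.
#' @param Xw `expression_matrix` or matrix passed to `fn`.
#' @return A validated `baseline_fit`.
#' @export
adapter_external <- function(fn, Xw) {
  Xv <- if (inherits(Xw, "expression_matrix")) Xw$values else as.matrix(Xw)
  out <- tryCatch(fn(Xv), error = function(e) {
    stop("adapter-error: external baseline failed: ", conditionMessage(e),
         call. = FALSE)
  })
  n <- nrow(Xv); N <- ncol(Xv)
  if (is.list(out) && !is.null(out$encoder) && !is.null(out$decoder)) {
    Y <- if (!is.null(out$Y)) as.matrix(out$Y) else out$decoder(out$encoder(Xv))
    if (!all(dim(Y) == dim(Xv))) {
      stop("adapter-error: reconstruction shape ", paste(dim(Y), collapse = "x"),
           " does not match input ", n, "x", N, call. = FALSE)
    }
    code <- out$encoder(Xv)
    return(new_baseline_fit("encoder_decoder", reconstruction = Y,
                            code = as.matrix(code), encoder = out$encoder,
                            decoder = out$decoder, code_dim = nrow(as.matrix(code))))
  }
  out <- as.matrix(out)
  if (all(dim(out) == c(n, N))) {
    return(new_baseline_fit("encoder_decoder", reconstruction = out,
                            encoder = function(x) x, decoder = function(z) z,
                            code_dim = n))
  }
  if (ncol(out) == N) {
    rs <- rowSums(out)
    if (any(rs <= 0)) stop("adapter-error: mu row with nonpositive mass", call. = FALSE)
    if (any(abs(rs - 1) > 1e-9)) {
      warning("renormalizing location-distribution rows to sum to 1", call. = FALSE)
      out <- out / rs
    }
    profiles <- Xv %*% t(out)
    modal <- max.col(t(out), ties.method = "first")
    Y <- profiles[, modal, drop = FALSE]
    dimnames(Y) <- dimnames(Xv)
    return(new_baseline_fit("location_distribution", reconstruction = Y,
                            mu = out, code_dim = 1L))
  }
  stop("adapter-error: cannot interpret output of shape ",
       paste(dim(out), collapse = "x"), call. = FALSE)
}
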