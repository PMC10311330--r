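# Synthetic single-cell data: latent cell locations on simple 1-D/2-D
# manifolds, genes as random low-degree polynomials of location (z-scored per
# gene), stacked two-manifold mixtures, and a variance-preserving Gaussian
# noise model indexed by a noise scale beta.

#' Manifold specification
#'
#' @param family `"uniform"` (`Unif([0,1])^d`) or `"gaussian"`
#'   (`N(0, I_d)`).
#' @param dimension 1 or 2.
#' @return A list of class `manifold_spec`.
#' @export
manifold_spec <- function(family = c("uniform", "gaussian"), dimension = 1L) {
  family <- match.arg(family)
  dimension <- as.integer(dimension)
  if (!dimension %in% c(1L, 2L)) stop("dimension must be 1 or 2", call. = FALSE)
  structure(list(family = family, dimension = dimension),
            class = "manifold_spec")
}

#' Sample latent cell locations
#'
#' Draws `N` i.i.d. cell locations from the manifold's distribution.
#'
#' @param spec A [manifold_spec()].
#' @param N Cell count.
#' @param seed Integer seed.
#' @return Tibble with columns `cell_id` and `c1` (and `c2` for 2-D).
#' @export
sample_cell_locations <- function(spec, N, seed) {
  stopifnot(inherits(spec, "manifold_spec"), N >= 1)
  set.seed(as.integer(seed))
  d <- spec$dimension
  draws <- switch(spec$family,
                  uniform = matrix(stats::runif(N * d), N, d),
                  gaussian = matrix(stats::rnorm(N * d), N, d))
  out <- tibble::tibble(cell_id = paste0("cell_", seq_len(N)),
                        c1 = draws[, 1])
  if (d == 2L) out$c2 <- draws[, 2]
  out
}

# Degree table of all polynomial basis terms with 1 <= total degree <=
# degree (the constant is dropped: z-scoring removes it anyway). Each row
# gives the per-coordinate degree of one term.
monomial_exponents <- function(dimension, degree) {
  if (dimension == 1L) {
    cbind(a = seq_len(degree))
  } else {
    grid <- expand.grid(a = 0:degree, b = 0:degree)
    grid <- grid[grid$a + grid$b >= 1 & grid$a + grid$b <= degree, , drop = FALSE]
    as.matrix(grid[order(grid$a + grid$b, grid$a), , drop = FALSE])
  }
}

# Degree-d polynomial orthonormal under the latent distribution: normalized
# probabilists' Hermite for gaussian latents, shifted Legendre on [0,1] for
# uniform latents (degree 0 is the constant 1). Using an orthogonal basis
# keeps "degree" an honest complexity scale: raw monomials of a gaussian
# latent are strongly cross-correlated (cov(c, c^3) = 3), which would make
# higher-degree gene blocks *easier* for a low-dimensional code to capture.
orthopoly_1d <- function(c, degree, family) {
  if (degree == 0L) return(rep(1, length(c)))
  if (family == "gaussian") {
    switch(degree,
           c,
           (c^2 - 1) / sqrt(2),
           (c^3 - 3 * c) / sqrt(6))
  } else {
    switch(degree,
           sqrt(3) * (2 * c - 1),
           sqrt(5) * (6 * c^2 - 6 * c + 1),
           sqrt(7) * (20 * c^3 - 30 * c^2 + 12 * c - 1))
  }
}

# Feature matrix (N x terms) of the orthonormal polynomial basis for the
# given per-term degree table.
polynomial_features <- function(coords, exponents, family) {
  vapply(seq_len(nrow(exponents)), function(j) {
    v <- orthopoly_1d(coords[, 1], exponents[j, 1], family)
    if (ncol(exponents) == 2L) {
      v <- v * orthopoly_1d(coords[, 2], exponents[j, 2], family)
    }
    v
  }, numeric(nrow(coords)))
}

eval_polynomial <- function(coefs, exponents, coords, family) {
  as.numeric(polynomial_features(coords, exponents, family) %*% coefs)
}

#' Generate a single-manifold synthetic dataset
#'
#' Each gene's expression is a random polynomial of the cell's latent
#' location: i.i.d. standard normal coefficients over all basis terms of
#' total degree 1..`degree`, where the basis is orthonormal under the latent
#' distribution (normalized Hermite polynomials for Gaussian manifolds,
#' shifted Legendre for uniform ones; products thereof in 2-D). This keeps
#' the degree an honest complexity scale across blocks. Rows are then
#' z-scored to mean 0, variance 1 (population convention). A gene whose
#' realized variance is numerically zero is resampled, up to 10 retries.
#'
#' @param spec A [manifold_spec()].
#' @param n_genes Number of genes.
#' @param degree Polynomial degree bound, 1-3.
#' @param N Number of cells.
#' @param seed Integer seed.
#' @param block_label Label stored with every gene (used by mixtures).
#' @return A `synthetic_dataset`: list with `X` (`expression_matrix`,
#'   standardized), `locations` (tibble, one row per cell), `truth` (tibble:
#'   `gene_id`, `block`, `family`, `dimension`, `degree`), `programs`
#'   (coefficients), `beta = 0`.
#' @export
generate_single_manifold_dataset <- function(spec, n_genes, degree, N, seed,
                                             block_label = "S1") {
  stopifnot(inherits(spec, "manifold_spec"), n_genes >= 1,
            degree %in% 1:3, N >= 2)
  locations <- sample_cell_locations(spec, N, seed)
  coords <- as.matrix(locations[, -1, drop = FALSE])
  expo <- monomial_exponents(spec$dimension, degree)
  basis <- polynomial_features(coords, expo, spec$family)
  set.seed(as.integer(seed) + 1L)
  vals <- matrix(NA_real_, n_genes, N)
  programs <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    for (try in seq_len(11L)) {
      if (try == 11L) stop("generation-error: zero-variance gene after 10 retries",
                           call. = FALSE)
      coefs <- stats::rnorm(nrow(expo))
      row <- as.numeric(basis %*% coefs)
      if (stats::var(row) > 1e-12) break
    }
    vals[g, ] <- row
    programs[[g]] <- coefs
  }
  z <- zscore_rows(vals)
  gene_ids <- paste0(block_label, "_gene_", seq_len(n_genes))
  X <- expression_matrix(z$values, gene_ids, locations$cell_id,
                         standardized = TRUE)
  truth <- tibble::tibble(gene_id = gene_ids, block = block_label,
                          family = spec$family, dimension = spec$dimension,
                          degree = as.integer(degree))
  structure(list(X = X, locations = locations, truth = truth,
                 programs = stats::setNames(programs, gene_ids),
                 exponents = expo, beta = 0,
                 gene_order_permutation = seq_len(n_genes),
                 recoverable_block = block_label),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d genes x %d cells, beta = %g, blocks: %s\n",
              n_genes(x$X), n_cells(x$X), x$beta,
              paste(unique(x$truth$block), collapse = ", ")))
  invisible(x)
}

#' Stack two single-manifold datasets into a mixture
#'
#' Concatenates the gene rows of two datasets over the same cells (each block
#' keeps its own latent manifold) and shuffles gene order by a recorded
#' permutation, so informative sets are not contiguous. Truth labels travel
#' with the genes.
#'
#' @param d1,d2 `synthetic_dataset`s with equal cell counts.
#' @param seed Seed for the gene-order shuffle.
#' @return A `synthetic_dataset`; `gene_order_permutation` maps stacked
#'   (block-ordered) row indices to output rows, i.e.
#'   `output_row[i] = stacked_row[perm[i]]`.
#' @export
mix_datasets <- function(d1, d2, seed) {
  stopifnot(inherits(d1, "synthetic_dataset"), inherits(d2, "synthetic_dataset"))
  if (n_cells(d1$X) != n_cells(d2$X)) {
    stop("cell counts differ between datasets", call. = FALSE)
  }
  vals <- rbind(d1$X$values, d2$X$values)
  truth <- dplyr::bind_rows(d1$truth, d2$truth)
  gene_ids <- c(d1$X$gene_ids, d2$X$gene_ids)
  if (anyDuplicated(gene_ids)) {
    gene_ids <- make.unique(gene_ids, sep = "_dup")
    truth$gene_id <- gene_ids
  }
  set.seed(as.integer(seed))
  perm <- sample.int(length(gene_ids))
  X <- expression_matrix(vals[perm, , drop = FALSE], gene_ids[perm],
                         d1$X$cell_ids, standardized = TRUE)
  locs <- d1$locations
  names(locs)[-1] <- paste0("m1_", names(locs)[-1])
  locs2 <- d2$locations[, -1, drop = FALSE]
  names(locs2) <- paste0("m2_", names(locs2))
  structure(list(X = X, locations = dplyr::bind_cols(locs, locs2),
                 truth = truth[perm, , drop = FALSE],
                 programs = c(d1$programs, d2$programs)[perm],
                 beta = 0, gene_order_permutation = perm,
                 recoverable_block = NULL),
            class = "synthetic_dataset")
}

#' Corrupt a dataset with calibrated Gaussian noise
#'
#' Mixes the standardized signal with per-gene-standardized Gaussian noise as
#' \eqn{X_\beta = \sqrt{1-\beta}\, X + \sqrt{\beta}\, \bar N} and re-z-scores
#' each row, so every gene keeps mean 0 and variance exactly 1 at any noise
#' scale. `beta = 0` returns the dataset unchanged; `beta = 1` replaces the
#' signal entirely.
#'
#' @param d A standardized `synthetic_dataset`.
#' @param beta Noise scale in `[0, 1]`.
#' @param seed Seed for the noise draw.
#' @return The dataset with corrupted `X` and `beta` recorded.
#' @export
add_noise <- function(d, beta, seed) {
  stopifnot(inherits(d, "synthetic_dataset"))
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) ||
      beta < 0 || beta > 1) {
    stop("beta must lie in [0, 1]", call. = FALSE)
  }
  if (beta == 0) return(d)
  set.seed(as.integer(seed))
  n <- n_genes(d$X); N <- n_cells(d$X)
  noise <- matrix(stats::rnorm(n * N), n, N)
  noise <- zscore_rows(noise)$values
  mixed <- sqrt(1 - beta) * d$X$values + sqrt(beta) * noise
  mixed <- zscore_rows(mixed)$values
  d$X <- expression_matrix(mixed, d$X$gene_ids, d$X$cell_ids,
                           standardized = TRUE)
  d$beta <- beta
  d
}

# Derive a component seed from a master seed, kept inside 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %%
               (.Machine$integer.max - 1)) + 1L
}

benchmark_recipes <- list(
  D1 = list(b1 = list(family = "uniform",  dim = 2L, degree = 3L),
            b2 = list(family = "gaussian", dim = 2L, degree = 3L),
            recoverable = "S1"),
  D2 = list(b1 = list(family = "gaussian", dim = 1L, degree = 2L),
            b2 = list(family = "gaussian", dim = 1L, degree = 3L),
            recoverable = "S1"),
  D3 = list(b1 = list(family = "uniform",  dim = 2L, degree = 3L),
            b2 = list(family = "uniform",  dim = 1L, degree = 3L),
            recoverable = "S2"),
  D4 = list(b1 = list(family = "gaussian", dim = 1L, degree = 2L),
            b2 = list(family = "gaussian", dim = 2L, degree = 1L),
            recoverable = "S2"))

#' Build a two-manifold benchmark mixture
#'
#' Composes the generator, mixer and noise model into the four standard
#' two-block benchmarks:
#' * `D1` — different location distributions: `Unif([0,1])^2` vs `N(0, I_2)`,
#'   degree-3 programs; recoverable set = the uniform block.
#' * `D2` — different program degree: both blocks on `N(0,1)` latents,
#'   degrees 2 vs 3; recoverable set = the degree-2 block.
#' * `D3` — different manifold dimension: `Unif([0,1])^2` vs `Unif([0,1])`,
#'   degree 3; recoverable set = the 1-D block.
#' * `D4` — different dimension and degree: `N(0,1)` degree 2 vs `N(0,I_2)`
#'   degree 1; recoverable set = the degree-1 block.
#'
#' "Recoverable" names the block a one-dimensional-code reconstruction is
#' expected to capture, the ground-truth positive set for TPR/AUC evaluation
#' (available as `truth$informative` and `recoverable_block`).
#'
#' @param recipe `"D1"`..`"D4"`.
#' @param n_genes_per_block Genes per block (default 50).
#' @param N Cells (default 2e4).
#' @param beta Noise scale in `[0,1]` (default 0).
#' @param seed Master seed; block, shuffle and noise seeds are derived.
#' @return A `synthetic_dataset` with `truth$informative` set.
#' @export
make_benchmark <- function(recipe = c("D1", "D2", "D3", "D4"),
                           n_genes_per_block = 50L, N = 20000L, beta = 0,
                           seed = 1L) {
  recipe <- match.arg(recipe)
  r <- benchmark_recipes[[recipe]]
  seed <- as.integer(seed)
  d1 <- generate_single_manifold_dataset(
    manifold_spec(r$b1$family, r$b1$dim), n_genes_per_block, r$b1$degree, N,
    seed = derive_seed(seed, 1L), block_label = "S1")
  d2 <- generate_single_manifold_dataset(
    manifold_spec(r$b2$family, r$b2$dim), n_genes_per_block, r$b2$degree, N,
    seed = derive_seed(seed, 2L), block_label = "S2")
  mixed <- mix_datasets(d1, d2, seed = derive_seed(seed, 3L))
  mixed <- add_noise(mixed, beta, seed = derive_seed(seed, 4L))
  mixed$recoverable_block <- r$recoverable
  mixed$recipe <- recipe
  mixed$truth$informative <- mixed$truth$block == r$recoverable
  mixed
}

#' Ground-truth informative mask of a benchmark dataset
#' @param d A `synthetic_dataset` from [make_benchmark()].
#' @return Logical vector in gene order of `d$X`.
#' @export
truth_mask <- function(d) {
  if (is.null(d$truth$informative)) {
    stop("dataset has no recoverable-block annotation", call. = FALSE)
  }
  stats::setNames(d$truth$informative, d$truth$gene_id)
}
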