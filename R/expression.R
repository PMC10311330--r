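# The genes x cells expression container and standardization.

#' Construct an expression matrix
#'
#' Wraps a genes-by-cells numeric matrix with gene/cell identifiers and a flag
#' recording whether rows have been z-scored. All reconstruction and
#' reweighting functions consume this container.
#'
#' @param values Numeric matrix, genes in rows, cells in columns, no NaN/Inf.
#' @param gene_ids,cell_ids Identifier vectors; default `gene_1..`, `cell_1..`.
#' @param standardized Logical: have rows been centred to mean 0, variance 1?
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids = NULL, cell_ids = NULL,
                              standardized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values must be finite", call. = FALSE)
  }
  n <- nrow(values); N <- ncol(values)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(n))
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(N))
  gene_ids <- as.character(gene_ids); cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != n) stop("gene_ids length != nrow", call. = FALSE)
  if (length(cell_ids) != N) stop("cell_ids length != ncol", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids", call. = FALSE)
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 standardized = isTRUE(standardized)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d cells, standardized = %s\n",
              nrow(x$values), ncol(x$values), x$standardized))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Number of genes / cells of an expression matrix
#' @param X An `expression_matrix`.
#' @return Integer count.
#' @export
n_genes <- function(X) nrow(X$values)

#' @rdname n_genes
#' @export
n_cells <- function(X) ncol(X$values)

# Coerce a plain matrix to expression_matrix, pass through otherwise.
as_expression_matrix <- function(X, standardized = FALSE) {
  if (inherits(X, "expression_matrix")) return(X)
  expression_matrix(X, standardized = standardized)
}

# Row z-score with the population (divide by N) variance convention.
zscore_rows <- function(values) {
  mu <- rowMeans(values)
  centred <- values - mu
  sd_pop <- sqrt(rowMeans(centred^2))
  keep <- sd_pop > 0
  centred[keep, ] <- centred[keep, , drop = FALSE] / sd_pop[keep]
  list(values = centred, constant = !keep)
}

#' Standardize an expression matrix
#'
#' Optionally applies `log(1 + x)` and then z-scores every gene row to mean 0
#' and (population) variance 1, the normalization the reweighting algorithm
#' expects. Constant genes are left at 0 and reported in a warning.
#'
#' @param X An `expression_matrix` or plain genes-by-cells matrix.
#' @param log_transform Apply `log1p` first (requires nonnegative values).
#' @return A standardized `expression_matrix`.
#' @export
standardize <- function(X, log_transform = FALSE) {
  X <- as_expression_matrix(X)
  v <- X$values
  if (log_transform) {
    if (any(v < 0)) stop("log transform requires nonnegative values", call. = FALSE)
    v <- log1p(v)
  }
  z <- zscore_rows(v)
  if (any(z$constant)) {
    warning(sum(z$constant), " constant gene(s) left at zero: ",
            paste(utils::head(X$gene_ids[z$constant], 5), collapse = ", "),
            call. = FALSE)
  }
  expression_matrix(z$values, X$gene_ids, X$cell_ids, standardized = TRUE)
}
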