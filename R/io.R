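# Readers and writers: Matrix Market with gene/cell sidecar TSVs, dense
# CSV/TSV, weight and trajectory serialization, and the run manifest.

#' Read an expression matrix
#'
#' Genes are rows, cells are columns. For Matrix Market input, gene and cell
#' identifiers come from sidecar TSVs (first column used); for delimited
#' input the first column holds gene ids and the header row holds cell ids.
#'
#' @param path Matrix file (`.mtx`, `.csv`, `.tsv`).
#' @param format `"auto"` (by extension), `"mtx"`, `"csv"` or `"tsv"`.
#' @param genes,cells Sidecar paths for mtx input; default `genes.tsv` /
#'   `cells.tsv` next to the matrix.
#' @param cells_in_rows Set when a delimited file is transposed
#'   (cells-by-genes); never guessed.
#' @param standardized Flag recorded on the returned object.
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(path, format = c("auto", "mtx", "csv", "tsv"),
                        genes = NULL, cells = NULL, cells_in_rows = FALSE,
                        standardized = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "tsv",
                     stop("cannot infer format from extension of ", path,
                          call. = FALSE))
  }
  if (format == "mtx") {
    values <- as.matrix(Matrix::readMM(path))
    genes <- genes %||% file.path(dirname(path), "genes.tsv")
    cells <- cells %||% file.path(dirname(path), "cells.tsv")
    if (!file.exists(genes)) stop("gene sidecar not found: ", genes, call. = FALSE)
    if (!file.exists(cells)) stop("cell sidecar not found: ", cells, call. = FALSE)
    gtab <- utils::read.delim(genes, header = TRUE, sep = "\t",
                              check.names = FALSE)
    ctab <- utils::read.delim(cells, header = TRUE, sep = "\t",
                              check.names = FALSE)
    if (nrow(gtab) != nrow(values)) {
      stop("validation-error: genes sidecar has ", nrow(gtab),
           " rows but matrix has ", nrow(values), " genes", call. = FALSE)
    }
    if (nrow(ctab) != ncol(values)) {
      stop("validation-error: cells sidecar has ", nrow(ctab),
           " rows but matrix has ", ncol(values), " cells", call. = FALSE)
    }
    return(expression_matrix(values, gtab[[1L]], ctab[[1L]],
                             standardized = standardized))
  }
  delim <- if (format == "csv") "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = delim,
                           check.names = FALSE, colClasses = "character")
  ids <- tab[[1L]]
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow(mat), ncol(mat)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("parse-error: non-numeric value at data row ", bad[1L],
         ", column ", colnames(mat)[bad[2L]], " of ", path, call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(mat))
  if (cells_in_rows) num <- t(num)
  expression_matrix(num, rownames(num), colnames(num),
                    standardized = standardized)
}

#' Write an expression matrix
#'
#' Matrix Market output is coordinate `real general` written at full double
#' precision, with `genes.tsv` / `cells.tsv` sidecars beside it; delimited
#' output has gene ids in the first column and cell ids in the header.
#'
#' @param X An [expression_matrix()] or plain matrix.
#' @param path Output file; sidecars are placed in its directory for mtx.
#' @param format `"auto"`, `"mtx"`, `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(X, path, format = c("auto", "mtx", "csv", "tsv")) {
  format <- match.arg(format)
  X <- as_expression_matrix(X)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "tsv",
                     stop("cannot infer format from extension of ", path,
                          call. = FALSE))
  }
  v <- X$values
  if (format == "mtx") {
    nz <- which(v != 0)
    rows <- ((nz - 1L) %% nrow(v)) + 1L
    cols <- ((nz - 1L) %/% nrow(v)) + 1L
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("%%MatrixMarket matrix coordinate real general",
                 paste(nrow(v), ncol(v), length(nz))), con)
    writeLines(sprintf("%d %d %.17g", rows, cols, v[nz]), con)
    utils::write.table(data.frame(gene_id = X$gene_ids),
                       file.path(dirname(path), "genes.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(data.frame(cell_id = X$cell_ids),
                       file.path(dirname(path), "cells.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    delim <- if (format == "csv") "," else "\t"
    tab <- data.frame(gene_id = X$gene_ids,
                      matrix(sprintf("%.17g", v), nrow(v)),
                      check.names = FALSE)
    colnames(tab) <- c("gene_id", X$cell_ids)
    utils::write.table(tab, path, sep = delim, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write gene weights as a two-column CSV
#' @param p A `gene_weights` vector (named or paired with `gene_ids`).
#' @param path Output CSV.
#' @param gene_ids Identifiers if `p` is unnamed.
#' @return `path`, invisibly.
#' @export
write_weights <- function(p, path, gene_ids = NULL) {
  ids <- gene_ids %||% names(p) %||% paste0("gene_", seq_along(p))
  utils::write.table(
    data.frame(gene_id = ids, weight = sprintf("%.17g", as.numeric(p))),
    path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene weights written by [write_weights()]
#' @param path Two-column CSV (gene_id, weight).
#' @return A `gene_weights` vector named by gene id.
#' @export
read_weights <- function(path) {
  tab <- utils::read.csv(path, colClasses = c("character", "numeric"))
  gene_weights(tab$weight, gene_ids = tab$gene_id)
}

#' Write a trajectory to disk
#'
#' Produces `trajectory.csv` (long: round, gene_id, weight, gradient),
#' `weights.csv` (final weights) and `summary.json` (per-round loss and
#' concentration plus the configuration) inside `dir`.
#'
#' @param traj A `reweight_trajectory`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tidy(traj), file.path(dir, "trajectory.csv"))
  write_weights(final_weights(traj), file.path(dir, "weights.csv"))
  jsonlite::write_json(
    list(rounds = traj$summary,
         config = unclass(traj$config)),
    file.path(dir, "summary.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, input file MD5 digests, seed and
#' package version, so a run can be verified and reproduced.
#'
#' @param path Output JSON path.
#' @param config Configuration list to snapshot.
#' @param inputs Character vector of input file paths to digest.
#' @param seed Master seed of the run.
#' @param extra Optional named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, inputs = character(), seed = NULL,
                           extra = list()) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- c(list(
    package = "reconboost",
    version = as.character(utils::packageVersion("reconboost")),
    seed = seed,
    config = if (is.null(config)) NULL else unclass(config),
    input_digests = digests), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Verify the input digests of a manifest
#' @param path Manifest JSON written by [write_manifest()].
#' @return `TRUE` if all recorded digests match the files on disk.
#' @export
verify_manifest <- function(path) {
  m <- jsonlite::read_json(path)
  d <- m$input_digests
  if (length(d) == 0L) return(TRUE)
  current <- tools::md5sum(names(d))
  all(!is.na(current) & current == unlist(d))
}
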