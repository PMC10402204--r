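#' Write a benchmark (or any count matrix) as a 10x-style MTX triplet
#'
#' Writes `matrix.mtx` (genes x cells, MatrixMarket), `features.tsv`,
#' `barcodes.tsv`, and -- for a benchmark object -- `metadata.tsv` with
#' columns cell_id, sample_id, day, cell_type, theta.
#'
#' @param x a `"bcd_benchmark"` object or a cells x genes count matrix.
#' @param dir output directory (created if absent).
#' @param metadata optional metadata data.frame when `x` is a bare matrix.
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(x, dir, metadata = NULL) {
  if (inherits(x, "bcd_benchmark")) {
    metadata <- x$metadata
    x <- x$counts
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(as.matrix(x)), sparse = TRUE)  # genes x cells
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(colnames(x)),
                     file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(rownames(x)),
                     file.path(dir, "barcodes.tsv"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(metadata)) {
    utils::write.table(metadata, file.path(dir, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a 10x-style MTX triplet
#'
#' @param dir directory containing `matrix.mtx` (genes x cells),
#'   `features.tsv` and `barcodes.tsv`; a `metadata.tsv` is read if present.
#' @return list with `counts` (cells x genes dense matrix) and `metadata`
#'   (data.frame or `NULL`).
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)[[1]]
  cells <- utils::read.table(file.path(dir, "barcodes.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)[[1]]
  counts <- t(as.matrix(m))
  dimnames(counts) <- list(cells, genes)
  meta_path <- file.path(dir, "metadata.tsv")
  metadata <- if (file.exists(meta_path)) {
    utils::read.delim(meta_path, stringsAsFactors = FALSE)
  } else NULL
  list(counts = counts, metadata = metadata)
}

#' Read a dense expression CSV
#'
#' Cells in rows, a header of feature names, first column the cell id.
#'
#' @param path CSV file path.
#' @return numeric matrix with cell ids as rownames.
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write an embedding (or any cells x features matrix) as CSV
#'
#' @param x numeric matrix with cell ids as rownames.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_embedding_csv <- function(x, path) {
  df <- data.frame(cell_id = rownames(x), as.data.frame(x),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a full pairwise distance matrix as CSV
#'
#' Materializing all n^2 distances is the caller's choice, not a requirement
#' of the metric (clustering and embedding work from the whitened space); a
#' size cap guards against accidental huge outputs.
#'
#' @param d n x n distance matrix.
#' @param path output CSV path.
#' @param max_cells refuse to write matrices larger than this (default
#'   20000).
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(d, path, max_cells = 20000) {
  d <- as.matrix(d)
  if (nrow(d) > max_cells) {
    stop("distance matrix has ", nrow(d), " cells, above the cap of ",
         max_cells, "; raise max_cells to force writing")
  }
  write_embedding_csv(d, path)
}
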