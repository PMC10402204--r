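#' Gaussian locality weights between cells and batches
#'
#' Computes the n x B weight matrix
#' \deqn{W_{ij} = \exp(-\|\tau_i - t_j\|^2 / (2 l^2))}
#' where \eqn{\tau_i} is the time/space label of cell i and \eqn{t_j} that of
#' batch j. Labels may be scalars (e.g. day) or d-dimensional vectors (e.g.
#' \code{[week, location]} with a numeric location coding such as 0/2/4); the
#' user's coding defines the geometry, no internal rescaling is applied.
#'
#' @param cell_times numeric vector (length n) or n x d matrix of per-cell
#'   labels.
#' @param batch_times numeric vector (length B) or B x d matrix of per-batch
#'   labels, same d as `cell_times`.
#' @param length_scale positive length scale l, in the units of the labels.
#'   A length-d vector applies a separate scale per label dimension
#'   (equivalent to pre-dividing that label column by its scale).
#' @return n x B numeric matrix with entries in (0, 1]; `W[i, j] == 1` exactly
#'   when the labels coincide.
#' @examples
#' locality_weights(c(1, 1, 2), c(1, 2))
#' @export
locality_weights <- function(cell_times, batch_times, length_scale = 1) {
  tau <- as.matrix(cell_times)
  tj <- as.matrix(batch_times)
  storage.mode(tau) <- "double"
  storage.mode(tj) <- "double"
  if (ncol(tau) != ncol(tj)) {
    stop("cell_times and batch_times must have the same number of label dimensions (",
         ncol(tau), " vs ", ncol(tj), ")")
  }
  if (any(!is.finite(tau))) {
    bad <- which(!stats::complete.cases(tau) | rowSums(!is.finite(tau)) > 0)
    stop("non-finite time/space label for cell(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(!is.finite(tj))) {
    bad <- which(rowSums(!is.finite(tj)) > 0)
    stop("non-finite time/space label for batch(es): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!is.numeric(length_scale) || any(!is.finite(length_scale)) ||
      any(length_scale <= 0)) {
    stop("length_scale must be positive and finite")
  }
  if (!length(length_scale) %in% c(1L, ncol(tau))) {
    stop("length_scale must be scalar or one value per label dimension")
  }
  # per-dimension scale == pre-scaling the labels, then unit global scale
  if (length(length_scale) > 1L) {
    tau <- sweep(tau, 2L, length_scale, "/")
    tj <- sweep(tj, 2L, length_scale, "/")
    length_scale <- 1
  }
  # squared distances ||tau_i - t_j||^2 without forming an n*B*d array
  sq <- outer(rowSums(tau^2), rowSums(tj^2), "+") - 2 * tcrossprod(tau, tj)
  sq[sq < 0] <- 0  # numerical floor
  w <- exp(-sq / (2 * length_scale^2))
  dimnames(w) <- list(rownames(tau), rownames(tj))
  w
}

#' Per-batch time/space labels from per-cell labels
#'
#' In the intended designs every cell in a batch is collected at one time
#' point, so the batch label t_j is just the shared value of its cells. This
#' helper extracts it and warns if cells within a batch disagree (in which
#' case the per-batch mean is used).
#'
#' @param cell_times numeric vector or n x d matrix of per-cell labels.
#' @param batch factor or vector of per-cell batch assignments.
#' @return B x d matrix of batch labels, rows named and ordered by
#'   `levels(factor(batch))`.
#' @export
batch_times_from_cells <- function(cell_times, batch) {
  tau <- as.matrix(cell_times)
  b <- as.factor(batch)
  if (nrow(tau) != length(b)) stop("cell_times and batch lengths differ")
  out <- apply(tau, 2L, function(col) tapply(col, b, mean))
  out <- matrix(out, nrow = nlevels(b),
                dimnames = list(levels(b), colnames(tau)))
  spread <- apply(tau, 2L, function(col) tapply(col, b, function(v) diff(range(v))))
  if (any(spread > 0)) {
    warning("cells within a batch carry different time/space labels; ",
            "using per-batch means")
  }
  out
}
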