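#' Pearson correlation between two expression profiles
#'
#' The sample similarity used throughout: the Pearson correlation
#' coefficient between two length-n expression vectors. Degenerate
#' (zero-variance) profiles raise an error rather than silently returning
#' zero, because a constant profile has no defined correlation.
#'
#' @param x,y numeric vectors of equal length (n >= 2).
#' @return the correlation, in \[-1, 1\].
#' @examples
#' pearson_correlation(c(1, 2, 3), c(2, 4, 6)) # exactly 1
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_ergcn("vectors differ in length")
  if (length(x) < 2L) stop_ergcn("need at least 2 genes")
  if (anyNA(x) || anyNA(y)) stop_ergcn("missing values in expression profiles")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_ergcn("zero-variance profile: correlation undefined")
  }
  stats::cor(x, y)
}

#' Sample-sample correlation matrix
#'
#' Pairwise Pearson correlations between all sample rows of an expression
#' matrix. All genes enter the computation; no filtering or transformation is
#' applied.
#'
#' @param x samples-x-genes numeric matrix.
#' @return symmetric m x m correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x) {
  check_matrix(x, "expression matrix")
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) {
    who <- rownames(x)[which(sds == 0)[1L]] %||% as.character(which(sds == 0)[1L])
    stop_ergcn("constant expression profile for sample '", who,
               "': correlation undefined")
  }
  r <- stats::cor(t(x))
  # enforce exact symmetry and unit diagonal against rounding in cor()
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Threshold a correlation matrix into a binary adjacency
#'
#' An off-diagonal edge is present iff the absolute correlation strictly
#' exceeds `theta`; both strong positive and strong negative correlation
#' connect two patients. Every node carries a self-loop: the diagonal is 1
#' regardless of `theta`. Comparisons use the raw double-precision
#' correlations, with no rounding.
#'
#' @param r symmetric correlation matrix.
#' @param theta threshold in (0, 1).
#' @return binary m x m adjacency matrix with unit diagonal.
#' @export
threshold_adjacency <- function(r, theta) {
  if (!is_scalar_number(theta) || theta <= 0 || theta >= 1) {
    stop_ergcn("theta must be a single number in (0, 1)")
  }
  check_matrix(r, "correlation matrix")
  if (nrow(r) != ncol(r)) stop_ergcn("correlation matrix must be square")
  a <- (abs(r) > theta) * 1
  diag(a) <- 1
  dimnames(a) <- dimnames(r)
  a
}

#' Symmetric normalization of an adjacency matrix
#'
#' Computes \eqn{D^{-1/2} A D^{-1/2}}, the propagation operator of the graph
#' convolution, where D is the degree matrix of A. Self-loops are counted in
#' the degrees, so every degree is at least 1 and the operator is always
#' defined. All eigenvalues of the result lie in \[-1, 1\].
#'
#' @param a symmetric binary adjacency matrix with unit diagonal.
#' @return the normalized matrix, entries \eqn{A_{ij}/\sqrt{d_i d_j}}.
#' @export
normalize_adjacency <- function(a) {
  check_matrix(a, "adjacency matrix")
  if (nrow(a) != ncol(a) || max(abs(a - t(a))) != 0) {
    stop_ergcn("adjacency must be square and symmetric")
  }
  if (!all(a %in% c(0, 1)) || any(diag(a) != 1)) {
    stop_ergcn("adjacency must be binary with unit diagonal")
  }
  d <- rowSums(a)
  inv_sqrt_d <- 1 / sqrt(d)
  s <- a * tcrossprod(inv_sqrt_d)
  dimnames(s) <- dimnames(a)
  s
}

#' Build the patient similarity network
#'
#' Composition of [correlation_matrix()], [threshold_adjacency()] and
#' [normalize_adjacency()]: the full network object used by [ergcn()].
#' Isolated samples (no neighbor above threshold) are retained with their
#' self-loop only, so every sample still receives a prediction.
#'
#' @param x samples-x-genes expression matrix.
#' @param theta correlation threshold in (0, 1).
#' @param verbose print edge and isolated-node counts.
#' @return an object of class `similarity_network` with fields `sample_ids`,
#'   `correlation`, `theta`, `adjacency`, `degrees`, and `snorm` (the
#'   symmetric-normalized adjacency).
#' @examples
#' bench <- default_benchmark()
#' net <- build_network(bench$x, theta = 0.5)
#' net
#' @export
build_network <- function(x, theta, verbose = FALSE) {
  r <- correlation_matrix(x)
  a <- threshold_adjacency(r, theta)
  s <- normalize_adjacency(a)
  d <- rowSums(a)
  n_edges <- (sum(a) - nrow(a)) / 2
  n_isolated <- sum(d == 1)
  if (verbose) {
    message(sprintf("similarity network: %d samples, %d edges, %d isolated",
                    nrow(a), n_edges, n_isolated))
  }
  structure(list(sample_ids = rownames(x) %||% as.character(seq_len(nrow(x))),
                 correlation = r, theta = theta, adjacency = a,
                 degrees = d, snorm = s,
                 n_edges = n_edges, n_isolated = n_isolated),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("Patient similarity network: %d samples, theta = %g\n",
              length(x$sample_ids), x$theta))
  cat(sprintf("  edges: %d  isolated samples (self-loop only): %d\n",
              x$n_edges, x$n_isolated))
  cat(sprintf("  mean degree (incl. self-loop): %.2f\n", mean(x$degrees)))
  invisible(x)
}

#' Augment a network with one new sample
#'
#' Implements the new-sample protocol: the correlations between a held-out
#' sample and the m training samples are computed, thresholded at the same
#' `theta`, and appended as row/column m+1. The leading m x m adjacency block
#' is exactly the training adjacency; the whole augmented matrix is then
#' re-normalized (degrees of the new node's neighbors change in the
#' normalized operator).
#'
#' @param x_train training samples-x-genes matrix.
#' @param new_sample length-n expression profile of the new sample.
#' @param theta correlation threshold in (0, 1).
#' @param new_id identifier for the new sample.
#' @return a `similarity_network` of size m + 1; the new sample is last.
#' @export
augment_network <- function(x_train, new_sample, theta, new_id = "new_sample") {
  validate_expression(x_train)
  if (length(new_sample) != ncol(x_train)) {
    stop_ergcn("new sample has ", length(new_sample), " genes; expected ",
               ncol(x_train))
  }
  if (stats::sd(new_sample) == 0) stop_ergcn("zero-variance profile: correlation undefined")
  r_train <- correlation_matrix(x_train)
  r_new <- as.numeric(stats::cor(t(x_train), new_sample))
  m <- nrow(x_train)
  r <- rbind(cbind(r_train, r_new), c(r_new, 1))
  ids <- c(rownames(x_train), new_id)
  dimnames(r) <- list(ids, ids)
  a <- threshold_adjacency(r, theta)
  s <- normalize_adjacency(a)
  d <- rowSums(a)
  structure(list(sample_ids = ids, correlation = r, theta = theta,
                 adjacency = a, degrees = d, snorm = s,
                 n_edges = (sum(a) - (m + 1)) / 2, n_isolated = sum(d == 1)),
            class = "similarity_network")
}
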