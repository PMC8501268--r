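#' Enumerate edge pairs in the fixed ordering
#'
#' The package uses a single edge-ordering convention everywhere: the
#' upper triangle of a symmetric connectome, traversed row-major, i.e.
#' node pairs (i, j) with i < j ordered first by i and then by j.
#' Node indices are 1-based.
#'
#' @param n_nodes Number of nodes (>= 2).
#' @return A tibble with columns `index`, `i`, `j` where `index` runs
#'   from 1 to `n_nodes * (n_nodes - 1) / 2`.
#' @examples
#' edge_pairs(4)
#' @export
edge_pairs <- function(n_nodes) {
  n <- as.integer(n_nodes)
  if (is.na(n) || n < 2) {
    rlang::abort("`n_nodes` must be an integer >= 2.")
  }
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n),
              use.names = FALSE)
  tibble::tibble(index = seq_along(i), i = i, j = j)
}

#' Number of edges for a given node count
#' @param n_nodes Number of nodes.
#' @return `n_nodes * (n_nodes - 1) / 2`.
#' @export
n_edges <- function(n_nodes) {
  as.integer(n_nodes * (n_nodes - 1) / 2)
}

# Infer node count from an edge-vector length; NA if not triangular.
nodes_from_edges <- function(m) {
  n <- (1 + sqrt(1 + 8 * m)) / 2
  if (abs(n - round(n)) > 1e-9) return(NA_integer_)
  as.integer(round(n))
}

#' Vectorize the upper triangle of a connectome
#'
#' Flattens a symmetric zero-diagonal matrix into an edge vector using
#' the package-wide row-major upper-triangle ordering (see
#' [edge_pairs()]).
#'
#' @param mat Square symmetric numeric matrix with zero diagonal.
#' @param tol Symmetry tolerance; asymmetries beyond it are an error
#'   (the maximal asymmetry is reported), never silently repaired.
#' @return Numeric vector of length `n (n - 1) / 2` with attribute
#'   `n_nodes`.
#' @examples
#' m <- matrix(0, 3, 3)
#' m[1, 2] <- m[2, 1] <- 0.4
#' vectorize_upper(m)
#' @export
vectorize_upper <- function(mat, tol = 1e-8) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat)) {
    rlang::abort("`mat` must be a square matrix.")
  }
  asym <- max(abs(mat - t(mat)))
  if (asym > tol) {
    rlang::abort(sprintf(
      "Matrix is not symmetric: max |A - t(A)| = %.3g exceeds tol %.3g.",
      asym, tol))
  }
  tm <- t(mat)
  v <- tm[lower.tri(tm)]
  attr(v, "n_nodes") <- nrow(mat)
  v
}

#' Rebuild a connectome from an edge vector
#'
#' Inverse of [vectorize_upper()]: produces the symmetric
#' zero-diagonal matrix whose row-major upper triangle equals `v`.
#'
#' @param v Numeric edge vector.
#' @param n_nodes Node count; inferred from `length(v)` when omitted.
#' @return An `n_nodes` x `n_nodes` symmetric matrix.
#' @export
devectorize <- function(v, n_nodes = NULL) {
  m <- length(v)
  if (is.null(n_nodes)) {
    n_nodes <- nodes_from_edges(m)
    if (is.na(n_nodes)) {
      rlang::abort(sprintf(
        "Edge vector of length %d implies a non-integer node count (%.4f).",
        m, (1 + sqrt(1 + 8 * m)) / 2))
    }
  } else if (n_edges(n_nodes) != m) {
    rlang::abort(sprintf(
      "Edge vector of length %d is incompatible with n_nodes = %d (expected %d).",
      m, n_nodes, n_edges(n_nodes)))
  }
  out <- matrix(0, n_nodes, n_nodes)
  # column-major traversal of the lower triangle visits (j, i) pairs in
  # exactly the row-major order of the upper triangle
  out[lower.tri(out)] <- as.numeric(v)
  out + t(out)
}
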