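#' Library-size normalize a counts matrix
#'
#' Scales each cell's counts to the median total count over cells.
#'
#' @param counts cells x genes matrix.
#' @return matrix of the same shape.
#' @export
size_normalize <- function(counts) {
  tot <- rowSums(counts)
  tot[tot == 0] <- 1
  counts * (stats::median(tot) / tot)
}

#' First-order moments: kNN-smoothed spliced/unspliced matrices
#'
#' Library-size normalizes the spliced and unspliced matrices, builds a
#' k-nearest-neighbour graph in the space of the top principal components
#' of the normalized spliced matrix (Euclidean distance), and replaces
#' each cell's profile by the mean over its neighbour set including the
#' cell itself. With `n_neighbors = 1` the smoothing is the identity.
#'
#' @param pair a `cell_matrix_pair` (typically one sample; see
#'   [subset_pair()]).
#' @param n_neighbors neighbourhood size including self (must be smaller
#'   than the number of cells).
#' @param n_pcs number of principal components for the kNN space.
#' @return object of class `moments`: list with `Ms`, `Mu` (cells x genes
#'   smoothed matrices), `knn` (cells x n_neighbors index matrix, first
#'   column = self), `n_neighbors`, `n_pcs`.
#' @export
compute_moments <- function(pair, n_neighbors = 30L, n_pcs = 30L) {
  stopifnot(inherits(pair, "cell_matrix_pair"))
  n <- nrow(pair$spliced)
  if (n_neighbors >= n)
    stop("n_neighbors (", n_neighbors, ") must be smaller than the number ",
         "of cells (", n, ")")
  s_norm <- size_normalize(pair$spliced)
  u_norm <- size_normalize(pair$unspliced)

  k_pcs <- min(n_pcs, n - 1L, ncol(s_norm))
  pcs <- stats::prcomp(s_norm, center = TRUE, scale. = FALSE,
                       rank. = k_pcs)$x
  d2 <- as.matrix(stats::dist(pcs))^2
  diag(d2) <- -1                       # self sorts first even under ties
  knn <- t(apply(d2, 1L, function(row) order(row)[seq_len(n_neighbors)]))
  knn <- matrix(knn, nrow = n)

  smooth <- function(m) {
    out <- matrix(0, n, ncol(m), dimnames = dimnames(m))
    for (i in seq_len(n)) out[i, ] <- colMeans(m[knn[i, ], , drop = FALSE])
    out
  }
  structure(list(Ms = smooth(s_norm), Mu = smooth(u_norm), knn = knn,
                 n_neighbors = as.integer(n_neighbors),
                 n_pcs = as.integer(k_pcs)),
            class = "moments")
}
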