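#' RNA velocity field from kinetic fits and moments
#'
#' Per gene, `v = beta * Mu - gamma * Ms` with `beta = 1` (the fitting
#' gauge), so velocity is zero exactly on the fitted steady-state line
#' `Mu = (gamma/beta) * Ms`, positive above it and negative below.
#' Genes with invalid fits are excluded; `likelihood_quantile`
#' optionally restricts the field to well-fitted genes — a gene without
#' resolvable dynamics gets an arbitrary fitted `gamma`, and the
#' resulting constant velocity component can drown the real signal in
#' the downstream transition kernel.
#'
#' @param fits list of `gene_fit`.
#' @param moments a [compute_moments()] result.
#' @param likelihood_quantile quantile of the valid fits' likelihoods
#'   below which genes are dropped from the field (0 = keep all valid).
#' @return cells x genes matrix of velocities (columns = kept genes).
#' @export
compute_velocity <- function(fits, moments, likelihood_quantile = 0) {
  stopifnot(inherits(moments, "moments"))
  valid <- Filter(function(f) f$valid, fits)
  if (!length(valid)) stop("no valid fits")
  if (likelihood_quantile > 0) {
    liks <- vapply(valid, `[[`, 1, "fit_likelihood")
    valid <- valid[liks >= stats::quantile(liks, likelihood_quantile)]
  }
  ids <- vapply(valid, `[[`, "", "gene_id")
  gam <- vapply(valid, `[[`, 1, "gamma")
  v <- moments$Mu[, ids, drop = FALSE] -
    sweep(moments$Ms[, ids, drop = FALSE], 2L, gam, `*`)
  v
}

#' Velocity-kernel cell-cell transition matrix
#'
#' Over the kNN graph, the probability of moving from cell i to neighbour
#' j grows with the cosine similarity between i's velocity vector and the
#' displacement `s_j - s_i` in (smoothed spliced) expression space:
#' `w_ij = exp(cos(v_i, s_j - s_i) / kernel_scale)`, rows normalized to
#' 1. Cells with zero velocity transition uniformly over their
#' neighbours. Self-edges are excluded unless a row would otherwise be
#' empty, in which case the cell keeps a unit self-loop.
#'
#' @param moments a [compute_moments()] result.
#' @param velocity matrix from [compute_velocity()].
#' @param knn optional neighbour index matrix (defaults to
#'   `moments$knn`).
#' @param kernel_scale softness of the kernel (> 0).
#' @return row-stochastic sparse `dgCMatrix` (cells x cells).
#' @export
velocity_graph <- function(moments, velocity, knn = NULL,
                           kernel_scale = 0.1) {
  stopifnot(inherits(moments, "moments"), kernel_scale > 0)
  if (is.null(knn)) knn <- moments$knn
  n <- nrow(velocity)
  S <- moments$Ms[, colnames(velocity), drop = FALSE]
  ii <- jj <- xx <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- setdiff(knn[i, ], i)
    if (!length(nb)) { ii[[i]] <- i; jj[[i]] <- i; xx[[i]] <- 1; next }
    disp <- S[nb, , drop = FALSE] -
      matrix(S[i, ], length(nb), ncol(S), byrow = TRUE)
    vi <- velocity[i, ]
    nv <- sqrt(sum(vi^2))
    nd <- sqrt(rowSums(disp^2))
    if (nv < 1e-12) {
      w <- rep(1, length(nb))
    } else {
      cosine <- as.numeric(disp %*% vi) / (nv * pmax(nd, 1e-12))
      cosine[nd < 1e-12] <- 0
      w <- exp(cosine / kernel_scale)
    }
    w <- w / sum(w)
    ii[[i]] <- rep(i, length(nb)); jj[[i]] <- nb; xx[[i]] <- w
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, n))
}

#' Terminal-state probabilities from the transition Markov chain
#'
#' Computes the stationary distribution of the row-stochastic transition
#' matrix by power iteration on its transpose and aggregates it by
#' cluster mean. Cells where the random walk accumulates (low probability
#' of transitioning onward) mark the terminal state of the trajectory.
#'
#' @param transition row-stochastic matrix (e.g. [velocity_graph()]).
#' @param clusters per-cell cluster labels.
#' @param max_iter,tol power-iteration controls.
#' @return list with `cell_prob` (stationary distribution, sums to 1),
#'   `cluster_score` (mean stationary mass per cluster), `converged`,
#'   `residual`, `iterations`.
#' @export
terminal_states <- function(transition, clusters, max_iter = 2000L,
                            tol = 1e-10) {
  n <- nrow(transition)
  rs <- Matrix::rowSums(transition)
  if (any(abs(rs - 1) > 1e-9))
    stop("transition matrix is not row-stochastic")
  stopifnot(length(clusters) == n)
  p <- rep(1 / n, n)
  tT <- Matrix::t(transition)
  residual <- Inf
  it <- 0L
  for (it in seq_len(max_iter)) {
    p_new <- as.numeric(tT %*% p)
    p_new <- p_new / sum(p_new)
    residual <- sum(abs(p_new - p))
    p <- p_new
    if (residual < tol) break
  }
  converged <- residual < tol
  if (!converged)
    warning("power iteration did not converge after ", max_iter,
            " iterations (L1 residual ", signif(residual, 3), ")")
  score <- tapply(p, clusters, mean)
  list(cell_prob = p, cluster_score = score, converged = converged,
       residual = residual, iterations = it)
}

#' Cluster-graph abstraction of the kNN graph
#'
#' Connectivity between two clusters is the observed number of
#' inter-cluster kNN edges divided by the count expected if the same
#' number of undirected edges were placed at random among all cell
#' pairs: `E[o_ab] = m * 2 * n_a * n_b / (n * (n - 1))`. Values well
#' above 1 indicate adjacent clusters. If a velocity transition matrix
#' is supplied, a directed net flux between clusters
#' (`sum T_ij - T_ji` over inter-cluster pairs) is reported as well.
#'
#' @param knn neighbour index matrix (first column self).
#' @param clusters per-cell labels (at least two distinct).
#' @param transition optional transition matrix for edge directions.
#' @return list with symmetric matrix `connectivity` (zero diagonal),
#'   matrix `flux` (antisymmetric, or NULL), and `singletons` (labels of
#'   single-cell clusters, flagged).
#' @export
cluster_graph <- function(knn, clusters, transition = NULL) {
  clusters <- as.character(clusters)
  labs <- sort(unique(clusters))
  if (length(labs) < 2L) stop("need at least two clusters")
  n <- nrow(knn)
  # undirected edge list from the kNN sets (self excluded, deduplicated)
  src <- rep(seq_len(n), ncol(knn) - 1L)
  dst <- as.integer(knn[, -1L])
  a <- pmin(src, dst); b <- pmax(src, dst)
  keep <- a != b
  edges <- unique(cbind(a[keep], b[keep]))
  m <- nrow(edges)
  sizes <- table(factor(clusters, levels = labs))
  conn <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  ca <- clusters[edges[, 1]]; cb <- clusters[edges[, 2]]
  for (x in labs) for (y in labs) {
    if (x >= y) next
    o <- sum((ca == x & cb == y) | (ca == y & cb == x))
    e <- m * 2 * sizes[[x]] * sizes[[y]] / (n * (n - 1))
    conn[x, y] <- conn[y, x] <- o / e
  }
  flux <- NULL
  if (!is.null(transition)) {
    flux <- matrix(0, length(labs), length(labs),
                   dimnames = list(labs, labs))
    for (x in labs) for (y in labs) {
      if (x == y) next
      ix <- which(clusters == x); iy <- which(clusters == y)
      flux[x, y] <- sum(transition[ix, iy]) - sum(transition[iy, ix])
    }
  }
  singles <- labs[sizes == 1L]
  if (length(singles))
    warning("singleton cluster(s): ", paste(singles, collapse = ", "))
  list(connectivity = conn, flux = flux, singletons = singles)
}
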