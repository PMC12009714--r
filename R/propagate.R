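#' Impute features at unobserved nodes by clamped graph diffusion
#'
#' Iterates row-normalized diffusion with unit self-loops,
#' `X <- D^{-1} (A + I) X`, resetting the observed rows to their input after
#' every sweep, until the largest absolute change at unobserved rows falls
#' below `tol` or `max_iter` is reached. The fixed point is the harmonic
#' (Dirichlet) interpolation of the observed values over the graph, so each
#' imputed value lies within the observed range of its connected component.
#' Unobserved nodes with no path to any observed node are set to the global
#' observed feature mean and reported.
#'
#' @param X_obs matrix (N x M); rows at unobserved nodes are ignored (may be
#'   `NA`).
#' @param graph a `SpatialGraph` over all N nodes.
#' @param obs_mask logical vector of length N, `TRUE` where observed.
#' @param max_iter maximum sweeps (default 200).
#' @param tol convergence tolerance on the max absolute per-entry change at
#'   unobserved rows (default 1e-5).
#' @return a `PropagatedFeatures` list: `X_full` (N x M) (observed rows equal
#'   `X_obs` exactly), `n_iter_used`, `max_delta` (last sweep), `unreachable`
#'   (integer indices).
#' @export
propagate_features <- function(X_obs, graph, obs_mask,
                               max_iter = 200L, tol = 1e-5) {
  X_obs <- as.matrix(X_obs)
  A <- graph$adjacency
  N <- nrow(A)
  if (nrow(X_obs) != N) stop("X_obs rows must match graph size")
  if (length(obs_mask) != N) stop("obs_mask length must match graph size")
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (tol <= 0) stop("tol must be positive")
  if (!any(obs_mask)) stop("at least one observed node is required")
  obs <- which(obs_mask); uno <- which(!obs_mask)
  mu <- colMeans(X_obs[obs, , drop = FALSE])
  if (any(!is.finite(mu))) stop("observed rows of X_obs contain non-finite values")

  # connected components: unobserved nodes in components with no observed node
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  obs_comps <- unique(comp[obs])
  unreachable <- uno[!(comp[uno] %in% obs_comps)]

  P <- row_normalized_operator(A)
  X <- X_obs
  X[uno, ] <- rep(mu, each = length(uno))   # mean init keeps values in range
  n_iter <- 0L
  max_delta <- 0
  if (length(uno)) {
    for (it in seq_len(max_iter)) {
      n_iter <- it
      Xn <- as.matrix(P %*% X)
      Xn[obs, ] <- X_obs[obs, , drop = FALSE]
      max_delta <- max(abs(Xn[uno, , drop = FALSE] - X[uno, , drop = FALSE]))
      X <- Xn
      if (max_delta < tol) break
    }
  } else {
    n_iter <- 1L
  }
  if (length(unreachable)) {
    X[unreachable, ] <- rep(mu, each = length(unreachable))
    warning(length(unreachable),
            " unobserved node(s) unreachable from any observed node; set to the observed feature mean")
  }
  dimnames(X) <- dimnames(X_obs)
  structure(list(X_full = X, n_iter_used = n_iter, max_delta = max_delta,
                 unreachable = unreachable),
            class = "PropagatedFeatures")
}

row_normalized_operator <- function(A) {
  N <- nrow(A)
  Ahat <- A + Matrix::Diagonal(N)   # unit self-loops
  d <- Matrix::rowSums(Ahat)
  Matrix::Diagonal(N, 1 / d) %*% Ahat
}

#' Feature-propagation completion of a dataset
#'
#' Convenience wrapper: runs [propagate_features()] with the dataset's
#' observed mask and returns the completed matrix X' covering all locations.
#'
#' @param ds a `SpatialDataset`
#' @param graph a `SpatialGraph` over the same locations
#' @param ... passed to [propagate_features()]
#' @return the `PropagatedFeatures` object
#' @export
complete_features <- function(ds, graph, ...) {
  propagate_features(ds$expr, graph, ds$status == "observed", ...)
}
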