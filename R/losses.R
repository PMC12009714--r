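# Loss functions of the pairwise GAE. Probabilities are clipped to
# [eps, 1 - eps] before any log; eps = 1e-7.

.bce_eps <- 1e-7

clip01 <- function(p) pmin(pmax(p, .bce_eps), 1 - .bce_eps)

bce_vec <- function(target, p) {
  p <- clip01(p)
  -(target * log(p) + (1 - target) * log(1 - p))
}

#' Attribute reconstruction loss
#'
#' Mean squared self-reconstruction of observed expression from the
#' attribute encoding, plus `lambda_cross` times the cross-reconstruction
#' from the topology encoding of the same (observed) locations, both scaled
#' by `1 / (N_o * M)` in the Frobenius sense:
#' `(1/(N_o M)) ||X_o - dec(Z_Xo)||_F^2 + (lambda_cross/(N_o M)) ||X_o - dec(Z_Ao)||_F^2`.
#'
#' @param X_o observed expression (N_o x M)
#' @param Z_Xo attribute encoding of observed locations (N_o x l)
#' @param Z_Ao topology encoding rows at observed locations (N_o x l)
#' @param state a `ModelState` (provides the attribute decoder)
#' @param lambda_cross cross-reconstruction weight
#' @return scalar loss
#' @export
loss_attr <- function(X_o, Z_Xo, Z_Ao, state, lambda_cross = 1) {
  X_o <- as.matrix(X_o)
  n <- length(X_o)
  self <- sum((X_o - decode_attr(Z_Xo, state))^2) / n
  if (lambda_cross == 0) return(self)
  cross <- sum((X_o - decode_attr(Z_Ao, state))^2) / n
  self + lambda_cross * cross
}

#' Topology reconstruction loss
#'
#' Mean binary cross-entropy of the self-reconstruction of adjacency entries
#' (predicted from the topology encoding) plus `lambda_cross` times the mean
#' BCE of the cross-reconstruction of observed-submatrix entries (predicted
#' from the attribute encoding). Entries may be the full off-diagonal set or
#' any sampled subset (see [sample_partial_adjacency()]); optional `weights`
#' make the sampled mean a stratified estimate of the full-matrix mean.
#'
#' @param targets_self 0/1 vector of adjacency targets for the self term
#' @param p_self predicted probabilities for the self term
#' @param targets_cross,p_cross same for the cross term (may be `NULL` when
#'   `lambda_cross = 0`)
#' @param lambda_cross cross-reconstruction weight
#' @param weights_self,weights_cross optional per-entry weights (must mean
#'   to 1 for an interpretable scale)
#' @return scalar loss
#' @export
loss_topo <- function(targets_self, p_self, targets_cross = NULL,
                      p_cross = NULL, lambda_cross = 1,
                      weights_self = NULL, weights_cross = NULL) {
  b <- bce_vec(targets_self, p_self)
  self <- if (is.null(weights_self)) mean(b) else mean(weights_self * b)
  if (lambda_cross == 0 || is.null(targets_cross)) return(self)
  b2 <- bce_vec(targets_cross, p_cross)
  cross <- if (is.null(weights_cross)) mean(b2) else mean(weights_cross * b2)
  self + lambda_cross * cross
}

#' Adversarial distribution-matching loss
#'
#' The discriminator objective
#' `2 E[-log D(Z')] + E[-log(1 - D(Z_Xo))] + E[-log(1 - D(Z_A))]`,
#' minimized in the discriminator parameters (D is pushed to 1 on prior
#' samples, 0 on encodings) and maximized in the encoder parameters.
#'
#' @param D_prior discriminator outputs on prior samples Z'
#' @param D_zx discriminator outputs on attribute encodings
#' @param D_za discriminator outputs on topology encodings
#' @return scalar loss
#' @export
loss_adv <- function(D_prior, D_zx, D_za) {
  2 * mean(-log(clip01(D_prior))) +
    mean(-log(1 - clip01(D_zx))) +
    mean(-log(1 - clip01(D_za)))
}

#' Sample adjacency entries for partial reconstruction
#'
#' Draws `m` edges (unordered pairs, uniformly without replacement) and
#' `ceiling(neg_pos_ratio * m)` non-edges (i != j, uniformly) from a graph,
#' so the adjacency BCE can be estimated from a subset of entries instead of
#' all N^2. If the requested negatives meet or exceed the number of
#' available non-edge pairs, all of them are returned (the estimator is then
#' exact). Deterministic given `seed`.
#'
#' @param graph a `SpatialGraph` (or a sparse/dense 0/1 adjacency matrix)
#' @param m number of positive entries (<= number of edges)
#' @param neg_pos_ratio negatives per positive
#' @param seed integer seed; `NULL` uses (and advances) the current RNG
#'   state, which the training loop relies on for a single seeded stream
#' @return list: `pairs` (2-column matrix, i < j), `target` 0/1 vector,
#'   `n_pos_total`, `n_neg_total` (population counts of unordered pairs),
#'   `weights` (per-entry stratified weights averaging to 1, such that
#'   `mean(weights * bce)` estimates the full off-diagonal mean BCE).
#' @export
sample_partial_adjacency <- function(graph, m, neg_pos_ratio = 1, seed = 1L) {
  A <- if (inherits(graph, "SpatialGraph")) graph$adjacency else graph
  N <- nrow(A)
  Au <- Matrix::triu(A, k = 1)
  s <- Matrix::summary(methods::as(methods::as(Au, "CsparseMatrix"),
                                   "TsparseMatrix"))
  E <- cbind(s$i, s$j)
  n_pos_total <- nrow(E)
  if (n_pos_total == 0) stop("graph has no edges")
  if (m > n_pos_total) stop("m exceeds the number of edges")
  n_pair <- N * (N - 1) / 2
  n_neg_total <- n_pair - n_pos_total
  n_neg <- ceiling(neg_pos_ratio * m)
  if (!is.null(seed)) set.seed(as.integer(seed))
  pos <- E[sample.int(n_pos_total, m), , drop = FALSE]
  if (n_neg >= n_neg_total) {
    # exhaustive: enumerate every non-edge pair
    Ad <- as.matrix(A) > 0
    Ad[lower.tri(Ad, diag = TRUE)] <- TRUE
    neg <- which(!Ad, arr.ind = TRUE)[, c(1, 2), drop = FALSE]
    n_neg <- nrow(neg)
  } else {
    # rejection-sample unordered non-edge pairs
    neg <- matrix(0L, 0, 2)
    while (nrow(neg) < n_neg) {
      need <- n_neg - nrow(neg)
      i <- sample.int(N, 2 * need + 10, replace = TRUE)
      j <- sample.int(N, 2 * need + 10, replace = TRUE)
      lo <- pmin(i, j); hi <- pmax(i, j)
      ok <- lo != hi & A[cbind(lo, hi)] == 0
      cand <- unique(cbind(lo, hi)[ok, , drop = FALSE])
      neg <- unique(rbind(neg, cand))
    }
    neg <- neg[seq_len(n_neg), , drop = FALSE]
  }
  pairs <- rbind(pos, neg)
  target <- c(rep(1, m), rep(0, nrow(neg)))
  n_samp <- length(target)
  w_pos <- (n_pos_total / n_pair) * n_samp / m
  w_neg <- (n_neg_total / n_pair) * n_samp / nrow(neg)
  weights <- c(rep(w_pos, m), rep(w_neg, nrow(neg)))
  list(pairs = unname(pairs), target = target,
       n_pos_total = n_pos_total, n_neg_total = n_neg_total,
       weights = weights)
}

#' Stratified partial-adjacency BCE estimate
#'
#' Combines per-class mean BCEs over a [sample_partial_adjacency()] draw
#' into an unbiased estimate of the mean BCE over all unordered off-diagonal
#' entries.
#'
#' @param sample a [sample_partial_adjacency()] result
#' @param p predicted probabilities for `sample$pairs` (same order)
#' @return scalar estimate
#' @export
bce_stratified <- function(sample, p) {
  mean(sample$weights * bce_vec(sample$target, p))
}

#' Full-matrix adjacency BCE
#'
#' Exact mean BCE over all unordered off-diagonal entries; the reference
#' the partial estimator is tested against.
#'
#' @param A 0/1 adjacency (matrix or sparse)
#' @param P probability matrix of the same size
#' @return scalar
#' @export
bce_full <- function(A, P) {
  A <- as.matrix(A); P <- as.matrix(P)
  ut <- upper.tri(A)
  mean(bce_vec(A[ut], P[ut]))
}
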