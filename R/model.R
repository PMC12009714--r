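# Pairwise graph-autoencoder architecture: an MLP attribute autoencoder and a
# message-passing topology autoencoder share an l-dimensional latent space,
# coupled by cross-reconstruction and by an MLP discriminator that matches
# both latent distributions to a standard Gaussian prior.

#' Model configuration
#'
#' @param latent_dim latent width l shared by both encoders (>= 2).
#' @param attr_hidden hidden widths of the attribute encoder (decoder mirrors
#'   them reversed).
#' @param topo_hidden node-state width of the topology encoder rounds.
#' @param topo_rounds message-passing rounds.
#' @param edge_hidden hidden width of the edge-weight MLP.
#' @param topo_dec_hidden hidden widths of the topology decoder MLP applied
#'   before the inner product.
#' @param disc_hidden hidden widths of the discriminator.
#' @param lambda_cross weight of the cross-reconstruction terms (>= 0). Large
#'   values emphasize spatial homogeneity; small values preserve expression
#'   heterogeneity within domains.
#' @param lambda_adv weight of the adversarial matching term (>= 0).
#' @param lr,disc_lr Adam learning rates for the autoencoder and the
#'   discriminator.
#' @param epochs training epochs (full-batch).
#' @param adj_subset number of positive adjacency entries sampled per epoch
#'   for the topology loss (`NULL` = all edges).
#' @param neg_pos_ratio sampled negative entries per positive.
#' @param full_adj_threshold use the exact full-matrix adjacency loss when
#'   the node count does not exceed this (memory/time trade-off).
#' @param adv_mode `"nonsaturating"` (generator maximizes log D(Z)) or
#'   `"saturating"` (literal minimax form).
#' @param fp_max_iter,fp_tol feature-propagation settings (see
#'   [propagate_features()]).
#' @param seed integer; governs every random choice during training.
#' @return a `ModelConfig` list
#' @export
stweave_config <- function(latent_dim = 32L, attr_hidden = c(256L, 64L),
                           topo_hidden = 64L, topo_rounds = 2L,
                           edge_hidden = 32L, topo_dec_hidden = 64L,
                           disc_hidden = c(64L, 32L),
                           lambda_cross = 1.0, lambda_adv = 0.1,
                           lr = 1e-3, disc_lr = 1e-3, epochs = 500L,
                           adj_subset = NULL, neg_pos_ratio = 1,
                           full_adj_threshold = 2000L,
                           adv_mode = c("nonsaturating", "saturating"),
                           fp_max_iter = 200L, fp_tol = 1e-5, seed = 0L) {
  if (latent_dim < 2) stop("latent_dim must be >= 2")
  if (epochs < 1) stop("epochs must be >= 1")
  if (!is.finite(lambda_cross) || lambda_cross < 0)
    stop("lambda_cross must be finite and >= 0")
  if (!is.finite(lambda_adv) || lambda_adv < 0)
    stop("lambda_adv must be finite and >= 0")
  structure(list(latent_dim = as.integer(latent_dim),
                 attr_hidden = as.integer(attr_hidden),
                 topo_hidden = as.integer(topo_hidden),
                 topo_rounds = as.integer(topo_rounds),
                 edge_hidden = as.integer(edge_hidden),
                 topo_dec_hidden = as.integer(topo_dec_hidden),
                 disc_hidden = as.integer(disc_hidden),
                 lambda_cross = lambda_cross, lambda_adv = lambda_adv,
                 lr = lr, disc_lr = disc_lr, epochs = as.integer(epochs),
                 adj_subset = adj_subset, neg_pos_ratio = neg_pos_ratio,
                 full_adj_threshold = as.integer(full_adj_threshold),
                 adv_mode = match.arg(adv_mode),
                 fp_max_iter = as.integer(fp_max_iter), fp_tol = fp_tol,
                 seed = as.integer(seed)),
            class = "ModelConfig")
}

init_model_state <- function(M, cfg) {
  set.seed(cfg$seed)
  h <- cfg$topo_hidden
  topo_enc <- list(
    edge_mlp = mlp_init(2L * M + 1L, cfg$edge_hidden, 1L),
    rounds = lapply(seq_len(cfg$topo_rounds), function(r) {
      d_in <- if (r == 1L) 2L * M else 2L * h
      r0 <- sqrt(6 / (d_in + h))
      list(W = matrix(stats::runif(d_in * h, -r0, r0), d_in, h), b = rep(0, h))
    }),
    out = {
      r0 <- sqrt(6 / (h + cfg$latent_dim))
      list(W = matrix(stats::runif(h * cfg$latent_dim, -r0, r0), h, cfg$latent_dim),
           b = rep(0, cfg$latent_dim))
    },
    M = M, h = h, rounds_n = cfg$topo_rounds)
  structure(list(
    attr_enc = mlp_init(M, cfg$attr_hidden, cfg$latent_dim),
    attr_dec = mlp_init(cfg$latent_dim, rev(cfg$attr_hidden), M),
    topo_enc = topo_enc,
    topo_dec = mlp_init(cfg$latent_dim, cfg$topo_dec_hidden, cfg$latent_dim),
    disc = mlp_init(cfg$latent_dim, cfg$disc_hidden, 1L),
    cfg = cfg, history = NULL, trained = FALSE, M = M
  ), class = "ModelState")
}

#' @export
print.ModelState <- function(x, ...) {
  cat(sprintf("ModelState: M=%d -> l=%d%s\n", x$M, x$cfg$latent_dim,
              if (x$trained) sprintf(", trained %d epochs", nrow(x$history))
              else " (untrained)"))
  invisible(x)
}

#' Attribute encoder / decoder forward passes
#'
#' Deterministic row-wise MLP maps between expression space and the latent
#' space.
#'
#' @param X matrix, rows = locations, columns must match the training M.
#' @param Z latent matrix, columns = latent_dim.
#' @param state a `ModelState`.
#' @return `encode_attr`: (rows x latent_dim); `decode_attr`: (rows x M).
#' @export
encode_attr <- function(X, state) mlp_forward(state$attr_enc, X)$out

#' @rdname encode_attr
#' @export
decode_attr <- function(Z, state) mlp_forward(state$attr_dec, Z)$out

# ---- topology encoder: learned positive edge weights + normalized
# message passing (2 rounds) + linear head ----

topo_prepare <- function(X_prime, graph) {
  A <- graph$adjacency
  if (Matrix::nnzero(A) == 0) stop("topology encoder requires a graph with edges")
  s <- Matrix::summary(methods::as(A, "TsparseMatrix"))
  off <- s$i != s$j
  ei <- s$i[off]; ej <- s$j[off]       # directed edges (both directions present)
  d <- if (!is.null(graph$coords))
    sqrt(rowSums((graph$coords[ei, , drop = FALSE] -
                  graph$coords[ej, , drop = FALSE])^2))
  else rep(0, length(ei))
  E <- cbind(X_prime[ei, , drop = FALSE], X_prime[ej, , drop = FALSE], d)
  list(ei = ei, ej = ej, E = E, N = nrow(A))
}

topo_forward <- function(te, X_prime, ctx) {
  N <- ctx$N
  few <- mlp_forward(te$edge_mlp, ctx$E)
  wpre <- as.vector(few$out)
  w <- softplus(wpre)
  cdeg <- rep(1, N)                    # unit self-loop weight
  if (length(ctx$ei)) {
    agg <- rowsum(w, ctx$ei)
    cdeg[as.integer(rownames(agg))] <- 1 + agg[, 1]
  }
  P <- Matrix::sparseMatrix(i = c(ctx$ei, seq_len(N)),
                            j = c(ctx$ej, seq_len(N)),
                            x = c(w, rep(1, N)) / cdeg[c(ctx$ei, seq_len(N))],
                            dims = c(N, N))
  H <- list(X_prime)                   # H[[r]] enters round r
  S <- Z <- vector("list", te$rounds_n)
  for (r in seq_len(te$rounds_n)) {
    S[[r]] <- as.matrix(P %*% H[[r]])
    Z[[r]] <- sweep(cbind(H[[r]], S[[r]]) %*% te$rounds[[r]]$W, 2,
                    te$rounds[[r]]$b, "+")
    H[[r + 1]] <- elu(Z[[r]])
  }
  out <- sweep(H[[te$rounds_n + 1]] %*% te$out$W, 2, te$out$b, "+")
  list(out = out,
       cache = list(few = few, wpre = wpre, w = w, cdeg = cdeg, P = P,
                    H = H, S = S, Z = Z))
}

topo_backward <- function(te, cache, ctx, G) {
  R <- te$rounds_n
  Hlast <- cache$H[[R + 1]]
  g_outW <- crossprod(Hlast, G)
  g_outb <- colSums(G)
  dH <- tcrossprod(G, te$out$W)
  g_rounds <- vector("list", R)
  dw <- rep(0, length(cache$w))
  for (r in rev(seq_len(R))) {
    D <- dH * elu_grad(cache$Z[[r]], cache$H[[r + 1]])
    Hin <- cache$H[[r]]
    g_rounds[[r]] <- list(W = crossprod(cbind(Hin, cache$S[[r]]), D),
                          b = colSums(D))
    dcat <- tcrossprod(D, te$rounds[[r]]$W)
    p <- ncol(Hin)
    dHdir <- dcat[, seq_len(p), drop = FALSE]
    dS <- dcat[, p + seq_len(p), drop = FALSE]
    dH <- dHdir + as.matrix(Matrix::crossprod(cache$P, dS))
    if (length(ctx$ei)) {
      t1 <- rowSums(dS[ctx$ei, , drop = FALSE] * Hin[ctx$ej, , drop = FALSE])
      t2 <- rowSums(dS[ctx$ei, , drop = FALSE] *
                    cache$S[[r]][ctx$ei, , drop = FALSE])
      dw <- dw + (t1 - t2) / cache$cdeg[ctx$ei]
    }
  }
  dwpre <- dw * sigmoid(cache$wpre)    # softplus'
  gedge <- mlp_backward(te$edge_mlp, cache$few$cache,
                        matrix(dwpre, ncol = 1))
  list(edge_mlp = list(gW = gedge$gW, gb = gedge$gb),
       rounds = g_rounds,
       out = list(W = g_outW, b = g_outb))
}

#' Topology encoder forward pass
#'
#' Encodes the spatial graph together with the FP-completed feature matrix:
#' per directed edge, a small MLP on (features of both endpoints, Euclidean
#' distance) yields a positive weight via softplus; node states update over
#' `topo_rounds` rounds of weighted-degree-normalized message passing (unit
#' self-loop) followed by a node MLP, and a final linear map produces the
#' l-dimensional encoding for every node.
#'
#' @param X_prime matrix (N x M) covering all nodes (observed + FP-imputed).
#' @param graph a `SpatialGraph` over the same N nodes.
#' @param state a `ModelState`.
#' @return matrix (N x latent_dim)
#' @export
encode_topo <- function(X_prime, graph, state) {
  if (ncol(X_prime) != state$topo_enc$M)
    stop(sprintf("X_prime has %d features, topology encoder expects %d",
                 ncol(X_prime), state$topo_enc$M))
  ctx <- topo_prepare(as.matrix(X_prime), graph)
  topo_forward(state$topo_enc, as.matrix(X_prime), ctx)$out
}

#' Topology decoder: inner-product adjacency reconstruction
#'
#' `Zhat = MLP(Z)`, `Ahat = sigmoid(Zhat %*% t(Zhat))`. The result is exactly
#' symmetric with entries in (0,1).
#'
#' @param Z latent matrix
#' @param state a `ModelState`
#' @return dense probability matrix Ahat
#' @export
decode_topo <- function(Z, state) {
  Zh <- mlp_forward(state$topo_dec, Z)$out
  sigmoid(tcrossprod(Zh))
}
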