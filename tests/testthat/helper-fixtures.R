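# Shared fixtures: everything is generated in code at test time.

# small model configuration used throughout the unit tests (fast, seeded)
test_cfg <- function(seed = 1L, epochs = 40L, ...) {
  stweave_config(latent_dim = 6L, attr_hidden = c(16L, 8L), topo_hidden = 8L,
                 edge_hidden = 6L, topo_dec_hidden = 8L,
                 disc_hidden = c(8L, 6L), epochs = epochs, seed = seed, ...)
}

# the configuration used for the full-scale planted-domain runs
acc_cfg <- function(seed = 1L, epochs = 150L, ...) {
  stweave_config(latent_dim = 16L, attr_hidden = c(64L, 32L),
                 topo_hidden = 32L, edge_hidden = 16L, topo_dec_hidden = 32L,
                 disc_hidden = c(32L, 16L), epochs = epochs,
                 neg_pos_ratio = 2, full_adj_threshold = 300L,
                 seed = seed, ...)
}

# small hex-lattice planted-stripes dataset, preprocessed, with graph
make_small_pipeline <- function(n_side = 8L, n_domains = 2L, n_genes = 20L,
                                n_pcs = 6L, seed = 11L, layout = "stripes") {
  spec <- synthetic_spec(lattice = "hex", n_side = n_side, layout = layout,
                         n_domains = n_domains, n_genes = n_genes,
                         n_markers_per_domain = 3L, seed = seed)
  sim <- generate_synthetic(spec)
  dsp <- preprocess(sim$dataset, n_pcs = n_pcs, seed = seed)
  graph <- build_graph(dsp, method = "distance", param = 1.05)
  list(sim = sim, ds = dsp, graph = graph)
}

# an Erdos-Renyi-style random connected undirected graph as a SpatialGraph
random_connected_graph <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    A <- matrix(stats::runif(n * n) < p, n, n)
    A[lower.tri(A, diag = TRUE)] <- FALSE
    A <- A | t(A)
    mode(A) <- "numeric"
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    if (igraph::is_connected(g)) break
  }
  As <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                                "generalMatrix"), "CsparseMatrix")
  ids <- paste0("n", seq_len(n))
  dimnames(As) <- list(ids, ids)
  structure(list(adjacency = As, method = "knn", param = NA,
                 self_loops = FALSE, node_status = rep("observed", n),
                 location_ids = ids,
                 coords = cbind(seq_len(n), 0)),
            class = "SpatialGraph")
}

# independent oracle: harmonic interpolation by direct dense linear solve
harmonic_solve <- function(A, X_obs, obs_mask) {
  A <- as.matrix(A)
  N <- nrow(A)
  Ahat <- A + diag(N)
  P <- Ahat / rowSums(Ahat)
  u <- which(!obs_mask); o <- which(obs_mask)
  if (!length(u)) return(X_obs)
  # x_u = (I - P_uu)^{-1} P_uo x_o
  Puu <- P[u, u, drop = FALSE]
  Puo <- P[u, o, drop = FALSE]
  Xu <- solve(diag(length(u)) - Puu, Puo %*% X_obs[o, , drop = FALSE])
  X <- X_obs
  X[u, ] <- Xu
  X
}

# independent oracle: ARI by explicit pair counting
ari_pair_counting <- function(a, b) {
  n <- length(a)
  s00 <- s01 <- s10 <- s11 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (sa && !sb) s10 <- s10 + 1
    else if (!sa && sb) s01 <- s01 + 1
    else s00 <- s00 + 1
  }
  np <- s11 + s10 + s01 + s00
  expected <- (s11 + s10) * (s11 + s01) / np
  maxi <- ((s11 + s10) + (s11 + s01)) / 2
  if (maxi == expected) return(1)
  (s11 - expected) / (maxi - expected)
}
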