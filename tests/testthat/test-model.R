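make_state <- function(M = 5, seed = 13, ...) {
  cfg <- test_cfg(seed = seed, ...)
  stweave:::init_model_state(M, cfg)
}

test_that("attribute encoder is a deterministic row-wise map", {
  st <- make_state()
  X <- matrix(rnorm(4 * 5), 4, 5)
  Z <- encode_attr(X, st)
  expect_equal(dim(Z), c(4L, 6L))
  expect_identical(Z, encode_attr(X, st))

  # zeroing the final layer zeroes all encodings
  st0 <- st
  L <- length(st0$attr_enc$W)
  st0$attr_enc$W[[L]][] <- 0
  st0$attr_enc$b[[L]][] <- 0
  expect_true(all(encode_attr(X, st0) == 0))

  # duplicated rows encode identically; permutations commute
  Z2 <- encode_attr(X[c(1, 1, 3, 2, 4), ], st)
  expect_identical(Z2[1, ], Z2[2, ])
  perm <- c(3, 1, 4, 2)
  expect_identical(encode_attr(X[perm, ], st), Z[perm, ])
  expect_error(encode_attr(X[, 1:3], st), "column")
})

test_that("attribute decoder honors identity construction and stays finite", {
  cfg <- test_cfg()
  st <- stweave:::init_model_state(6, cfg)
  # identity toy decoder: single linear layer l=M=6, W=I, b=0
  st$attr_dec <- stweave:::mlp_init(6, integer(0), 6)
  st$attr_dec$W[[1]] <- diag(6)
  st$attr_dec$b[[1]][] <- 0
  Z <- matrix(rnorm(3 * 6), 3, 6)
  expect_equal(decode_attr(Z, st), Z)
  big <- matrix(1e6, 2, 6)
  expect_true(all(is.finite(decode_attr(big, st))))
})

test_that("topology decoder output is symmetric, in (0,1), 0.5 at zero", {
  st <- make_state()
  # force the decoder MLP to output zeros
  L <- length(st$topo_dec$W)
  st$topo_dec$W[[L]][] <- 0
  st$topo_dec$b[[L]][] <- 0
  A_hat <- decode_topo(matrix(rnorm(12), 2, 6), st)
  expect_true(all(A_hat == 0.5))

  st2 <- make_state(seed = 14)
  A_hat2 <- decode_topo(matrix(rnorm(5 * 6), 5, 6), st2)
  expect_identical(A_hat2, t(A_hat2))
  expect_true(all(A_hat2 > 0 & A_hat2 < 1))

  # orthogonal unit rows after the MLP: check the inner-product stage directly
  Zh <- diag(3)
  P <- stweave:::sigmoid(tcrossprod(Zh))
  expect_true(all(P[upper.tri(P)] == 0.5))
  expect_equal(unname(diag(P)), rep(stweave:::sigmoid(1), 3))
})

test_that("topology encoder respects graph symmetries", {
  # constant features on a cycle (vertex-transitive) -> identical encodings
  n <- 8
  A <- Matrix::sparseMatrix(i = seq_len(n), j = c(2:n, 1), x = 1, dims = c(n, n))
  A <- methods::as(A + Matrix::t(A), "CsparseMatrix")
  theta <- 2 * pi * seq_len(n) / n
  g <- structure(list(adjacency = A, method = "knn", param = 2,
                      self_loops = FALSE, node_status = rep("observed", n),
                      location_ids = paste0("n", seq_len(n)),
                      coords = NULL),  # constant edge distance not needed
                 class = "SpatialGraph")
  st <- make_state(M = 3, seed = 15)
  X <- matrix(1, n, 3)
  Z <- encode_topo(X, g, st)
  expect_lt(max(abs(sweep(Z, 2, Z[1, ]))), 1e-10)

  # two isomorphic disconnected components with identical features
  A2 <- Matrix::bdiag(A, A)
  g2 <- structure(list(adjacency = methods::as(A2, "CsparseMatrix"),
                       method = "knn", param = 2, self_loops = FALSE,
                       node_status = rep("observed", 2 * n),
                       location_ids = paste0("n", seq_len(2 * n)),
                       coords = NULL),
                  class = "SpatialGraph")
  set.seed(3)
  X1 <- matrix(rnorm(n * 3), n, 3)
  Z2 <- encode_topo(rbind(X1, X1), g2, st)
  expect_equal(Z2[seq_len(n), ], Z2[n + seq_len(n), ], tolerance = 1e-12)

  # zero-edge graph is rejected
  g0 <- g; g0$adjacency <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                                dims = c(n, n))
  expect_error(encode_topo(X, g0, st), "edges")
})

test_that("attribute loss reproduces hand-computed values", {
  st <- make_state(M = 2)
  # identity decoder so predictions equal latent inputs padded: build exact
  st$attr_dec <- stweave:::mlp_init(2, integer(0), 2)
  st$attr_dec$W[[1]] <- diag(2); st$attr_dec$b[[1]][] <- 0
  X_o <- matrix(c(1, 0, 0, 1), 2, 2)

  # decoder outputs exactly X_o from both encodings -> 0
  expect_equal(loss_attr(X_o, X_o, X_o, st, lambda_cross = 1), 0)

  # all-zero decoded outputs, lambda 1 -> (1/4)*2 + (1/4)*2 = 1
  Z0 <- matrix(0, 2, 2)
  expect_equal(loss_attr(X_o, Z0, Z0, st, lambda_cross = 1), 1.0)

  # lambda 0 -> plain self-reconstruction MSE
  set.seed(2)
  Zr <- matrix(rnorm(4), 2, 2)
  expect_equal(loss_attr(X_o, Zr, Z0, st, lambda_cross = 0),
               mean((X_o - Zr)^2))
})

test_that("topology loss reproduces hand-computed BCE values", {
  # all predictions 0.5 -> ln 2 per entry
  expect_equal(loss_topo(c(1, 0, 1), rep(0.5, 3), lambda_cross = 0), log(2))
  # predictions equal to clipped targets -> epsilon-level loss
  expect_lt(loss_topo(c(1, 0), c(1, 0), lambda_cross = 0), 1e-6)
  # hand-computed: targets [1,0], preds [0.8,0.2] -> -(ln .8 + ln .8)/2
  expect_equal(loss_topo(c(1, 0), c(0.8, 0.2), lambda_cross = 0),
               -(log(0.8) + log(0.8)) / 2, tolerance = 1e-12)
  # cross term scales with lambda
  expect_equal(
    loss_topo(c(1, 0), c(0.8, 0.2), targets_cross = c(1), p_cross = c(0.5),
              lambda_cross = 2),
    -(log(0.8) + log(0.8)) / 2 + 2 * log(2), tolerance = 1e-12)
})

test_that("adversarial loss reproduces its closed forms", {
  expect_equal(loss_adv(0.5, 0.5, 0.5), 4 * log(2), tolerance = 1e-9)
  expect_equal(loss_adv(0.9, 0.1, 0.1),
               2 * (-log(0.9)) + (-log(0.9)) + (-log(0.9)),
               tolerance = 1e-12)
  # discriminator optimum: D -> 1 on prior, 0 on encodings
  expect_lt(loss_adv(1 - 1e-9, 1e-9, 1e-9), 1e-5)
})

test_that("partial adjacency sampling is seeded and recovers the full BCE", {
  g <- random_connected_graph(n = 12, p = 0.3, seed = 6)
  s1 <- sample_partial_adjacency(g, m = 5, neg_pos_ratio = 1, seed = 42)
  s2 <- sample_partial_adjacency(g, m = 5, neg_pos_ratio = 1, seed = 42)
  expect_identical(s1, s2)
  expect_equal(sum(s1$target), 5)
  A <- as.matrix(g$adjacency)
  expect_true(all(A[s1$pairs[s1$target == 1, , drop = FALSE]] == 1))
  expect_true(all(A[s1$pairs[s1$target == 0, , drop = FALSE]] == 0))
  expect_error(sample_partial_adjacency(g, m = 1e6), "exceeds")

  # exhaustive sample reproduces the full-matrix BCE exactly
  n_edges <- s1$n_pos_total
  sx <- sample_partial_adjacency(g, m = n_edges, neg_pos_ratio = 1e6, seed = 1)
  set.seed(7)
  P <- matrix(runif(144, 0.05, 0.95), 12, 12)
  P[lower.tri(P)] <- t(P)[lower.tri(P)]
  p_entries <- P[sx$pairs]
  expect_equal(bce_stratified(sx, p_entries), bce_full(A, P),
               tolerance = 1e-12)
})

test_that("stratified subsampled BCE is unbiased over repeated draws", {
  g <- random_connected_graph(n = 20, p = 0.25, seed = 9)
  A <- as.matrix(g$adjacency)
  set.seed(11)
  P <- matrix(runif(400, 0.05, 0.95), 20, 20)
  P[lower.tri(P)] <- t(P)[lower.tri(P)]
  full <- bce_full(A, P)
  m <- min(10, sum(A[upper.tri(A)]))
  ests <- vapply(1:1000, function(k) {
    s <- sample_partial_adjacency(g, m = m, neg_pos_ratio = 1, seed = k)
    bce_stratified(s, P[s$pairs])
  }, numeric(1))
  expect_lt(abs(mean(ests) - full) / full, 0.02)
})

test_that("full AE objective gradient matches finite differences", {
  pl <- make_small_pipeline(n_side = 4, n_genes = 10, n_pcs = 3, seed = 17)
  ds <- pl$ds; graph <- pl$graph
  cfg <- stweave_config(latent_dim = 3, attr_hidden = 5, topo_hidden = 4,
                        edge_hidden = 3, topo_dec_hidden = 4, disc_hidden = 4,
                        epochs = 1, lambda_cross = 0.7, lambda_adv = 0.3,
                        seed = 19)
  st <- stweave:::init_model_state(ncol(ds$expr), cfg)
  obs <- observed_idx(ds)
  X_o <- ds$expr[obs, , drop = FALSE]
  Xp <- ds$expr
  ctx <- stweave:::topo_prepare(Xp, graph)
  T_self <- as.matrix(graph$adjacency)
  T_cross <- T_self[obs, obs]

  objective <- function(stt) {
    Z_Xo <- encode_attr(X_o, stt)
    Z_A <- stweave:::topo_forward(stt$topo_enc, Xp, ctx)$out
    Z_Ao <- Z_A[obs, , drop = FALSE]
    nMo <- length(X_o)
    l_attr <- sum((X_o - decode_attr(Z_Xo, stt))^2) / nMo +
      cfg$lambda_cross * sum((X_o - decode_attr(Z_Ao, stt))^2) / nMo
    ZhA <- stweave:::mlp_forward(stt$topo_dec, Z_A)$out
    ZhX <- stweave:::mlp_forward(stt$topo_dec, Z_Xo)$out
    l_topo <- stweave:::adj_bce_full(ZhA, T_self)$loss +
      cfg$lambda_cross * stweave:::adj_bce_full(ZhX, T_cross)$loss
    sX <- as.vector(stweave:::mlp_forward(stt$disc, Z_Xo)$out)
    sA <- as.vector(stweave:::mlp_forward(stt$disc, Z_A)$out)
    l_gen <- mean(stweave:::softplus(-sX)) + mean(stweave:::softplus(-sA))
    l_attr + l_topo + cfg$lambda_adv * l_gen
  }

  # analytic gradient via one AE step with lr=0 equivalents: reuse internals
  feX <- stweave:::mlp_forward(st$attr_enc, X_o)
  ft <- stweave:::topo_forward(st$topo_enc, Xp, ctx)
  Z_Xo <- feX$out; Z_A <- ft$out; Z_Ao <- Z_A[obs, , drop = FALSE]
  nMo <- length(X_o)
  gZx <- matrix(0, nrow(Z_Xo), 3); gZa <- matrix(0, nrow(Z_A), 3)
  fd1 <- stweave:::mlp_forward(st$attr_dec, Z_Xo)
  b1 <- stweave:::mlp_backward(st$attr_dec, fd1$cache, 2 * (fd1$out - X_o) / nMo)
  gZx <- gZx + b1$gin
  fd2 <- stweave:::mlp_forward(st$attr_dec, Z_Ao)
  b2 <- stweave:::mlp_backward(st$attr_dec, fd2$cache,
                               cfg$lambda_cross * 2 * (fd2$out - X_o) / nMo)
  gZa[obs, ] <- gZa[obs, ] + b2$gin
  fza <- stweave:::mlp_forward(st$topo_dec, Z_A)
  ra <- stweave:::adj_bce_full(fza$out, T_self)
  bt <- stweave:::mlp_backward(st$topo_dec, fza$cache, ra$gZh)
  gZa <- gZa + bt$gin
  fzx <- stweave:::mlp_forward(st$topo_dec, Z_Xo)
  rc <- stweave:::adj_bce_full(fzx$out, T_cross)
  btc <- stweave:::mlp_backward(st$topo_dec, fzx$cache, cfg$lambda_cross * rc$gZh)
  gZx <- gZx + btc$gin
  for (wz in c("x", "a")) {
    Z <- if (wz == "x") Z_Xo else Z_A
    fd <- stweave:::mlp_forward(st$disc, Z)
    s <- as.vector(fd$out)
    bg <- stweave:::mlp_backward(st$disc, fd$cache,
                                 matrix((stweave:::sigmoid(s) - 1) / length(s),
                                        ncol = 1))
    if (wz == "x") gZx <- gZx + cfg$lambda_adv * bg$gin
    else gZa <- gZa + cfg$lambda_adv * bg$gin
  }
  be <- stweave:::mlp_backward(st$attr_enc, feX$cache, gZx)
  bt2 <- stweave:::topo_backward(st$topo_enc, ft$cache, ctx, gZa)
  analytic <- stweave:::params_flatten(list(
    attr_enc = list(W = be$gW, b = be$gb),
    topo_edge = list(W = bt2$edge_mlp$gW, b = bt2$edge_mlp$gb),
    topo_rounds = bt2$rounds,
    topo_out = bt2$out))

  flat <- stweave:::params_flatten(stweave:::ae_skeleton(st))
  eps <- 1e-5
  set.seed(23)
  for (k in intersect(names(analytic), names(flat))) {
    for (ii in sample(length(flat[[k]]), min(2, length(flat[[k]])))) {
      fp <- flat; fp[[k]][ii] <- fp[[k]][ii] + eps
      fm <- flat; fm[[k]][ii] <- fm[[k]][ii] - eps
      stp <- stweave:::ae_write_back(st, stweave:::params_apply(
        stweave:::ae_skeleton(st), fp))
      stm <- stweave:::ae_write_back(st, stweave:::params_apply(
        stweave:::ae_skeleton(st), fm))
      num <- (objective(stp) - objective(stm)) / (2 * eps)
      expect_equal(analytic[[k]][ii], num, tolerance = 1e-4)
    }
  }
})
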