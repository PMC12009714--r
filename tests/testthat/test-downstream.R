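fake_bundle <- function(Z_obs, Z_inf, l = ncol(Z_obs)) {
  n_o <- nrow(Z_obs); n_i <- nrow(Z_inf)
  ids <- c(paste0("o", seq_len(n_o)), paste0("i", seq_len(n_i)))
  full <- rbind(Z_obs, Z_inf)
  rownames(full) <- ids
  structure(list(ATTR = Z_obs, ATTR_FP = Z_inf, ATTR_full = full,
                 TOPO = full, COMB = cbind(full, full),
                 source_flag = c(rep("observed", n_o), rep("inferred", n_i)),
                 location_ids = ids),
            class = "EncodingBundle")
}

test_that("label propagation assigns blob labels to inferred points", {
  set.seed(51)
  Zo <- rbind(matrix(rnorm(40, 0, 0.2), 20, 2),
              matrix(rnorm(40, 5, 0.2), 20, 2))
  lab <- rep(c("A", "B"), each = 20)
  Zi <- rbind(matrix(rnorm(10, 0, 0.2), 5, 2),
              matrix(rnorm(10, 5, 0.2), 5, 2))
  b <- fake_bundle(Zo, Zi)
  out <- propagate_labels(b, lab, encoding = "TOPO", k = 5)
  expect_identical(unname(out[b$source_flag == "inferred"]),
                   rep(c("A", "B"), each = 5))
  expect_identical(unname(out[b$source_flag == "observed"]), lab)

  # k = 1 is the single nearest observed label
  out1 <- propagate_labels(b, lab, encoding = "TOPO", k = 1)
  nn <- apply(as.matrix(dist(rbind(Zi, Zo)))[seq_len(10), -seq_len(10)], 1,
              which.min)
  expect_identical(unname(out1[b$source_flag == "inferred"]), lab[nn])
  expect_error(propagate_labels(b, lab, k = 100), "exceeds")
})

test_that("expression padding recovers a linear latent function", {
  set.seed(53)
  Zo <- matrix(rnorm(120 * 4), 120, 4)
  Zi <- matrix(rnorm(30 * 4), 30, 4)
  b <- fake_bundle(Zo, Zi)
  y_obs <- 2 * Zo[, 1] - 3 * Zo[, 2]
  y_inf <- 2 * Zi[, 1] - 3 * Zi[, 2]
  expr_obs <- cbind(lin = y_obs, flat = rep(1, 120))
  expect_warning(
    px <- pad_expression(b, expr_obs, encoding = "TOPO", seed = 1),
    "constant")
  # held-out R^2 on the inferred points
  r2 <- 1 - sum((y_inf - px$pred[, "lin"])^2) / sum((y_inf - mean(y_inf))^2)
  expect_gt(r2, 0.9)
  expect_true(px$constant[["flat"]])
  expect_true(is.na(px$train_r2[["flat"]]))
  expect_true(all(px$pred[, "flat"] == 1))
  # in-sample never worse than predicting the mean
  expect_true(px$train_r2[["lin"]] >= 0)
  expect_error(pad_expression(b, expr_obs, genes = "nope"), "valid names")
})

test_that("averaged-KNN baseline equals neighbor means with fallback", {
  co <- cbind(c(0, 1, 2, 10), c(0, 0, 0, 0))
  expr <- matrix(c(2, NA, 4, 6), 4, 1)
  ds <- spatial_dataset(expr, co, status = c("observed", "padding",
                                             "observed", "observed"))
  A <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 3), x = 1, dims = c(4, 4))
  g <- structure(list(adjacency = methods::as(A + Matrix::t(A), "CsparseMatrix"),
                      method = "distance", param = 1.2, self_loops = FALSE,
                      node_status = ds$status, location_ids = ds$location_ids,
                      coords = co),
                 class = "SpatialGraph")
  kb <- baseline_knn_average(ds, g)
  expect_equal(unname(kb$pred[1, 1]), 3)  # mean of 2 and 4
  expect_false(kb$fallback[[1]])

  # isolated target -> coordinate fallback flagged
  ds2 <- spatial_dataset(matrix(c(2, 4, NA), 3, 1),
                         cbind(c(0, 1, 50), c(0, 0, 0)),
                         status = c("observed", "observed", "padding"))
  A2 <- Matrix::sparseMatrix(i = 1, j = 2, x = 1, dims = c(3, 3))
  g2 <- structure(list(adjacency = methods::as(A2 + Matrix::t(A2), "CsparseMatrix"),
                       method = "distance", param = 1.2, self_loops = FALSE,
                       node_status = ds2$status, location_ids = ds2$location_ids,
                       coords = ds2$coords),
                  class = "SpatialGraph")
  kb2 <- baseline_knn_average(ds2, g2, k = 2)
  expect_true(kb2$fallback[[1]])
  expect_equal(unname(kb2$pred[1, 1]), 3)
})

test_that("averaged-KNN equals one FP sweep when all neighbors are observed", {
  pl <- make_small_pipeline(n_side = 5, n_genes = 6, n_pcs = NULL, seed = 55)
  ds <- pl$sim$dataset
  dsm <- apply_mask(ds, ids = ds$location_ids[7], seed = 1)
  g <- build_graph(dsm, method = "distance", param = 1.05)
  kb <- baseline_knn_average(dsm, g)
  fp1 <- propagate_features(dsm$expr, g, dsm$status == "observed",
                            max_iter = 1, tol = 1e-12)
  i <- which(dsm$status == "masked")
  # one diffusion sweep mixes the (mean-initialized) self state in; the
  # neighbor average equals the sweep after removing that self term
  deg <- sum(g$adjacency[i, ])
  mu <- colMeans(dsm$expr[dsm$status == "observed", ])
  sweep1 <- (fp1$X_full[i, ] * (deg + 1) - mu) / deg
  expect_equal(unname(kb$pred[1, ]), unname(sweep1), tolerance = 1e-12)
})

test_that("clustering recovers separated Gaussians and co-assigns duplicates", {
  set.seed(57)
  Z <- rbind(matrix(rnorm(60, 0, 0.3), 30, 2),
             matrix(rnorm(60, 6, 0.3), 30, 2),
             cbind(rnorm(30, 0, 0.3), rnorm(30, 12, 0.3)))
  truth <- rep(1:3, each = 30)
  cl <- cluster_encoding(Z, "gmm", n_clusters = 3, seed = 1)
  expect_equal(eval_ari(cl, truth), 1.0)
  cl_k <- cluster_encoding(Z, "kmeans", n_clusters = 3, seed = 1)
  expect_equal(eval_ari(cl_k, truth), 1.0)

  Zdup <- rbind(Z, Z[1:5, ])
  cl2 <- cluster_encoding(Zdup, "gmm", n_clusters = 3, seed = 1)
  expect_identical(cl2[nrow(Z) + 1:5], cl2[1:5])
})

test_that("leiden cluster count is non-decreasing in resolution", {
  set.seed(59)
  Z <- rbind(matrix(rnorm(80, 0, 0.5), 40, 2),
             matrix(rnorm(80, 4, 0.5), 40, 2),
             matrix(rnorm(80, c(4, -4), 0.5), 40, 2))
  k1 <- length(unique(cluster_encoding(Z, "leiden", resolution = 0.1, seed = 2)))
  k2 <- length(unique(cluster_encoding(Z, "leiden", resolution = 1.0, seed = 2)))
  expect_lte(k1, k2)
  k_lv <- length(unique(cluster_encoding(Z, "louvain", resolution = 0.4, seed = 2)))
  expect_gte(k_lv, 2)
})

test_that("agreement metrics match brute-force pair counting", {
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 2, 2, 2)
  expect_equal(eval_ari(a, b), ari_pair_counting(a, b), tolerance = 1e-12)
  expect_equal(eval_ari(a, a), 1)
  expect_equal(eval_nmi(a, a), 1)

  # invariance to label permutation
  b_perm <- c(2, 2, 1, 1, 1, 1)
  expect_equal(eval_ari(a, b), eval_ari(a, b_perm))
  expect_equal(eval_nmi(a, b), eval_nmi(a, b_perm))

  # NMI against direct entropy computation
  ct <- table(a, b) / 6
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  mi <- h(rowSums(ct)) + h(colSums(ct)) - h(as.vector(ct))
  expect_equal(eval_nmi(a, b), mi / ((h(rowSums(ct)) + h(colSums(ct))) / 2),
               tolerance = 1e-12)

  # internal metrics behave on an obvious two-cluster embedding
  Z <- rbind(matrix(0, 5, 2), matrix(10, 5, 2)) + rnorm(20, 0, 0.01)
  lab <- rep(1:2, each = 5)
  expect_gt(eval_silhouette(Z, lab), 0.9)
  expect_gt(eval_ch(Z, lab), 100)
  expect_equal(eval_acc(c("a", "b"), c("a", "c")), 0.5)
  expect_equal(eval_mse(c(1, 2), c(1, 4)), 2)
})

test_that("masking benchmark validates rates and returns the full grid", {
  pl <- make_small_pipeline(n_side = 6, n_genes = 12, seed = 61)
  expect_error(masking_benchmark(pl$sim$dataset, pl$sim$labels, rates = 0,
                                 seeds = 1), "rates")
  tab <- masking_benchmark(pl$sim$dataset, pl$sim$labels, rates = 0.2,
                           seeds = 1, cfg = test_cfg(epochs = 10),
                           n_pcs = 4, genes = pl$sim$markers$gene[1:3])
  expect_equal(nrow(tab), 3)   # |rates| x |seeds| x 3 methods
  expect_setequal(tab$method, c("stweave", "fp", "knn_average"))
  expect_true(all(is.finite(tab$MSE)))
})
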