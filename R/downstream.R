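# Downstream analyses on the latent encodings: label propagation to inferred
# locations, gene-expression padding via gradient-boosted trees, clustering,
# and evaluation metrics.

bundle_matrix <- function(bundle, encoding = c("COMB", "ATTR", "TOPO")) {
  encoding <- match.arg(encoding)
  switch(encoding, COMB = bundle$COMB, TOPO = bundle$TOPO,
         ATTR = bundle$ATTR_full)
}

#' Propagate labels from observed to inferred locations
#'
#' Each padding/masked location receives the majority label of its `k`
#' nearest observed locations in the chosen latent space (Euclidean); ties
#' are broken by the label of the single nearest observed neighbor.
#'
#' @param bundle an [extract_encodings()] bundle
#' @param labels_obs labels for the observed locations (named by location id
#'   or in observed-row order)
#' @param encoding latent space to measure distances in
#' @param k neighborhood size (default 15)
#' @return character vector of labels for all locations, in bundle row order
#' @export
propagate_labels <- function(bundle, labels_obs,
                             encoding = c("COMB", "ATTR", "TOPO"), k = 15L) {
  Z <- bundle_matrix(bundle, match.arg(encoding))
  obs <- which(bundle$source_flag == "observed")
  inf <- which(bundle$source_flag == "inferred")
  if (k < 1) stop("k must be >= 1")
  if (k > length(obs)) stop("k exceeds the number of observed locations")
  labels_obs <- as.character(labels_obs)
  if (!is.null(names(labels_obs)))
    labels_obs <- labels_obs[bundle$location_ids[obs]]
  if (length(labels_obs) != length(obs))
    stop("labels_obs must cover every observed location")
  out <- rep(NA_character_, nrow(Z))
  out[obs] <- labels_obs
  if (length(inf)) {
    Zo <- Z[obs, , drop = FALSE]
    Zi <- Z[inf, , drop = FALSE]
    d2 <- outer(rowSums(Zi^2), rowSums(Zo^2), "+") - 2 * Zi %*% t(Zo)
    for (r in seq_along(inf)) {
      ord <- order(d2[r, ], seq_along(obs))[seq_len(k)]
      votes <- table(labels_obs[ord])
      top <- names(votes)[votes == max(votes)]
      out[inf[r]] <- if (length(top) == 1) top else labels_obs[ord[1]]
    }
  }
  names(out) <- bundle$location_ids
  out
}

#' Predict gene expression at inferred locations via boosted trees
#'
#' Fits one gradient-boosted regression-tree model per gene on
#' (latent encoding -> observed expression) and predicts at inferred
#' (padding/masked) locations. Constant genes are predicted as their
#' constant with a warning, and flagged with `NA` training R-squared.
#'
#' @param bundle an [extract_encodings()] bundle
#' @param expr_obs observed expression matrix (observed locations x genes);
#'   row order must match the observed rows of the bundle
#' @param genes gene (column) names to pad; default all
#' @param encoding latent space used as features
#' @param nrounds,max_depth,eta boosted-tree settings
#' @param seed integer seed
#' @return list: `pred` (inferred locations x genes), `train_r2` per gene,
#'   `constant` logical per gene
#' @export
pad_expression <- function(bundle, expr_obs, genes = NULL,
                           encoding = c("COMB", "ATTR", "TOPO"),
                           nrounds = 200L, max_depth = 4L, eta = 0.1,
                           seed = 1L) {
  Z <- bundle_matrix(bundle, match.arg(encoding))
  obs <- which(bundle$source_flag == "observed")
  inf <- which(bundle$source_flag == "inferred")
  expr_obs <- as.matrix(expr_obs)
  if (nrow(expr_obs) != length(obs))
    stop("expr_obs must have one row per observed location")
  if (length(obs) < 20) stop("need at least 20 observed locations")
  if (is.null(genes)) genes <- colnames(expr_obs)
  missing_g <- setdiff(genes, colnames(expr_obs))
  if (length(missing_g))
    stop("unknown genes: ", paste(missing_g, collapse = ", "),
         "; valid names include ",
         paste(utils::head(colnames(expr_obs), 5), collapse = ", "))
  Zo <- Z[obs, , drop = FALSE]
  Zi <- Z[inf, , drop = FALSE]
  pred <- matrix(NA_real_, length(inf), length(genes),
                 dimnames = list(bundle$location_ids[inf], genes))
  r2 <- stats::setNames(rep(NA_real_, length(genes)), genes)
  const <- stats::setNames(rep(FALSE, length(genes)), genes)
  for (g in genes) {
    y <- expr_obs[, g]
    if (stats::var(y) == 0) {
      const[g] <- TRUE
      pred[, g] <- y[1]
      warning("gene ", g, " is constant over observed locations; predicting the constant")
      next
    }
    fit <- xgboost::xgboost(Zo, y, nrounds = nrounds,
                            max_depth = max_depth, learning_rate = eta,
                            objective = "reg:squarederror",
                            nthreads = 1, seed = as.integer(seed),
                            verbosity = 0)
    yhat <- stats::predict(fit, Zo)
    r2[g] <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
    if (length(inf)) pred[, g] <- stats::predict(fit, Zi)
  }
  list(pred = pred, train_r2 = r2, constant = const)
}

#' Averaged-KNN baseline for expression padding
#'
#' Predicts expression at an inferred location as the mean over its
#' graph-adjacent observed neighbors; locations with no observed neighbor
#' fall back to the mean of their `k` coordinate-space nearest observed
#' locations and are flagged.
#'
#' @param ds a `SpatialDataset` (expression rows at observed locations used)
#' @param graph a `SpatialGraph` over the same locations
#' @param targets indices or ids of locations to predict (default: all
#'   non-observed)
#' @param k coordinate-KNN fallback size
#' @return list: `pred` matrix (targets x features), `fallback` logical
#' @export
baseline_knn_average <- function(ds, graph, targets = NULL, k = 6L) {
  obs <- observed_idx(ds)
  if (is.null(targets)) targets <- which(ds$status != "observed")
  if (is.character(targets)) targets <- match(targets, ds$location_ids)
  A <- graph$adjacency
  Xo <- ds$expr[obs, , drop = FALSE]
  pred <- matrix(NA_real_, length(targets), ncol(ds$expr),
                 dimnames = list(ds$location_ids[targets], ds$feature_ids))
  fallback <- stats::setNames(rep(FALSE, length(targets)),
                              ds$location_ids[targets])
  co <- ds$coords
  for (t in seq_along(targets)) {
    i <- targets[t]
    nb <- intersect(which(A[i, ] > 0), obs)
    if (length(nb)) {
      pred[t, ] <- colMeans(ds$expr[nb, , drop = FALSE])
    } else {
      fallback[t] <- TRUE
      d2 <- rowSums(sweep(co[obs, , drop = FALSE], 2, co[i, ])^2)
      nn <- obs[order(d2, seq_along(obs))[seq_len(min(k, length(obs)))]]
      pred[t, ] <- colMeans(ds$expr[nn, , drop = FALSE])
    }
  }
  list(pred = pred, fallback = fallback)
}

#' Cluster a latent encoding
#'
#' @param Z encoding matrix (locations x dims)
#' @param method `"gmm"` (Gaussian mixture via mclust, the model family the
#'   reference analyses use), `"leiden"`/`"louvain"` (community detection on
#'   a 15-NN latent graph at the given `resolution`), or `"kmeans"`.
#' @param n_clusters number of clusters (gmm/kmeans)
#' @param resolution resolution parameter (leiden/louvain; default 0.4)
#' @param knn neighbors for the latent graph (leiden/louvain)
#' @param seed integer seed
#' @return integer cluster labels, one per row of `Z`
#' @export
cluster_encoding <- function(Z, method = c("gmm", "leiden", "louvain", "kmeans"),
                             n_clusters = NULL, resolution = 0.4, knn = 15L,
                             seed = 1L) {
  method <- match.arg(method)
  Z <- as.matrix(Z)
  set.seed(as.integer(seed))
  if (method == "gmm") {
    if (is.null(n_clusters)) stop("gmm requires n_clusters")
    fit <- mclust::Mclust(Z, G = n_clusters, verbose = FALSE)
    if (is.null(fit)) stop("mclust failed to fit a mixture model")
    return(as.integer(fit$classification))
  }
  if (method == "kmeans") {
    if (is.null(n_clusters)) stop("kmeans requires n_clusters")
    return(as.integer(stats::kmeans(Z, centers = n_clusters, nstart = 10)$cluster))
  }
  g <- latent_knn_graph(Z, knn)
  comm <- if (method == "louvain")
    igraph::cluster_louvain(g, resolution = resolution)
  else
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution)
  as.integer(igraph::membership(comm))
}

latent_knn_graph <- function(Z, k) {
  n <- nrow(Z)
  k <- min(k, n - 1)
  D <- as.matrix(stats::dist(Z))
  diag(D) <- Inf
  idx <- t(apply(D, 1, function(d) order(d)[seq_len(k)]))
  el <- cbind(rep(seq_len(n), each = k), as.vector(t(idx)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g)
}

# ---- evaluation metrics ----

#' Clustering and imputation evaluation metrics
#'
#' `eval_ari`/`eval_nmi` compare two labelings (ARI via adjusted pair
#' counting, NMI with arithmetic-mean normalization); `eval_silhouette` and
#' `eval_ch` are internal quality scores of a labeling on an embedding;
#' `eval_acc` is the fraction of correct labels; `eval_mse` the mean squared
#' error of imputed expression.
#'
#' @param a,b label vectors of equal length
#' @param Z embedding matrix
#' @param labels labels for the rows of `Z`
#' @param truth,pred matrices or vectors of equal shape
#' @return scalar metric value
#' @export
eval_ari <- function(a, b) mclust::adjustedRandIndex(a, b)

#' @rdname eval_ari
#' @export
eval_nmi <- function(a, b) {
  ct <- table(a, b)
  n <- sum(ct)
  pij <- ct / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  denom <- (h(pi_) + h(pj_)) / 2
  if (denom == 0) return(1)
  mi / denom
}

#' @rdname eval_ari
#' @export
eval_silhouette <- function(Z, labels) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2) return(NA_real_)
  mean(cluster::silhouette(labels, stats::dist(Z))[, 3])
}

#' @rdname eval_ari
#' @export
eval_ch <- function(Z, labels) {
  Z <- as.matrix(Z)
  labels <- as.integer(factor(labels))
  k <- length(unique(labels)); n <- nrow(Z)
  if (k < 2 || k >= n) return(NA_real_)
  mu <- colMeans(Z)
  ssb <- ssw <- 0
  for (c in unique(labels)) {
    Zi <- Z[labels == c, , drop = FALSE]
    mui <- colMeans(Zi)
    ssb <- ssb + nrow(Zi) * sum((mui - mu)^2)
    ssw <- ssw + sum(sweep(Zi, 2, mui)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' @rdname eval_ari
#' @export
eval_acc <- function(truth, pred) mean(as.character(truth) == as.character(pred))

#' @rdname eval_ari
#' @export
eval_mse <- function(truth, pred) mean((as.matrix(truth) - as.matrix(pred))^2)

#' Masking-robustness benchmark
#'
#' For every (rate, seed) combination: masks that fraction of observed
#' spots, trains the model, propagates domain labels and pads expression at
#' the masked spots, and scores label accuracy (ACC) and expression MSE
#' against the held-out truth for three methods: the trained model
#' (`stweave`), plain feature propagation (`fp`), and the averaged-KNN
#' baseline (`knn_average`). Label ACC is scored for `stweave` (latent-space
#' propagation) and `knn_average` (coordinate-space KNN majority vote).
#'
#' @param ds an all-observed `SpatialDataset` in count space
#' @param labels ground-truth domain labels per location
#' @param rates masking fractions, each in (0,1)
#' @param seeds integer seeds (one full pipeline run per rate x seed)
#' @param cfg a [stweave_config()] for the training runs
#' @param graph_param distance threshold or k for [build_graph()]
#' @param graph_method graph construction method
#' @param n_pcs,n_hvg preprocessing choices (see [preprocess()])
#' @param genes genes to score expression padding on (default: all)
#' @param encoding latent space for propagation/padding
#' @return data frame with columns rate, seed, method, MSE, ACC
#' @export
masking_benchmark <- function(ds, labels, rates, seeds, cfg = stweave_config(),
                              graph_method = "distance", graph_param = NULL,
                              n_pcs = NULL, n_hvg = NULL, genes = NULL,
                              encoding = "COMB") {
  if (any(rates <= 0 | rates >= 1)) stop("rates must be in (0, 1)")
  validate_dataset(ds)
  if (is.null(graph_param))
    graph_param <- if (graph_method == "distance")
      1.05 * infer_spacing(ds$coords) else 6L
  labels <- stats::setNames(as.character(labels), ds$location_ids)
  if (is.null(genes)) genes <- ds$feature_ids
  rows <- list()
  for (rate in rates) for (sd in seeds) {
    dsm <- apply_mask(ds, rate = rate, seed = sd)
    masked_ids <- rownames(dsm$masked_truth)
    midx <- match(masked_ids, dsm$location_ids)
    graph <- build_graph(dsm, method = graph_method, param = graph_param)
    dsp <- preprocess(dsm, n_hvg = n_hvg, n_pcs = n_pcs, seed = sd)
    cfg_run <- cfg; cfg_run$seed <- as.integer(sd)
    state <- train_model(dsp, graph, cfg_run)
    bundle <- extract_encodings(dsp, graph, state)

    obs <- observed_idx(dsm)
    lab_obs <- labels[dsm$location_ids[obs]]
    # truth in the evaluation space: log-normalized masked expression
    truth_ln <- eval_space_truth(dsm, dsp, masked_ids, genes)

    # --- stweave: latent propagation + boosted-tree padding
    lab_all <- propagate_labels(bundle, lab_obs, encoding = encoding)
    expr_obs_ln <- eval_space_obs(dsm, dsp, genes)
    padx <- pad_expression(bundle, expr_obs_ln, genes = genes,
                           encoding = encoding, seed = sd)
    pred_sw <- padx$pred[masked_ids, , drop = FALSE]
    rows[[length(rows) + 1]] <- data.frame(
      rate = rate, seed = sd, method = "stweave",
      MSE = eval_mse(truth_ln, pred_sw),
      ACC = eval_acc(labels[masked_ids], lab_all[masked_ids]))

    # --- fp: diffusion imputation of expression directly
    ln_full <- matrix(NA_real_, nrow(dsm$expr), length(genes))
    ln_full[obs, ] <- expr_obs_ln
    fp <- propagate_features(ln_full, graph, dsm$status == "observed",
                             max_iter = cfg$fp_max_iter, tol = cfg$fp_tol)
    rows[[length(rows) + 1]] <- data.frame(
      rate = rate, seed = sd, method = "fp",
      MSE = eval_mse(truth_ln, fp$X_full[midx, , drop = FALSE]),
      ACC = NA_real_)

    # --- knn_average: graph-neighbor mean + coordinate-KNN labels
    dsl <- dsm
    dsl$expr <- ln_full
    dsl$feature_ids <- genes
    colnames(dsl$expr) <- genes; rownames(dsl$expr) <- dsl$location_ids
    kb <- baseline_knn_average(dsl, graph, targets = masked_ids)
    lab_knn <- coord_knn_labels(dsm, lab_obs, masked_ids, k = 6L)
    rows[[length(rows) + 1]] <- data.frame(
      rate = rate, seed = sd, method = "knn_average",
      MSE = eval_mse(truth_ln, kb$pred),
      ACC = eval_acc(labels[masked_ids], lab_knn))
  }
  do.call(rbind, rows)
}

# log1p median-depth-normalized expression of selected genes, the common
# space all padding methods are scored in
eval_space_obs <- function(ds_counts, ds_pre, genes) {
  obs <- observed_idx(ds_counts)
  X <- ds_counts$expr[obs, genes, drop = FALSE]
  sf <- ds_pre$transform$size_factors[obs]
  log1p(X * sf)
}

eval_space_truth <- function(ds_counts, ds_pre, masked_ids, genes) {
  X <- ds_counts$masked_truth[masked_ids, genes, drop = FALSE]
  lib <- rowSums(ds_counts$masked_truth[masked_ids, , drop = FALSE])
  target <- ds_pre$transform$steps$normalize$target_depth
  if (is.null(target)) return(log1p(X))
  lib[lib == 0] <- 1
  log1p(X * (target / lib))
}

coord_knn_labels <- function(ds, lab_obs, target_ids, k = 6L) {
  obs <- observed_idx(ds)
  ti <- match(target_ids, ds$location_ids)
  co <- ds$coords
  out <- character(length(ti))
  for (r in seq_along(ti)) {
    d2 <- rowSums(sweep(co[obs, , drop = FALSE], 2, co[ti[r], ])^2)
    nn <- order(d2, seq_along(obs))[seq_len(min(k, length(obs)))]
    votes <- table(lab_obs[nn])
    top <- names(votes)[votes == max(votes)]
    out[r] <- if (length(top) == 1) top else lab_obs[nn[1]]
  }
  stats::setNames(out, target_ids)
}
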