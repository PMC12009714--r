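#' Preprocess expression features
#'
#' Standard SRT feature preparation on observed counts: optional library-size
#' normalization to the median depth, `log1p`, highly-variable-gene selection
#' by a variance/mean dispersion statistic, and PCA. All transformation
#' parameters (size factors, HVG index, PCA center/rotation) are stored in
#' `ds$transform` so that model outputs at padded locations can later be
#' mapped back to gene space ([invert_transform()]).
#'
#' Rows with status `padding`/`masked` are excluded from parameter fitting
#' (size-factor median, dispersion ranking, PCA fit) and then transformed
#' with the fitted parameters where their values are defined.
#'
#' @param ds a `SpatialDataset` with `feature_space == "counts"`.
#' @param normalize scale each location to the median observed library size.
#' @param log1p apply `log(1 + x)`.
#' @param n_hvg keep this many top-dispersion genes (`NULL` = keep all).
#' @param n_pcs project to this many principal components (`NULL` = none).
#' @param seed integer seed (PCA sign convention and any sampling).
#' @return a new `SpatialDataset` with transformed `expr`, updated
#'   `feature_space`, and `transform` recording every step.
#' @export
preprocess <- function(ds, normalize = TRUE, log1p = TRUE,
                       n_hvg = NULL, n_pcs = NULL, seed = 1L) {
  validate_dataset(ds)
  if (ds$feature_space != "counts")
    stop("preprocess() expects feature_space == 'counts', got ", ds$feature_space)
  X <- ds$expr
  obs <- observed_idx(ds)
  if (!is.null(n_pcs) && n_pcs >= min(length(obs), ncol(X)))
    stop(sprintf("n_pcs (%d) must be < min(n observed locations, n features) = %d",
                 n_pcs, min(length(obs), ncol(X))))
  steps <- list()
  size_factors <- rep(1, nrow(X))
  if (normalize) {
    lib <- rowSums(X)
    target <- stats::median(lib[obs])
    lib[lib == 0] <- 1
    size_factors <- target / lib
    X <- X * size_factors
    steps$normalize <- list(target_depth = target)
  }
  if (log1p) {
    X <- log1p(X)
    steps$log1p <- TRUE
  }
  hvg_index <- seq_len(ncol(X))
  if (!is.null(n_hvg)) {
    if (n_hvg > ncol(X)) stop("n_hvg exceeds number of features")
    disp <- feature_dispersion(X[obs, , drop = FALSE])
    hvg_index <- sort(order(disp, decreasing = TRUE)[seq_len(n_hvg)])
    X <- X[, hvg_index, drop = FALSE]
    steps$hvg <- list(n_hvg = n_hvg)
  }
  space <- "normalized"
  pca <- NULL
  if (!is.null(n_pcs)) {
    set.seed(as.integer(seed))
    ctr <- colMeans(X[obs, , drop = FALSE])
    Xc <- sweep(X[obs, , drop = FALSE], 2, ctr)
    sv <- svd(Xc, nu = 0, nv = n_pcs)
    rot <- sv$v
    # deterministic sign: largest-magnitude loading positive per component
    for (k in seq_len(ncol(rot))) {
      j <- which.max(abs(rot[, k]))
      if (rot[j, k] < 0) rot[, k] <- -rot[, k]
    }
    Xp <- matrix(NA_real_, nrow(X), n_pcs)
    valid <- rowSums(is.na(X)) == 0
    Xp[valid, ] <- sweep(X[valid, , drop = FALSE], 2, ctr) %*% rot
    X <- Xp
    colnames(X) <- paste0("PC", seq_len(n_pcs))
    pca <- list(center = ctr, rotation = rot,
                sdev = sv$d[seq_len(n_pcs)] / sqrt(max(1, length(obs) - 1)))
    steps$pca <- list(n_pcs = n_pcs)
    space <- "pca"
  }
  out <- spatial_dataset(X, ds$coords, ds$status,
                         location_ids = ds$location_ids,
                         feature_ids = colnames(X),
                         feature_space = space,
                         masked_truth = ds$masked_truth)
  out$transform <- list(steps = steps, size_factors = size_factors,
                        hvg_index = hvg_index, hvg_ids = ds$feature_ids[hvg_index],
                        pca = pca, source_feature_ids = ds$feature_ids)
  out
}

#' Per-feature dispersion statistic
#'
#' Simple variance/mean ratio used to rank highly variable genes. Features
#' with zero mean get dispersion 0.
#'
#' @param X matrix, locations x features
#' @return numeric vector of length `ncol(X)`
#' @export
feature_dispersion <- function(X) {
  mu <- colMeans(X)
  v <- apply(X, 2, stats::var)
  d <- ifelse(mu > 0, v / mu, 0)
  names(d) <- colnames(X)
  d
}

#' Invert the stored preprocessing transform
#'
#' Maps model-space values (PCA or log-normalized) back toward gene space:
#' PCA inversion (`Z %*% t(rotation) + center`), then `expm1` if `log1p` was
#' applied. Values are returned at the common (median) library depth; the
#' per-spot size factor is not re-applied for padded locations, which have no
#' library of their own.
#'
#' @param values matrix in the dataset's current feature space
#' @param transform the `transform` element of a preprocessed dataset
#' @return matrix in (depth-normalized) gene space, HVG columns only
#' @export
invert_transform <- function(values, transform) {
  V <- as.matrix(values)
  if (!is.null(transform$pca)) {
    V <- V %*% t(transform$pca$rotation)
    V <- sweep(V, 2, transform$pca$center, "+")
    colnames(V) <- transform$hvg_ids
  }
  if (isTRUE(transform$steps$log1p)) V <- expm1(V)
  V
}
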