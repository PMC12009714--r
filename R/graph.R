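#' Build the spatial neighborhood graph
#'
#' Constructs a binary, symmetric adjacency over all locations from their 2-D
#' coordinates. With `method = "knn"`, location i is linked to its `param`
#' nearest neighbors (Euclidean; ties broken by location index) and the
#' result symmetrized by union, so every node has degree >= k before
#' symmetrization and no node is isolated. With `method = "distance"`, an
#' edge joins every pair with `0 < d <= param`; nodes left without neighbors
#' are kept in the graph and reported in a warning.
#'
#' @param ds a `SpatialDataset` (or a 2-column coordinate matrix).
#' @param method `"knn"` or `"distance"`. Distance thresholding is the
#'   natural choice for lattice protocols (e.g. Visium); KNN with `k = 6`
#'   emulates hexagonal neighborhoods on irregular cell-resolution data.
#' @param param k (count) for knn, threshold (same units as coords) for
#'   distance.
#' @param self_loops add unit diagonal (default FALSE).
#' @return a `SpatialGraph`: list with sparse 0/1 `adjacency` (class
#'   `dgCMatrix`), `method`, `param`, `self_loops`, `node_status`,
#'   `location_ids`.
#' @export
build_graph <- function(ds, method = c("knn", "distance"), param,
                        self_loops = FALSE) {
  method <- match.arg(method)
  if (inherits(ds, "SpatialDataset")) {
    coords <- ds$coords; status <- ds$status; ids <- ds$location_ids
  } else {
    coords <- as.matrix(ds); status <- rep("observed", nrow(coords))
    ids <- rownames(coords)
    if (is.null(ids)) ids <- paste0("loc", seq_len(nrow(coords)))
  }
  n <- nrow(coords)
  if (n < 2) stop("need at least 2 locations to build a graph")
  if (param <= 0) stop("`param` must be positive")
  D <- as.matrix(stats::dist(coords))
  if (method == "knn") {
    k <- as.integer(param)
    if (k >= n) stop("k must be < number of locations")
    ii <- jj <- vector("list", n)
    for (i in seq_len(n)) {
      # order() on (distance, index) gives deterministic tie-breaking
      nb <- order(D[i, ], seq_len(n))[-1][seq_len(k)]
      ii[[i]] <- rep.int(i, k); jj[[i]] <- nb
    }
    i <- unlist(ii); j <- unlist(jj)
    A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
    A <- methods::as(((A + Matrix::t(A)) > 0) * 1, "dMatrix")  # union symmetrize
  } else {
    hit <- which(D > 0 & D <= param, arr.ind = TRUE)
    A <- Matrix::sparseMatrix(i = hit[, 1], j = hit[, 2], x = 1, dims = c(n, n))
    iso <- which(Matrix::rowSums(A) == 0)
    if (length(iso))
      warning("isolated nodes under distance threshold: ",
              paste(utils::head(ids[iso], 10), collapse = ", "),
              if (length(iso) > 10) " ...")
  }
  A <- methods::as(Matrix::drop0(A), "CsparseMatrix")
  A@x[] <- 1
  if (self_loops) A <- A + Matrix::Diagonal(n)
  dimnames(A) <- list(ids, ids)
  structure(list(adjacency = A, method = method, param = param,
                 self_loops = self_loops, node_status = status,
                 location_ids = ids, coords = coords),
            class = "SpatialGraph")
}

#' @export
print.SpatialGraph <- function(x, ...) {
  cat(sprintf("SpatialGraph: %d nodes, %d undirected edges (%s, param=%g)\n",
              nrow(x$adjacency), Matrix::nnzero(x$adjacency) %/% 2,
              x$method, x$param))
  invisible(x)
}

graph_edges <- function(graph) {
  # unordered pairs i < j as a 2-column matrix
  A <- Matrix::triu(graph$adjacency, k = 1)
  s <- Matrix::summary(methods::as(A, "TsparseMatrix"))
  cbind(i = s$i, j = s$j)
}

#' Export a graph as an edge-list TSV and a MatrixMarket file
#'
#' @param graph a `SpatialGraph`
#' @param prefix output path prefix
#' @return invisibly, the written paths
#' @export
write_graph_files <- function(graph, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  e <- graph_edges(graph)
  p_edges <- paste0(prefix, "_edges.tsv")
  utils::write.table(
    data.frame(i = graph$location_ids[e[, 1]], j = graph$location_ids[e[, 2]]),
    p_edges, sep = "\t", quote = FALSE, row.names = FALSE)
  p_mtx <- paste0(prefix, ".mtx")
  Matrix::writeMM(graph$adjacency, p_mtx)
  invisible(c(edges = p_edges, mtx = p_mtx))
}

#' Infer the native lattice spacing
#'
#' Modal nearest-neighbor distance over observed locations (mode of the
#' rounded NN-distance distribution, to be robust to jitter).
#'
#' @param coords 2-column coordinate matrix
#' @return numeric spacing
#' @export
infer_spacing <- function(coords) {
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  nn <- apply(D, 1, min)
  tab <- table(signif(nn, 3))
  as.numeric(names(tab)[which.max(tab)])
}

#' Generate padding spots between adjacent measured spots
#'
#' For lattice protocols the capture spots leave unmeasured interstitial
#' tissue; this inserts an artificial "padding" location at the midpoint of
#' every pair of observed spots adjacent at the native spacing, so the model
#' can infer the biology there. Midpoints are deduplicated within
#' `spacing / 4` and appended in deterministic order (sorted by y, then x).
#' Padding rows of `expr` are `NA` (never used as supervision).
#'
#' @param ds an all-observed `SpatialDataset`.
#' @param lattice `"hex"`, `"square"`, or `"auto"` (only used for the
#'   spacing-regularity warning; placement is geometry-agnostic).
#' @param spacing center-to-center distance of adjacent spots, or `"auto"`
#'   to use [infer_spacing()].
#' @return a new `SpatialDataset` with original locations first, padding
#'   locations (ids `pad<i>`) appended with status `"padding"`.
#' @export
generate_padding <- function(ds, lattice = c("auto", "hex", "square"),
                             spacing = "auto") {
  lattice <- match.arg(lattice)
  validate_dataset(ds)
  # padding is placed from all measured (observed or masked) locations
  co <- ds$coords[ds$status != "padding", , drop = FALSE]
  if (nrow(co) == 0) stop("no spots to generate padding from")
  if (nrow(co) == 1) return(ds)   # a single spot has no adjacent pair
  D <- as.matrix(stats::dist(co))
  diag(D) <- Inf
  nn <- apply(D, 1, min)
  if (spacing == "auto") spacing <- infer_spacing(co)
  spacing <- as.numeric(spacing)
  cv <- stats::sd(nn) / mean(nn)
  if (cv > 0.5 && lattice != "auto")
    warning(sprintf("nearest-neighbor spacing is irregular (CV = %.2f); %s lattice assumption may not hold",
                    cv, lattice))
  adj <- which(D <= spacing * 1.05, arr.ind = TRUE)
  adj <- adj[adj[, 1] < adj[, 2], , drop = FALSE]
  if (nrow(adj) == 0)
    return(ds)
  mids <- (co[adj[, 1], , drop = FALSE] + co[adj[, 2], , drop = FALSE]) / 2
  # dedupe within spacing/4, then drop midpoints colliding with existing spots
  mids <- dedupe_points(mids, tol = spacing / 4)
  dmin <- proxy_min_dist(mids, ds$coords)
  mids <- mids[dmin > spacing / 4, , drop = FALSE]
  ord <- order(mids[, 2], mids[, 1])
  mids <- mids[ord, , drop = FALSE]
  if (nrow(mids) == 0) return(ds)
  pad_ids <- paste0("pad", seq_len(nrow(mids)))
  expr_pad <- matrix(NA_real_, nrow(mids), ncol(ds$expr))
  out <- spatial_dataset(rbind(ds$expr, expr_pad),
                         rbind(ds$coords, mids),
                         c(ds$status, rep("padding", nrow(mids))),
                         location_ids = c(ds$location_ids, pad_ids),
                         feature_ids = ds$feature_ids,
                         feature_space = ds$feature_space,
                         masked_truth = ds$masked_truth)
  out$transform <- ds$transform
  out$spacing <- spacing
  out
}

dedupe_points <- function(pts, tol) {
  if (nrow(pts) <= 1) return(pts)
  keep <- rep(TRUE, nrow(pts))
  # grid-hash then exact check; fine at the sizes padding produces
  D <- as.matrix(stats::dist(pts))
  for (i in seq_len(nrow(pts))[-1]) {
    if (any(D[i, seq_len(i - 1)][keep[seq_len(i - 1)]] < tol)) keep[i] <- FALSE
  }
  pts[keep, , drop = FALSE]
}

proxy_min_dist <- function(a, b) {
  # per row of a: min distance to any row of b
  if (nrow(a) == 0) return(numeric(0))
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * a %*% t(b)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Mask observed locations to create held-out ground truth
#'
#' Selected locations change status to `"masked"`: their expression rows are
#' moved to `masked_truth` (for later evaluation) and replaced by `NA` so no
#' model stage can use them as supervision. [unmask()] restores them.
#'
#' @param ds a `SpatialDataset`.
#' @param ids explicit location ids to mask (overrides `rate`).
#' @param rate fraction in (0,1) of observed locations to mask at random.
#' @param seed integer seed for the random selection.
#' @return the masked `SpatialDataset`.
#' @export
apply_mask <- function(ds, ids = NULL, rate = NULL, seed = 1L) {
  validate_dataset(ds)
  if (is.null(ids)) {
    if (is.null(rate)) stop("provide `ids` or `rate`")
    if (rate <= 0 || rate >= 1) stop("rate must be in (0, 1)")
    obs <- which(ds$status == "observed")
    set.seed(as.integer(seed))
    take <- sample(obs, round(rate * length(obs)))
    ids <- ds$location_ids[take]
  }
  if (length(ids) == 0) return(ds)
  idx <- match(ids, ds$location_ids)
  if (any(is.na(idx))) stop("unknown location ids: ",
                            paste(ids[is.na(idx)], collapse = ", "))
  if (any(ds$status[idx] != "observed"))
    stop("can only mask locations that are currently observed")
  truth <- ds$expr[idx, , drop = FALSE]
  rownames(truth) <- ids
  ds$masked_truth <- rbind(ds$masked_truth, truth)
  ds$expr[idx, ] <- NA_real_
  ds$status[idx] <- "masked"
  ds
}

#' @rdname apply_mask
#' @export
unmask <- function(ds) {
  idx <- which(ds$status == "masked")
  if (length(idx) == 0) return(ds)
  ids <- ds$location_ids[idx]
  ds$expr[idx, ] <- ds$masked_truth[ids, , drop = FALSE]
  ds$status[idx] <- "observed"
  keep <- setdiff(rownames(ds$masked_truth), ids)
  ds$masked_truth <- if (length(keep)) ds$masked_truth[keep, , drop = FALSE] else NULL
  ds
}

#' Build the combined observed + padding graph
#'
#' After [generate_padding()], the full graph is rebuilt with the distance
#' method at `0.55 * spacing`: each padding spot then connects to its two
#' generating spots and to adjacent padding spots, while observed-observed
#' pairs at full spacing are no longer directly linked (the padding spot sits
#' between them). Keeps padded nodes topologically anchored without creating
#' long-range edges.
#'
#' @param ds a padded `SpatialDataset` (from [generate_padding()])
#' @param spacing native spacing; defaults to the value stored by
#'   [generate_padding()] or [infer_spacing()] of the observed spots.
#' @return a `SpatialGraph` over all locations
#' @export
build_padded_graph <- function(ds, spacing = NULL) {
  if (is.null(spacing)) spacing <- ds$spacing
  if (is.null(spacing))
    spacing <- infer_spacing(ds$coords[ds$status != "padding", , drop = FALSE])
  build_graph(ds, method = "distance", param = 0.55 * spacing)
}
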