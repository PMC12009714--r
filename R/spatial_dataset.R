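#' Spatial transcriptomics dataset container
#'
#' A `SpatialDataset` bundles an expression matrix (locations x features), a
#' 2-D coordinate table, and a per-location status label. Locations are always
#' rows; features (genes or principal components) are columns. Status is one
#' of `"observed"` (expression measured), `"padding"` (artificial unobserved
#' location inserted between measured spots), or `"masked"` (measured, but
#' withheld from model supervision; the held-out truth is kept in
#' `masked_truth` for evaluation).
#'
#' @param expr numeric matrix, locations x features. Rows at padding/masked
#'   locations are ignored as supervision (padding rows are typically `NA`).
#' @param coords numeric matrix or data frame with two columns (x, y),
#'   platform-native units.
#' @param status character vector, one of `"observed"`, `"padding"`,
#'   `"masked"` per location. Defaults to all observed.
#' @param location_ids unique location identifiers; defaults to rownames of
#'   `expr` or `loc<i>`.
#' @param feature_ids unique feature identifiers; defaults to colnames of
#'   `expr` or `feat<j>`.
#' @param feature_space one of `"counts"`, `"normalized"`, `"pca"`.
#' @param masked_truth optional matrix of held-out expression for masked rows
#'   (rownames are location ids).
#'
#' @return an object of class `SpatialDataset`: a list with elements `expr`,
#'   `coords`, `status`, `location_ids`, `feature_ids`, `feature_space`,
#'   `masked_truth`, `transform` (preprocessing parameters, see
#'   [preprocess()]).
#' @export
spatial_dataset <- function(expr, coords, status = NULL,
                            location_ids = NULL, feature_ids = NULL,
                            feature_space = c("counts", "normalized", "pca"),
                            masked_truth = NULL) {
  expr <- as.matrix(expr)
  storage.mode(expr) <- "double"
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L)
    stop("`coords` must have exactly 2 columns (x, y)")
  n <- nrow(expr)
  if (nrow(coords) != n)
    stop(sprintf("expr has %d rows but coords has %d", n, nrow(coords)))
  if (any(!is.finite(coords))) {
    bad <- which(rowSums(!is.finite(coords)) > 0)
    stop("non-finite coordinates at rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  if (is.null(status)) status <- rep("observed", n)
  status <- as.character(status)
  if (length(status) != n) stop("`status` length must equal number of locations")
  ok <- status %in% c("observed", "padding", "masked")
  if (!all(ok)) stop("invalid status values: ",
                     paste(unique(status[!ok]), collapse = ", "))
  if (is.null(location_ids)) {
    location_ids <- rownames(expr)
    if (is.null(location_ids)) location_ids <- paste0("loc", seq_len(n))
  }
  if (anyDuplicated(location_ids)) stop("location_ids must be unique")
  if (is.null(feature_ids)) {
    feature_ids <- colnames(expr)
    if (is.null(feature_ids)) feature_ids <- paste0("feat", seq_len(ncol(expr)))
  }
  if (anyDuplicated(feature_ids)) stop("feature_ids must be unique")
  rownames(expr) <- location_ids
  colnames(expr) <- feature_ids
  rownames(coords) <- location_ids
  colnames(coords) <- c("x", "y")
  ds <- structure(list(
    expr = expr, coords = coords, status = status,
    location_ids = location_ids, feature_ids = feature_ids,
    feature_space = match.arg(feature_space),
    masked_truth = masked_truth, transform = NULL
  ), class = "SpatialDataset")
  ds
}

#' @export
print.SpatialDataset <- function(x, ...) {
  tab <- table(factor(x$status, levels = c("observed", "padding", "masked")))
  cat(sprintf("SpatialDataset: %d locations x %d features [%s]\n",
              nrow(x$expr), ncol(x$expr), x$feature_space))
  cat(sprintf("  observed %d | padding %d | masked %d\n",
              tab[["observed"]], tab[["padding"]], tab[["masked"]]))
  if (!is.null(x$transform))
    cat("  preprocessed:", paste(names(x$transform$steps), collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.SpatialDataset <- function(x) dim(x$expr)

#' Number of observed locations
#' @param ds a `SpatialDataset`
#' @return integer count of locations with status `"observed"`
#' @export
n_observed <- function(ds) sum(ds$status == "observed")

#' Indices of observed locations
#' @param ds a `SpatialDataset`
#' @return integer vector of row indices with status `"observed"`
#' @export
observed_idx <- function(ds) which(ds$status == "observed")

validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "SpatialDataset"),
            nrow(ds$expr) == nrow(ds$coords),
            nrow(ds$expr) == length(ds$status),
            !anyDuplicated(ds$location_ids),
            !anyDuplicated(ds$feature_ids))
  invisible(ds)
}

#' Coerce to/from SingleCellExperiment
#'
#' Bridges to the Bioconductor single-cell container: `as_sce()` stores
#' counts in the assay slot (features x cells, the Bioconductor convention)
#' with coordinates in `colData`; `as_spatial_dataset()` reverses this.
#'
#' @param ds a `SpatialDataset`
#' @param sce a `SingleCellExperiment` with `x`/`y` columns in `colData`
#' @param assay assay name to read counts from
#' @return `as_sce`: a `SingleCellExperiment`; `as_spatial_dataset`: a
#'   `SpatialDataset` with all locations observed.
#' @export
as_sce <- function(ds) {
  if (!requireNamespace("SingleCellExperiment", quietly = TRUE))
    stop("SingleCellExperiment is required for as_sce()")
  validate_dataset(ds)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = t(ds$expr)),
    colData = S4Vectors::DataFrame(x = ds$coords[, 1], y = ds$coords[, 2],
                                   status = ds$status,
                                   row.names = ds$location_ids))
}

#' @rdname as_sce
#' @export
as_spatial_dataset <- function(sce, assay = "counts") {
  if (!requireNamespace("SingleCellExperiment", quietly = TRUE))
    stop("SingleCellExperiment is required for as_spatial_dataset()")
  cd <- SingleCellExperiment::colData(sce)
  if (!all(c("x", "y") %in% colnames(cd)))
    stop("colData must contain `x` and `y` coordinate columns")
  expr <- t(as.matrix(SummarizedExperiment::assay(sce, assay)))
  spatial_dataset(expr, cbind(cd$x, cd$y),
                  location_ids = colnames(sce), feature_ids = rownames(sce))
}
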