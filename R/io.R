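#' Read an SRT dataset from standard on-disk formats
#'
#' Supported formats:
#' * `csv`: `path` is a CSV of expression values (locations x features, first
#'   column = location id) and `coord_path` a CSV with columns
#'   (id, `coord_keys[1]`, `coord_keys[2]`).
#' * `mtx_dir`: `path` is a CellRanger-style directory containing
#'   `matrix.mtx` (features x barcodes), `features.tsv` (or `genes.tsv`) and
#'   `barcodes.tsv`; coordinates come from `coord_path` (CSV/TSV keyed by
#'   barcode) since the CellRanger triplet carries none. The matrix is
#'   transposed so locations are rows.
#'
#' @param path file or directory, per `format`.
#' @param format `"csv"` or `"mtx_dir"`. See [as_spatial_dataset()] for the
#'   in-memory SingleCellExperiment route.
#' @param coord_path coordinate table path (required for `mtx_dir`; for `csv`
#'   defaults to `<path-sans-ext>_coords.csv`).
#' @param coord_keys names of the two coordinate columns.
#' @return a [spatial_dataset()] with all locations observed and counts
#'   preserved losslessly.
#' @export
read_dataset <- function(path, format = c("csv", "mtx_dir"),
                         coord_path = NULL, coord_keys = c("x", "y")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input not found: ", path)
  if (format == "csv") {
    if (is.null(coord_path))
      coord_path <- paste0(sub("\\.csv$", "", path), "_coords.csv")
    if (!file.exists(coord_path)) stop("coordinate file not found: ", coord_path)
    ex <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    co <- utils::read.csv(coord_path, row.names = 1, check.names = FALSE)
    missing_keys <- setdiff(coord_keys, colnames(co))
    if (length(missing_keys))
      stop("coordinate columns not found: ", paste(missing_keys, collapse = ", "))
    co <- co[rownames(ex), coord_keys, drop = FALSE]
    expr <- as.matrix(ex)
  } else {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) stop("matrix.mtx not found in ", path)
    feats <- file.path(path, c("features.tsv", "genes.tsv"))
    feats <- feats[file.exists(feats)][1]
    if (is.na(feats)) stop("features.tsv / genes.tsv not found in ", path)
    bcs <- file.path(path, "barcodes.tsv")
    if (!file.exists(bcs)) stop("barcodes.tsv not found in ", path)
    m <- Matrix::readMM(mtx)            # features x barcodes
    ftab <- utils::read.delim(feats, header = FALSE)
    btab <- utils::read.delim(bcs, header = FALSE)
    expr <- t(as.matrix(m))             # locations x features
    rownames(expr) <- as.character(btab[[1]])
    colnames(expr) <- as.character(ftab[[1]])
    if (is.null(coord_path)) stop("mtx_dir format requires `coord_path`")
    if (!file.exists(coord_path)) stop("coordinate file not found: ", coord_path)
    sep <- if (grepl("\\.tsv$", coord_path)) "\t" else ","
    co <- utils::read.table(coord_path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE)
    missing_keys <- setdiff(coord_keys, colnames(co))
    if (length(missing_keys))
      stop("coordinate columns not found: ", paste(missing_keys, collapse = ", "))
    if (!all(rownames(expr) %in% rownames(co)))
      stop("coordinates missing for some barcodes")
    co <- co[rownames(expr), coord_keys, drop = FALSE]
  }
  co <- as.matrix(co)
  if (any(is.na(co))) {
    bad <- rownames(co)[rowSums(is.na(co)) > 0]
    stop("NaN/NA coordinates for: ", paste(utils::head(bad, 10), collapse = ", "))
  }
  spatial_dataset(expr, co)
}

#' Write a dataset (and optional artifacts) as CSV files
#'
#' Writes `<prefix>.csv` (expression, location ids in first column),
#' `<prefix>_coords.csv`, and `<prefix>_status.csv`; [read_dataset()] on the
#' written files round-trips counts, coordinates and ids losslessly.
#'
#' @param ds a `SpatialDataset`
#' @param prefix output path prefix (directories are created)
#' @return invisibly, the paths written
#' @export
write_dataset <- function(ds, prefix) {
  validate_dataset(ds)
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  p_expr <- paste0(prefix, ".csv")
  p_co <- paste0(prefix, "_coords.csv")
  p_st <- paste0(prefix, "_status.csv")
  utils::write.csv(as.data.frame(ds$expr), p_expr)
  utils::write.csv(as.data.frame(ds$coords), p_co)
  utils::write.csv(data.frame(status = ds$status, row.names = ds$location_ids), p_st)
  invisible(c(expr = p_expr, coords = p_co, status = p_st))
}

#' Export latent encodings and labels as CSV
#'
#' @param bundle an `EncodingBundle` from [extract_encodings()]
#' @param dir output directory
#' @param labels optional per-location label vector to write alongside
#' @return invisibly, the files written
#' @export
write_encodings <- function(bundle, dir, labels = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in c("ATTR_full", "TOPO", "COMB")) {
    p <- file.path(dir, paste0(tolower(nm), ".csv"))
    utils::write.csv(as.data.frame(bundle[[nm]]), p)
    paths <- c(paths, p)
  }
  fl <- file.path(dir, "source_flag.csv")
  utils::write.csv(data.frame(source_flag = bundle$source_flag,
                              row.names = rownames(bundle$TOPO)), fl)
  paths <- c(paths, fl)
  if (!is.null(labels)) {
    pl <- file.path(dir, "labels.csv")
    utils::write.csv(data.frame(label = labels,
                                row.names = rownames(bundle$TOPO)), pl)
    paths <- c(paths, pl)
  }
  invisible(paths)
}
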