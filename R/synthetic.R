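#' Specification for a synthetic SRT dataset with planted domains
#'
#' The generator emulates the geometries and structures the method is meant
#' for: hex/square capture lattices or irregular cell positions, with
#' domains laid out as parallel stripes, concentric rings (laminar
#' organization), or sporadic minority patches inside a background domain
#' (infiltrative tumor foci). Expression is negative-binomial (mean mu,
#' dispersion theta, variance mu + mu^2/theta) or Gaussian around a
#' baseline, with disjoint marker-gene sets up-shifted per domain on the
#' log scale.
#'
#' @param lattice `"hex"`, `"square"`, or `"random_uniform"`
#' @param n_side lattice side length (hex/square; total spots = n_side^2)
#' @param n_cells number of cells (random_uniform)
#' @param spacing lattice spacing / mean cell separation
#' @param layout `"stripes"`, `"rings"`, or `"sporadic"`
#' @param n_domains number of planted domains
#' @param n_genes number of genes M
#' @param n_markers_per_domain disjoint marker genes per domain
#' @param marker_effect log-fold mean shift of a marker in its domain
#' @param noise `"nb"` or `"gaussian"`
#' @param mu_base baseline mean expression
#' @param nb_dispersion NB dispersion theta
#' @param gaussian_sd standard deviation for gaussian noise
#' @param dropout_rate probability an entry is zeroed after sampling
#' @param sporadic_fraction target minority fraction for sporadic layout
#'   (capped at 0.15)
#' @param seed integer seed
#' @return a `SyntheticSpec` list
#' @export
synthetic_spec <- function(lattice = c("hex", "square", "random_uniform"),
                           n_side = 30L, n_cells = 900L, spacing = 1,
                           layout = c("stripes", "rings", "sporadic"),
                           n_domains = 3L, n_genes = 60L,
                           n_markers_per_domain = 5L, marker_effect = 1.5,
                           noise = c("nb", "gaussian"), mu_base = 5,
                           nb_dispersion = 10, gaussian_sd = 1,
                           dropout_rate = 0, sporadic_fraction = 0.15,
                           seed = 1L) {
  spec <- list(lattice = match.arg(lattice), n_side = as.integer(n_side),
               n_cells = as.integer(n_cells), spacing = spacing,
               layout = match.arg(layout), n_domains = as.integer(n_domains),
               n_genes = as.integer(n_genes),
               n_markers_per_domain = as.integer(n_markers_per_domain),
               marker_effect = marker_effect, noise = match.arg(noise),
               mu_base = mu_base, nb_dispersion = nb_dispersion,
               gaussian_sd = gaussian_sd, dropout_rate = dropout_rate,
               sporadic_fraction = min(sporadic_fraction, 0.15),
               seed = as.integer(seed))
  if (spec$n_markers_per_domain * spec$n_domains > spec$n_genes)
    stop("marker sets exceed the number of genes")
  structure(spec, class = "SyntheticSpec")
}

lattice_coords <- function(spec) {
  if (spec$lattice == "hex") {
    g <- expand.grid(col = seq_len(spec$n_side), row = seq_len(spec$n_side))
    x <- (g$col - 1) * spec$spacing + ifelse(g$row %% 2 == 0, spec$spacing / 2, 0)
    y <- (g$row - 1) * spec$spacing * sqrt(3) / 2
    cbind(x = x, y = y)
  } else if (spec$lattice == "square") {
    g <- expand.grid(col = seq_len(spec$n_side), row = seq_len(spec$n_side))
    cbind(x = (g$col - 1) * spec$spacing, y = (g$row - 1) * spec$spacing)
  } else {
    side <- sqrt(spec$n_cells) * spec$spacing
    cbind(x = stats::runif(spec$n_cells, 0, side),
          y = stats::runif(spec$n_cells, 0, side))
  }
}

domain_labels <- function(spec, coords) {
  n <- nrow(coords)
  if (spec$layout == "stripes") {
    br <- stats::quantile(coords[, 2], probs = seq(0, 1, length.out = spec$n_domains + 1))
    br[1] <- -Inf; br[length(br)] <- Inf
    as.integer(cut(coords[, 2], br, labels = FALSE))
  } else if (spec$layout == "rings") {
    ctr <- colMeans(coords)
    r <- sqrt(rowSums(sweep(coords, 2, ctr)^2))
    br <- stats::quantile(r, probs = seq(0, 1, length.out = spec$n_domains + 1))
    br[1] <- -Inf; br[length(br)] <- Inf
    as.integer(cut(r, br, labels = FALSE))
  } else {
    # sporadic: Poisson-seeded minority patches of radius 2*spacing inside a
    # background domain; remaining domains (if n_domains > 2) are stripes of
    # the background so the tissue still has coarse structure
    lab <- rep(1L, n)
    if (spec$n_domains > 2) {
      br <- stats::quantile(coords[, 2],
                            probs = seq(0, 1, length.out = spec$n_domains))
      br[1] <- -Inf; br[length(br)] <- Inf
      lab <- as.integer(cut(coords[, 2], br, labels = FALSE))
    }
    target <- spec$sporadic_fraction * n
    patch_r <- 2 * spec$spacing
    per_patch <- pi * patch_r^2 / (spec$spacing^2)   # rough spots per patch
    n_patch <- max(1L, stats::rpois(1, max(1, target / per_patch)))
    ctrs <- coords[sample.int(n, n_patch), , drop = FALSE]
    minority <- rep(FALSE, n)
    for (p in seq_len(n_patch)) {
      d <- sqrt(rowSums(sweep(coords, 2, ctrs[p, ])^2))
      minority <- minority | d <= patch_r
    }
    if (sum(minority) > 0.15 * n) {   # cap the minority fraction
      keep <- which(minority)[seq_len(floor(0.15 * n))]
      minority <- rep(FALSE, n); minority[keep] <- TRUE
    }
    lab[minority] <- spec$n_domains
    lab
  }
}

#' Generate a synthetic SRT dataset
#'
#' @param spec a [synthetic_spec()]
#' @return list: `dataset` (a count-space `SpatialDataset`), `labels`
#'   (integer ground-truth domain per location), `markers` (data frame of
#'   gene, domain, log-fold effect)
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  coords <- lattice_coords(spec)
  n <- nrow(coords)
  if (spec$n_domains > n) stop("more domains than locations")
  lab <- domain_labels(spec, coords)
  M <- spec$n_genes
  genes <- sprintf("gene%03d", seq_len(M))
  # disjoint marker blocks per domain
  marker_rows <- list()
  logmu <- matrix(log(spec$mu_base), n, M)
  for (d in seq_len(spec$n_domains)) {
    gi <- (d - 1) * spec$n_markers_per_domain + seq_len(spec$n_markers_per_domain)
    logmu[lab == d, gi] <- logmu[lab == d, gi] + spec$marker_effect
    marker_rows[[d]] <- data.frame(gene = genes[gi], domain = d,
                                   log_fold = spec$marker_effect)
  }
  mu <- exp(logmu)
  expr <- if (spec$noise == "nb") {
    matrix(stats::rnbinom(n * M, mu = mu, size = spec$nb_dispersion), n, M)
  } else {
    matrix(stats::rnorm(n * M, mean = mu, sd = spec$gaussian_sd), n, M)
  }
  if (spec$dropout_rate > 0) {
    drop <- matrix(stats::runif(n * M) < spec$dropout_rate, n, M)
    expr[drop] <- 0
  }
  colnames(expr) <- genes
  rownames(expr) <- sprintf("spot%04d", seq_len(n))
  ds <- spatial_dataset(expr, coords)
  list(dataset = ds, labels = stats::setNames(lab, ds$location_ids),
       markers = do.call(rbind, marker_rows))
}

#' Degrade measurement quality of random spots
#'
#' Binomially thins the counts of randomly chosen spots by `depth_factor`
#' (each count k becomes Binomial(k, depth_factor)) and flags them
#' low-quality, emulating spots with poor capture that are candidates for
#' masking and re-inference.
#'
#' @param ds a count-space `SpatialDataset`
#' @param low_quality_rate fraction of observed spots to degrade
#' @param depth_factor retention probability in (0, 1]
#' @param seed integer seed
#' @return the degraded `SpatialDataset`, with a logical `low_quality`
#'   element flagging affected locations
#' @export
degrade <- function(ds, low_quality_rate, depth_factor, seed = 1L) {
  validate_dataset(ds)
  if (ds$feature_space != "counts") stop("degrade() expects count data")
  if (depth_factor <= 0 || depth_factor > 1)
    stop("depth_factor must be in (0, 1]")
  set.seed(as.integer(seed))
  obs <- observed_idx(ds)
  pick <- sort(sample(obs, round(low_quality_rate * length(obs))))
  flags <- stats::setNames(rep(FALSE, nrow(ds$expr)), ds$location_ids)
  flags[pick] <- TRUE
  if (depth_factor < 1 && length(pick)) {
    sub <- ds$expr[pick, , drop = FALSE]
    thinned <- stats::rbinom(length(sub), size = as.integer(sub),
                             prob = depth_factor)
    ds$expr[pick, ] <- matrix(thinned, nrow = length(pick))
  }
  ds$low_quality <- flags
  ds
}
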