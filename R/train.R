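# Alternating adversarial training of the pairwise GAE. Per epoch:
#   (a) discriminator step: minimize L_adv in the discriminator parameters
#       (prior samples pushed to 1, encodings to 0);
#   (b) autoencoder step: minimize L_recon + lambda_adv * L_gen in the
#       encoder/decoder parameters, L_gen being the non-saturating generator
#       form by default.
# All randomness (weight init, prior draws, adjacency-entry sampling) comes
# from one stream seeded by cfg$seed, so runs are bitwise reproducible.

mlp_wb <- function(m) list(W = m$W, b = m$b)

ae_skeleton <- function(state) {
  list(attr_enc = mlp_wb(state$attr_enc),
       attr_dec = mlp_wb(state$attr_dec),
       topo_dec = mlp_wb(state$topo_dec),
       topo_edge = mlp_wb(state$topo_enc$edge_mlp),
       topo_rounds = state$topo_enc$rounds,
       topo_out = state$topo_enc$out)
}

ae_write_back <- function(state, sk) {
  state$attr_enc$W <- sk$attr_enc$W; state$attr_enc$b <- sk$attr_enc$b
  state$attr_dec$W <- sk$attr_dec$W; state$attr_dec$b <- sk$attr_dec$b
  state$topo_dec$W <- sk$topo_dec$W; state$topo_dec$b <- sk$topo_dec$b
  state$topo_enc$edge_mlp$W <- sk$topo_edge$W
  state$topo_enc$edge_mlp$b <- sk$topo_edge$b
  state$topo_enc$rounds <- sk$topo_rounds
  state$topo_enc$out <- sk$topo_out
  state
}

# fast per-epoch pair sampler: edge keys precomputed once, negatives drawn by
# rejection against a sorted key table (no sparse-matrix indexing)
make_pair_sampler <- function(A) {
  N <- nrow(A)
  s <- Matrix::summary(methods::as(Matrix::triu(A, 1), "TsparseMatrix"))
  E <- cbind(s$i, s$j)
  keys <- sort((E[, 1] - 1) * N + E[, 2])
  n_pair <- N * (N - 1) / 2
  list(N = N, E = E, keys = keys, n_pos_total = nrow(E),
       n_neg_total = n_pair - nrow(E), n_pair = n_pair)
}

draw_pairs <- function(ps, m, neg_pos_ratio) {
  n_neg <- ceiling(neg_pos_ratio * m)
  pos <- ps$E[sample.int(ps$n_pos_total, m), , drop = FALSE]
  neg <- matrix(0L, 0, 2)
  while (nrow(neg) < n_neg) {
    need <- n_neg - nrow(neg)
    i <- sample.int(ps$N, 2 * need + 10, replace = TRUE)
    j <- sample.int(ps$N, 2 * need + 10, replace = TRUE)
    lo <- pmin(i, j); hi <- pmax(i, j)
    k <- (lo - 1) * ps$N + hi
    ok <- lo != hi & !(k %in% ps$keys)
    neg <- rbind(neg, cbind(lo, hi)[ok, , drop = FALSE])
  }
  neg <- neg[seq_len(n_neg), , drop = FALSE]
  n_samp <- m + n_neg
  w_pos <- (ps$n_pos_total / ps$n_pair) * n_samp / m
  w_neg <- (ps$n_neg_total / ps$n_pair) * n_samp / n_neg
  list(pairs = rbind(pos, neg), target = c(rep(1, m), rep(0, n_neg)),
       weights = c(rep(w_pos, m), rep(w_neg, n_neg)))
}

# adjacency BCE + gradient over an explicit entry sample (stratified weights)
adj_bce_sampled <- function(Zh, samp) {
  i <- samp$pairs[, 1]; j <- samp$pairs[, 2]
  s <- rowSums(Zh[i, , drop = FALSE] * Zh[j, , drop = FALSE])
  loss <- mean(samp$weights * (softplus(s) - samp$target * s))
  g <- samp$weights * (sigmoid(s) - samp$target) / length(s)
  N <- nrow(Zh)
  G <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(g, g),
                            dims = c(N, N))
  list(loss = loss, gZh = as.matrix(G %*% Zh))
}

# adjacency BCE + gradient over the full off-diagonal entry set
adj_bce_full <- function(Zh, Tdense) {
  S <- tcrossprod(Zh)
  n <- nrow(S) * (nrow(S) - 1)
  B <- softplus(S) - Tdense * S
  diag(B) <- 0
  loss <- sum(B) / n
  G <- (sigmoid(S) - Tdense) / n
  diag(G) <- 0
  list(loss = loss, gZh = (G + t(G)) %*% Zh)
}

#' Train the pairwise graph autoencoder
#'
#' Runs feature propagation to complete expression at unobserved locations,
#' then alternates discriminator and autoencoder updates for `cfg$epochs`
#' full-batch epochs (see [stweave_config()] for the objective weights).
#' The recorded `loss_recon` is exactly `loss_attr + loss_topo` at every
#' epoch.
#'
#' @param ds a preprocessed `SpatialDataset` (padding/masked rows allowed).
#' @param graph a `SpatialGraph` over the same locations, with edges.
#' @param cfg a [stweave_config()].
#' @param modules `"both"` (default), `"attr_only"`, or `"topo_only"`:
#'   ablation switch that trains a single autoencoder while consuming the
#'   identical random stream, so loss traces are directly comparable.
#' @param verbose print losses every 50 epochs.
#' @return a trained `ModelState`; `$history` is a data frame with one row
#'   per epoch (`loss_attr`, `loss_topo`, `loss_recon`, `loss_adv`,
#'   `loss_gen`, plus the attr self/cross split).
#' @export
train_model <- function(ds, graph, cfg = stweave_config(),
                        modules = c("both", "attr_only", "topo_only"),
                        verbose = FALSE) {
  modules <- match.arg(modules)
  validate_dataset(ds)
  N <- nrow(ds$expr); M <- ncol(ds$expr)
  if (nrow(graph$adjacency) != N) stop("graph does not cover all locations")
  if (Matrix::nnzero(graph$adjacency) == 0) stop("graph has no edges")
  obs <- observed_idx(ds)
  N_o <- length(obs)
  if (N_o < 2) stop("need at least 2 observed locations")
  use_attr <- modules != "topo_only"
  use_topo <- modules != "attr_only"

  state <- init_model_state(M, cfg)   # seeds the stream
  l <- cfg$latent_dim

  X_o <- ds$expr[obs, , drop = FALSE]
  if (any(!is.finite(X_o))) stop("observed expression must be finite")
  if (N_o < N) {
    fp <- propagate_features(ds$expr, graph, ds$status == "observed",
                             max_iter = cfg$fp_max_iter, tol = cfg$fp_tol)
    Xp <- fp$X_full
  } else {
    Xp <- ds$expr
  }
  ctx <- if (use_topo) topo_prepare(Xp, graph) else NULL

  A <- graph$adjacency
  full_self <- N <= cfg$full_adj_threshold
  full_cross <- N_o <= cfg$full_adj_threshold
  T_self <- if (full_self) as.matrix(A) else NULL
  Ao <- A[obs, obs, drop = FALSE]
  T_cross <- if (full_cross) as.matrix(Ao) else NULL
  ps_self <- if (!full_self) make_pair_sampler(A) else NULL
  ps_cross <- if (!full_cross && Matrix::nnzero(Ao) > 0)
    make_pair_sampler(Ao) else NULL
  cross_has_edges <- Matrix::nnzero(Ao) > 0
  edges_n <- Matrix::nnzero(Matrix::triu(A, 1))
  m_self <- min(edges_n, if (is.null(cfg$adj_subset)) edges_n else cfg$adj_subset)
  edges_no <- Matrix::nnzero(Matrix::triu(Ao, 1))
  m_cross <- if (edges_no > 0)
    min(edges_no, if (is.null(cfg$adj_subset)) edges_no else cfg$adj_subset) else 0

  flatAE <- params_flatten(ae_skeleton(state))
  flatD <- params_flatten(mlp_wb(state$disc))
  adamAE <- adam_init(flatAE)
  adamD <- adam_init(flatD)

  hist <- matrix(NA_real_, cfg$epochs, 7,
                 dimnames = list(NULL, c("loss_attr", "loss_topo", "loss_recon",
                                         "loss_adv", "loss_gen",
                                         "attr_self", "attr_cross")))
  nMo <- N_o * M

  for (ep in seq_len(cfg$epochs)) {
    # --- fixed-order random draws (unconditional, for trace comparability)
    samp_self <- if (!full_self)
      draw_pairs(ps_self, m_self, cfg$neg_pos_ratio) else NULL
    samp_cross <- if (!is.null(ps_cross) && m_cross > 0)
      draw_pairs(ps_cross, m_cross, cfg$neg_pos_ratio) else NULL
    Zprior <- matrix(stats::rnorm(N * l), N, l)

    # --- encoder forwards
    feX <- if (use_attr) mlp_forward(state$attr_enc, X_o) else NULL
    ftopo <- if (use_topo) topo_forward(state$topo_enc, Xp, ctx) else NULL
    Z_Xo <- if (use_attr) feX$out else NULL
    Z_A <- if (use_topo) ftopo$out else NULL

    # --- (a) discriminator step
    gD <- flat_zero_like(flatD)
    fdp <- mlp_forward(state$disc, Zprior)
    sp <- as.vector(fdp$out)
    l_adv <- 2 * mean(softplus(-sp))          # 2 E[-log D(Z')]
    bp <- mlp_backward(state$disc, fdp$cache,
                       matrix(2 * (sigmoid(sp) - 1) / length(sp), ncol = 1))
    gD <- flat_add(gD, params_flatten(list(W = bp$gW, b = bp$gb)))
    for (Zenc in list(Z_Xo, Z_A)) {
      if (is.null(Zenc)) next
      fd <- mlp_forward(state$disc, Zenc)
      s <- as.vector(fd$out)
      l_adv <- l_adv + mean(softplus(s))      # E[-log(1 - D(Z))]
      bb <- mlp_backward(state$disc, fd$cache,
                         matrix(sigmoid(s) / length(s), ncol = 1))
      gD <- flat_add(gD, params_flatten(list(W = bb$gW, b = bb$gb)))
    }
    up <- adam_step(flatD, gD, adamD, cfg$disc_lr)
    flatD <- up$flat; adamD <- up$state
    wb <- params_apply(mlp_wb(state$disc), flatD)
    state$disc$W <- wb$W; state$disc$b <- wb$b

    # --- (b) autoencoder step
    gZx <- if (use_attr) matrix(0, N_o, l) else NULL
    gZa <- if (use_topo) matrix(0, N, l) else NULL
    g_attr_dec <- g_topo_dec <- NULL
    l_attr_self <- l_attr_cross <- l_topo <- 0

    if (use_attr) {
      fd1 <- mlp_forward(state$attr_dec, Z_Xo)
      l_attr_self <- sum((X_o - fd1$out)^2) / nMo
      b1 <- mlp_backward(state$attr_dec, fd1$cache, 2 * (fd1$out - X_o) / nMo)
      g_attr_dec <- params_flatten(list(W = b1$gW, b = b1$gb))
      gZx <- gZx + b1$gin
    }
    if (use_attr && use_topo && cfg$lambda_cross > 0) {
      Z_Ao <- Z_A[obs, , drop = FALSE]
      fd2 <- mlp_forward(state$attr_dec, Z_Ao)
      l_attr_cross <- sum((X_o - fd2$out)^2) / nMo
      b2 <- mlp_backward(state$attr_dec, fd2$cache,
                         cfg$lambda_cross * 2 * (fd2$out - X_o) / nMo)
      g_attr_dec <- flat_add(g_attr_dec, params_flatten(list(W = b2$gW, b = b2$gb)))
      gZa[obs, ] <- gZa[obs, ] + b2$gin
    }
    l_attr <- l_attr_self + cfg$lambda_cross * l_attr_cross

    if (use_topo) {
      fza <- mlp_forward(state$topo_dec, Z_A)
      r <- if (full_self) adj_bce_full(fza$out, T_self)
           else adj_bce_sampled(fza$out, samp_self)
      l_topo <- r$loss
      bt <- mlp_backward(state$topo_dec, fza$cache, r$gZh)
      g_topo_dec <- params_flatten(list(W = bt$gW, b = bt$gb))
      gZa <- gZa + bt$gin
    }
    if (use_attr && use_topo && cfg$lambda_cross > 0 && cross_has_edges) {
      fzx <- mlp_forward(state$topo_dec, Z_Xo)
      rc <- if (full_cross) adj_bce_full(fzx$out, T_cross)
            else adj_bce_sampled(fzx$out, samp_cross)
      l_topo <- l_topo + cfg$lambda_cross * rc$loss
      btc <- mlp_backward(state$topo_dec, fzx$cache,
                          cfg$lambda_cross * rc$gZh)
      g_topo_dec <- flat_add(g_topo_dec,
                             params_flatten(list(W = btc$gW, b = btc$gb)))
      gZx <- gZx + btc$gin
    }

    l_gen <- 0
    if (cfg$lambda_adv > 0) {
      for (which_z in c("x", "a")) {
        Zenc <- if (which_z == "x") Z_Xo else Z_A
        if (is.null(Zenc)) next
        fd <- mlp_forward(state$disc, Zenc)
        s <- as.vector(fd$out)
        if (cfg$adv_mode == "nonsaturating") {
          l_gen <- l_gen + mean(softplus(-s))           # -log D(Z)
          dlog <- (sigmoid(s) - 1) / length(s)
        } else {
          l_gen <- l_gen - mean(softplus(s))            # log(1 - D(Z))
          dlog <- -sigmoid(s) / length(s)
        }
        bg <- mlp_backward(state$disc, fd$cache, matrix(dlog, ncol = 1))
        if (which_z == "x") gZx <- gZx + cfg$lambda_adv * bg$gin
        else gZa <- gZa + cfg$lambda_adv * bg$gin
      }
    }

    gflat <- flat_zero_like(flatAE)
    if (use_attr) {
      be <- mlp_backward(state$attr_enc, feX$cache, gZx)
      gflat <- flat_add(gflat, params_flatten(
        list(attr_enc = list(W = be$gW, b = be$gb))))
      gflat <- flat_add(gflat, params_flatten(list(attr_dec = params_apply(
        mlp_wb(state$attr_dec), g_attr_dec))))
    }
    if (use_topo) {
      bt2 <- topo_backward(state$topo_enc, ftopo$cache, ctx, gZa)
      gflat <- flat_add(gflat, params_flatten(list(
        topo_edge = list(W = bt2$edge_mlp$gW, b = bt2$edge_mlp$gb),
        topo_rounds = bt2$rounds,
        topo_out = bt2$out)))
      gflat <- flat_add(gflat, params_flatten(list(topo_dec = params_apply(
        mlp_wb(state$topo_dec), g_topo_dec))))
    }
    up <- adam_step(flatAE, gflat, adamAE, cfg$lr)
    flatAE <- up$flat; adamAE <- up$state
    state <- ae_write_back(state, params_apply(ae_skeleton(state), flatAE))

    l_recon <- l_attr + l_topo
    hist[ep, ] <- c(l_attr, l_topo, l_recon, l_adv, l_gen,
                    l_attr_self, l_attr_cross)
    if (!all(is.finite(hist[ep, ])))
      stop(sprintf("non-finite loss at epoch %d (attr=%.4g topo=%.4g adv=%.4g); reduce lr or check inputs",
                   ep, l_attr, l_topo, l_adv))
    if (verbose && (ep %% 50 == 0 || ep == 1))
      message(sprintf("epoch %4d | attr %.4f | topo %.4f | adv %.4f",
                      ep, l_attr, l_topo, l_adv))
  }
  check_finite_params(flatAE, "training")
  state$history <- as.data.frame(cbind(epoch = seq_len(cfg$epochs), hist))
  state$trained <- TRUE
  state$modules <- modules
  state
}

#' Extract ATTR / TOPO / COMB encodings for every location
#'
#' ATTR rows at observed locations come from the attribute encoder on the
#' measured expression; at padding/masked locations the attribute encoder is
#' applied to the feature-propagation-imputed expression (ATTR_FP). TOPO
#' covers all locations. COMB is their column-wise concatenation.
#'
#' @param ds the `SpatialDataset` the model was trained on
#' @param graph the `SpatialGraph` used in training
#' @param state a trained `ModelState`
#' @return an `EncodingBundle`: list with `ATTR` (observed rows),
#'   `ATTR_FP` (unobserved rows, possibly 0-row), `ATTR_full` (N x l),
#'   `TOPO` (N x l), `COMB` (N x 2l), `source_flag` per location
#'   (`"observed"`/`"inferred"`), row names = location ids.
#' @export
extract_encodings <- function(ds, graph, state) {
  if (!isTRUE(state$trained)) stop("model state is untrained")
  validate_dataset(ds)
  obs_mask <- ds$status == "observed"
  obs <- which(obs_mask)
  if (all(obs_mask)) {
    Xp <- ds$expr
  } else {
    Xp <- propagate_features(ds$expr, graph, obs_mask,
                             max_iter = state$cfg$fp_max_iter,
                             tol = state$cfg$fp_tol)$X_full
  }
  N <- nrow(ds$expr); l <- state$cfg$latent_dim
  ATTR_full <- encode_attr(Xp, state)
  TOPO <- encode_topo(Xp, graph, state)
  rownames(ATTR_full) <- rownames(TOPO) <- ds$location_ids
  COMB <- cbind(ATTR_full, TOPO)
  colnames(COMB) <- c(paste0("attr", seq_len(l)), paste0("topo", seq_len(l)))
  structure(list(
    ATTR = ATTR_full[obs, , drop = FALSE],
    ATTR_FP = ATTR_full[!obs_mask, , drop = FALSE],
    ATTR_full = ATTR_full, TOPO = TOPO, COMB = COMB,
    source_flag = ifelse(obs_mask, "observed", "inferred"),
    location_ids = ds$location_ids
  ), class = "EncodingBundle")
}

#' @export
print.EncodingBundle <- function(x, ...) {
  cat(sprintf("EncodingBundle: %d locations (%d observed, %d inferred), l=%d\n",
              nrow(x$TOPO), sum(x$source_flag == "observed"),
              sum(x$source_flag == "inferred"), ncol(x$TOPO)))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Single-file JSON archive of all parameter tensors, the configuration and
#' the training history.
#'
#' @param state a `ModelState`
#' @param path checkpoint file path
#' @return `load_model` returns the restored `ModelState`
#' @export
save_model <- function(state, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  flat <- params_flatten(c(ae_skeleton(state), list(disc = mlp_wb(state$disc))))
  ser <- lapply(flat, function(p) list(dim = dim(p), x = as.vector(p)))
  obj <- list(params = ser, cfg = unclass(state$cfg), M = state$M,
              history = state$history, trained = state$trained)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(stweave_config, obj$cfg[setdiff(names(obj$cfg), NULL)])
  state <- init_model_state(obj$M, cfg)
  flat <- params_flatten(c(ae_skeleton(state), list(disc = mlp_wb(state$disc))))
  for (k in names(flat)) {
    p <- obj$params[[k]]
    v <- as.numeric(p$x)
    flat[[k]] <- if (length(p$dim)) array(v, dim = unlist(p$dim)) else v
  }
  full <- params_apply(c(ae_skeleton(state), list(disc = mlp_wb(state$disc))),
                       flat)
  state <- ae_write_back(state, full)
  state$disc$W <- full$disc$W; state$disc$b <- full$disc$b
  state$history <- as.data.frame(obj$history)
  state$trained <- isTRUE(obj$trained)
  state
}
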