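# Minimal dense neural-network core: ELU MLPs with hand-derived reverse-mode
# gradients and an Adam optimizer over flat lists of parameter arrays.
# Everything is full-batch matrix algebra; correctness is guarded by
# finite-difference gradient checks in the test suite.

# branch-free forms: cheaper than ifelse() on large matrices
elu <- function(x) pmax(x, 0) + expm1(pmin(x, 0))
elu_grad <- function(x, fx) 1 + fx * (x <= 0)

sigmoid <- function(x) 1 / (1 + exp(-x))
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Initialise a multilayer perceptron
#'
#' Hidden layers use ELU; the output layer is linear (downstream losses add
#' sigmoid/softplus where needed). Weights are Glorot-uniform draws from the
#' current RNG state, so callers control determinism with `set.seed()`.
#'
#' @param d_in input width
#' @param hidden integer vector of hidden widths (may be empty)
#' @param d_out output width
#' @return an `mlp` object (list of weight matrices `W` and bias vectors `b`)
#' @export
mlp_init <- function(d_in, hidden, d_out) {
  sizes <- c(d_in, hidden, d_out)
  L <- length(sizes) - 1L
  W <- b <- vector("list", L)
  for (l in seq_len(L)) {
    r <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -r, r),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  structure(list(W = W, b = b, sizes = sizes), class = "mlp")
}

#' Forward pass of an MLP
#'
#' @param mlp an [mlp_init()] object
#' @param X input matrix (rows = samples)
#' @return list with `out` (output matrix) and `cache` for [mlp_backward()]
#' @export
mlp_forward <- function(mlp, X) {
  X <- as.matrix(X)
  if (ncol(X) != mlp$sizes[1])
    stop(sprintf("input has %d columns, MLP expects %d", ncol(X), mlp$sizes[1]))
  L <- length(mlp$W)
  H <- vector("list", L + 1L)  # H[[l]] = activation entering layer l
  Z <- vector("list", L)       # pre-activations
  H[[1]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(H[[l]] %*% mlp$W[[l]], 2, mlp$b[[l]], "+")
    H[[l + 1]] <- if (l < L) elu(Z[[l]]) else Z[[l]]
  }
  list(out = H[[L + 1]], cache = list(H = H, Z = Z))
}

#' Backward pass of an MLP
#'
#' @param mlp an [mlp_init()] object
#' @param cache the cache returned by [mlp_forward()]
#' @param G gradient of the loss with respect to the MLP output
#' @return list with `gW`, `gb` (parameter gradients) and `gin` (gradient
#'   with respect to the input)
#' @export
mlp_backward <- function(mlp, cache, G) {
  L <- length(mlp$W)
  gW <- gb <- vector("list", L)
  D <- as.matrix(G)
  for (l in rev(seq_len(L))) {
    if (l < L) D <- D * elu_grad(cache$Z[[l]], cache$H[[l + 1]])
    gW[[l]] <- crossprod(cache$H[[l]], D)
    gb[[l]] <- colSums(D)
    D <- tcrossprod(D, mlp$W[[l]])
  }
  list(gW = gW, gb = gb, gin = D)
}

# ---- flat parameter-list plumbing (for Adam and checkpoints) ----

params_flatten <- function(x, prefix = "") {
  if (is.list(x)) {
    out <- list()
    nms <- names(x)
    if (is.null(nms)) nms <- as.character(seq_along(x))
    for (k in seq_along(x))
      out <- c(out, params_flatten(x[[k]], paste0(prefix, ".", nms[k])))
    out
  } else {
    stats::setNames(list(x), prefix)
  }
}

params_apply <- function(x, flat, prefix = "") {
  if (is.list(x)) {
    nms <- names(x)
    if (is.null(nms)) nms <- as.character(seq_along(x))
    for (k in seq_along(x))
      x[[k]] <- params_apply(x[[k]], flat, paste0(prefix, ".", nms[k]))
    x
  } else {
    flat[[prefix]]
  }
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0),
       t = 0L)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (k in names(flat)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    flat[[k]] <- flat[[k]] -
      lr * (state$m[[k]] / b1t) / (sqrt(state$v[[k]] / b2t) + eps)
  }
  list(flat = flat, state = state)
}

flat_add <- function(a, b) {
  for (k in names(b)) a[[k]] <- if (is.null(a[[k]])) b[[k]] else a[[k]] + b[[k]]
  a
}

flat_zero_like <- function(flat) lapply(flat, function(p) p * 0)

check_finite_params <- function(flat, where) {
  bad <- names(flat)[!vapply(flat, function(p) all(is.finite(p)), logical(1))]
  if (length(bad))
    stop("non-finite parameters after ", where, ": ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}
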