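## Dense rectified-linear Q-network over the discrete dose-action space,
## implemented with base matrix algebra. Small networks at the problem sizes
## used here train in seconds on one CPU; everything is seeded and exactly
## reproducible.

#' Q-network architecture specification
#'
#' @param n_features Input width (state dimension).
#' @param n_actions Output width; one Q-value per discrete dose action.
#' @param hidden Integer vector of hidden-layer widths. The full-scale
#'   default is three hidden layers of 256 units.
#' @return An object of class `qnet_spec`.
#' @export
qnet_spec <- function(n_features, n_actions = 16L, hidden = c(256L, 256L, 256L)) {
  check_number(n_features, "n_features", lower = 1, integer = TRUE)
  check_number(n_actions, "n_actions", lower = 2, integer = TRUE)
  if (length(hidden) < 1L || any(hidden < 1))
    stopf("'hidden' must contain at least one positive layer width")
  structure(list(n_features = as.integer(n_features),
                 n_actions = as.integer(n_actions),
                 hidden = as.integer(hidden)),
            class = "qnet_spec")
}

## He-scaled initialization; draws come from the current RNG stream.
qnet_init <- function(spec) {
  dims <- c(spec$n_features, spec$hidden, spec$n_actions)
  L <- length(dims) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1L], 0, sqrt(2 / dims[l])),
                     dims[l], dims[l + 1L])
    b[[l]] <- rep(0, dims[l + 1L])
  }
  structure(list(W = W, b = b, spec = spec), class = "qnet")
}

## Forward pass; returns the Q matrix (n x actions) and, optionally, the
## layer activations needed for backpropagation.
qnet_forward <- function(net, X, keep_cache = FALSE) {
  L <- length(net$W)
  A <- X
  cache <- if (keep_cache) vector("list", L) else NULL
  for (l in seq_len(L)) {
    if (keep_cache) cache[[l]] <- A
    Z <- sweep(A %*% net$W[[l]], 2, net$b[[l]], "+")
    A <- if (l < L) pmax(Z, 0) else Z
  }
  if (keep_cache) list(Q = A, cache = cache) else list(Q = A)
}

## Backpropagate dL/dQ through the network; returns parameter gradients.
qnet_backward <- function(net, cache, dQ) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- dQ
  for (l in rev(seq_len(L))) {
    A_in <- cache[[l]]
    gW[[l]] <- crossprod(A_in, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(net$W[[l]])
      ## rectifier derivative on the input activation of this layer
      delta <- delta * (A_in > 0)
    }
  }
  list(W = gW, b = gb)
}

adam_init <- function(net) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero_like(net$W), vW = zero_like(net$W),
       mb = zero_like(net$b), vb = zero_like(net$b), t = 0L)
}

adam_step <- function(net, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t; c2 <- 1 - beta2^opt$t
  for (l in seq_along(net$W)) {
    opt$mW[[l]] <- beta1 * opt$mW[[l]] + (1 - beta1) * grads$W[[l]]
    opt$vW[[l]] <- beta2 * opt$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (opt$mW[[l]] / c1) /
      (sqrt(opt$vW[[l]] / c2) + eps)
    opt$mb[[l]] <- beta1 * opt$mb[[l]] + (1 - beta1) * grads$b[[l]]
    opt$vb[[l]] <- beta2 * opt$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (opt$mb[[l]] / c1) /
      (sqrt(opt$vb[[l]] / c2) + eps)
  }
  list(net = net, opt = opt)
}

## Z-score scaler fitted on training states; constant columns get unit scale.
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[!is.finite(sdv) | sdv < 1e-8] <- 1
  list(center = mu, scale = sdv)
}

apply_scaler <- function(scaler, X) {
  if (is.null(scaler)) return(X)
  sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
}
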