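# Minimal neural-network primitives with hand-derived backward passes.
#
# Parameters live in flat named lists of base-R matrices/vectors; gradients
# mirror the names. Message passing uses Matrix sparse products, so a batch
# of molecules is one block-diagonal graph. Initialization is the standard
# uniform fan-in scheme U(-1/sqrt(fan_in), +1/sqrt(fan_in)).

init_linear <- function(n_out, n_in) {
  bound <- 1 / sqrt(n_in)
  list(W = matrix(stats::runif(n_out * n_in, -bound, bound), n_out, n_in),
       b = stats::runif(n_out, -bound, bound))
}

relu <- function(x) pmax(x, 0)

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

sigmoid <- function(x) 1 / (1 + exp(-x))

row_broadcast <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

# Two-layer MLP: Linear -> activation -> Linear. X is n x d_in.
mlp2_forward <- function(X, p, prefix, act = c("relu", "softplus")) {
  act <- match.arg(act)
  W1 <- p[[paste0(prefix, ".W1")]]; b1 <- p[[paste0(prefix, ".b1")]]
  W2 <- p[[paste0(prefix, ".W2")]]; b2 <- p[[paste0(prefix, ".b2")]]
  Z1 <- X %*% t(W1) + row_broadcast(b1, nrow(X))
  R <- if (act == "relu") relu(Z1) else softplus(Z1)
  out <- R %*% t(W2) + row_broadcast(b2, nrow(X))
  list(out = out, X = X, Z1 = Z1, R = R, act = act, prefix = prefix)
}

mlp2_backward <- function(cache, dOut, p, grads) {
  prefix <- cache$prefix
  W1 <- p[[paste0(prefix, ".W1")]]; W2 <- p[[paste0(prefix, ".W2")]]
  grads[[paste0(prefix, ".W2")]] <- grads[[paste0(prefix, ".W2")]] +
    t(dOut) %*% cache$R
  grads[[paste0(prefix, ".b2")]] <- grads[[paste0(prefix, ".b2")]] +
    colSums(dOut)
  dR <- dOut %*% W2
  dZ1 <- if (cache$act == "relu") dR * (cache$Z1 > 0) else
    dR * sigmoid(cache$Z1)
  grads[[paste0(prefix, ".W1")]] <- grads[[paste0(prefix, ".W1")]] +
    t(dZ1) %*% cache$X
  grads[[paste0(prefix, ".b1")]] <- grads[[paste0(prefix, ".b1")]] +
    colSums(dZ1)
  list(dX = dZ1 %*% W1, grads = grads)
}

# Per-feature batch normalization over all nodes in the batch.
BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_forward <- function(Z, gamma, beta, state, key, training) {
  n <- nrow(Z)
  if (training) {
    mu <- colMeans(Z)
    v <- colMeans(Z * Z) - mu^2
    v <- pmax(v, 0)
    state[[paste0(key, ".mean")]] <-
      (1 - BN_MOMENTUM) * state[[paste0(key, ".mean")]] + BN_MOMENTUM * mu
    state[[paste0(key, ".var")]] <-
      (1 - BN_MOMENTUM) * state[[paste0(key, ".var")]] + BN_MOMENTUM * v
  } else {
    mu <- state[[paste0(key, ".mean")]]
    v <- state[[paste0(key, ".var")]]
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- (Z - row_broadcast(mu, n)) * row_broadcast(invstd, n)
  out <- xhat * row_broadcast(gamma, n) + row_broadcast(beta, n)
  list(out = out, xhat = xhat, invstd = invstd, state = state,
       training = training)
}

bn_backward <- function(cache, dOut, gamma) {
  n <- nrow(dOut)
  dgamma <- colSums(dOut * cache$xhat)
  dbeta <- colSums(dOut)
  dxhat <- dOut * row_broadcast(gamma, n)
  if (cache$training) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dZ <- (dxhat - row_broadcast(s1 / n, n) -
             cache$xhat * row_broadcast(s2 / n, n)) *
      row_broadcast(cache$invstd, n)
  } else {
    dZ <- dxhat * row_broadcast(cache$invstd, n)
  }
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

# Adam optimizer state and update (beta1 = 0.9, beta2 = 0.999).
adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, opt = opt)
}

zero_grads <- function(params) {
  lapply(params, function(p) {
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  })
}
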