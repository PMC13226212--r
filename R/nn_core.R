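# Minimal dense-matrix neural-network primitives: leaky rectifier, Glorot
# initialization, batch normalization, and the AdamW update. Everything
# operates in a columns-are-samples convention (features x batch).

lrelu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)
lrelu_grad <- function(x, slope = 0.01) ifelse(x > 0, 1, slope)

glorot <- function(n_out, n_in) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Trainable scale/shift live in the parameter tree; running statistics are
# optimizer-invisible state. X: width x B.
new_bn_run <- function(width) {
  list(mean = rep(0, width), var = rep(1, width))
}

batchnorm_forward <- function(X, gamma, beta, run, train) {
  if (train) {
    mu <- rowMeans(X)
    v <- rowMeans((X - mu)^2)
    run$mean <- (1 - BN_MOMENTUM) * run$mean + BN_MOMENTUM * mu
    run$var <- (1 - BN_MOMENTUM) * run$var + BN_MOMENTUM * v
  } else {
    mu <- run$mean
    v <- run$var
  }
  inv_sd <- 1 / sqrt(v + BN_EPS)
  xhat <- (X - mu) * inv_sd
  out <- gamma * xhat + beta
  list(out = out, run = run,
       cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma))
}

# Training-mode backward (batch statistics participate in the gradient).
batchnorm_backward <- function(dout, cache) {
  B <- ncol(dout)
  dgamma <- rowSums(dout * cache$xhat)
  dbeta <- rowSums(dout)
  dxhat <- dout * cache$gamma
  dX <- (cache$inv_sd / B) *
    (B * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- recursive parameter-tree helpers (params are nested lists of numeric
# arrays; the tree shape is shared by gradients and optimizer state) ----

param_map <- function(p, f) {
  if (is.list(p)) lapply(p, param_map, f = f) else f(p)
}

param_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (k in seq_along(a)) out[[k]] <- param_map2(a[[k]], b[[k]], f)
    out
  } else {
    f(a, b)
  }
}

zeros_like <- function(p) param_map(p, function(x) x * 0)

adamw_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adamw_step <- function(params, grads, state, lr = 0.01, weight_decay = 0.01,
                       betas = c(0.9, 0.999), eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1L]; b2 <- betas[2L]
  state$m <- param_map2(state$m, grads, function(m, g) b1 * m + (1 - b1) * g)
  state$v <- param_map2(state$v, grads, function(v, g) b2 * v + (1 - b2) * g^2)
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  upd <- param_map2(state$m, state$v, function(m, v) {
    (m / bc1) / (sqrt(v / bc2) + eps)
  })
  params <- param_map2(params, upd, function(p, u) {
    p - lr * u - lr * weight_decay * p
  })
  list(params = params, state = state)
}

# first-index argmax per row plus the pooled vector
max_pool_rows <- function(Z) {
  idx <- max.col(Z, ties.method = "first")
  list(values = Z[cbind(seq_len(nrow(Z)), idx)], idx = idx)
}
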