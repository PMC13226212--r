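#' Multi-dimensional graph convolution (mGCN) forward pass
#'
#' One mGCN layer over a multigraph with D edge dimensions sharing one node
#' set. With the general representation H (nodes as columns internally), the
#' layer computes per dimension a projected representation
#' \eqn{E_d = \sigma(W_d H)}, a within-dimension aggregation
#' \eqn{H_w^d = E_d \hat{A}_d} over the row-normalized adjacency, and an
#' across-dimension aggregation \eqn{H_a^d = \sum_g b_{g,d} E_g} whose
#' attention weights are a softmax over \eqn{p_{g,d} = tr(W_g^T M_k W_d)}
#' (a trainable bilinear form on the projections). The new dimension
#' representations \eqn{H_d = (H_w^d + H_a^d)/2} are concatenated and
#' projected: \eqn{H' = \sigma(W \, Concat_d H_d)}.
#'
#' @param H n x F node-feature matrix (rows are nodes).
#' @param adjacencies List of D n x n symmetric 0/1 adjacency matrices.
#' @param params List with `Wd` (list of D  out x F projection matrices),
#'   `M` (out x out bilinear matrix), `W` (out x (out*D) output projection).
#' @param slope Leaky-rectifier slope (default 0.01).
#' @return List with `H_new` (n x out new general representation) and
#'   `b` (D x D matrix of attention weights, columns indexed by target
#'   dimension d and summing to 1).
#' @export
mgcn_forward <- function(H, adjacencies, params, slope = 0.01) {
  Hc <- t(as.matrix(H))
  Ahat <- lapply(adjacencies, row_normalize)
  fw <- mgcn_forward_internal(Hc, Ahat, params, slope)
  list(H_new = t(fw$Hp), b = fw$b)
}

# row-normalized adjacency; zero-degree rows stay zero
row_normalize <- function(A) {
  A <- as.matrix(A)
  deg <- rowSums(A)
  A / ifelse(deg > 0, deg, 1)
}

# symmetric normalization with self-loops: D^{-1/2} (A + I) D^{-1/2}
sym_normalize <- function(A) {
  A <- as.matrix(A) + diag(nrow(A))
  inv_sqrt <- 1 / sqrt(rowSums(A))
  A * outer(inv_sqrt, inv_sqrt)
}

# ---- internal column-convention forward/backward passes with caches ----
# Hc: F x n; Ahat: list of n x n normalized adjacencies.

mgcn_forward_internal <- function(Hc, Ahat, params, slope) {
  D <- length(Ahat)
  if (length(params$Wd) != D) {
    stop("mGCN parameter count (", length(params$Wd),
         ") does not match number of dimensions (", D, ")")
  }
  S <- vector("list", D); E <- vector("list", D)
  MW <- vector("list", D)                    # M %*% W_d, reused in p and grads
  for (d in seq_len(D)) {
    S[[d]] <- params$Wd[[d]] %*% Hc
    E[[d]] <- lrelu(S[[d]], slope)
    MW[[d]] <- params$M %*% params$Wd[[d]]
  }
  p <- matrix(0, D, D)
  for (d in seq_len(D)) {
    for (g in seq_len(D)) p[g, d] <- sum(params$Wd[[g]] * MW[[d]])
  }
  b <- apply(p, 2L, function(col) {
    e <- exp(col - max(col))
    e / sum(e)
  })
  b <- matrix(b, D, D)
  Hd <- vector("list", D); Hw <- vector("list", D); Ha <- vector("list", D)
  for (d in seq_len(D)) {
    Hw[[d]] <- E[[d]] %*% Ahat[[d]]
    Ha_d <- b[1L, d] * E[[1L]]
    if (D > 1L) for (g in 2:D) Ha_d <- Ha_d + b[g, d] * E[[g]]
    Ha[[d]] <- Ha_d
    Hd[[d]] <- 0.5 * (Hw[[d]] + Ha_d)
  }
  C <- do.call(rbind, Hd)
  Sp <- params$W %*% C
  Hp <- lrelu(Sp, slope)
  list(Hp = Hp, b = b,
       cache = list(Hc = Hc, Ahat = Ahat, S = S, E = E, p = p, b = b,
                    C = C, Sp = Sp, MW = MW))
}

mgcn_backward_internal <- function(dHp, params, cache, slope) {
  D <- length(cache$Ahat)
  width <- nrow(params$M)
  dSp <- dHp * lrelu_grad(cache$Sp, slope)
  dW <- dSp %*% t(cache$C)
  dC <- crossprod(params$W, dSp)
  dWd <- lapply(params$Wd, function(w) w * 0)
  dM <- params$M * 0
  dE <- lapply(cache$E, function(e) e * 0)
  db <- matrix(0, D, D)
  for (d in seq_len(D)) {
    rows <- ((d - 1L) * width + 1L):(d * width)
    dHd <- dC[rows, , drop = FALSE]
    dHw <- 0.5 * dHd
    dHa <- 0.5 * dHd
    dE[[d]] <- dE[[d]] + dHw %*% t(cache$Ahat[[d]])
    for (g in seq_len(D)) {
      dE[[g]] <- dE[[g]] + cache$b[g, d] * dHa
      db[g, d] <- sum(dHa * cache$E[[g]])
    }
  }
  # softmax (per column d) then bilinear-trace backward
  for (d in seq_len(D)) {
    bd <- cache$b[, d]
    dp <- bd * (db[, d] - sum(db[, d] * bd))
    for (g in seq_len(D)) {
      if (dp[g] == 0) next
      dWd[[g]] <- dWd[[g]] + dp[g] * cache$MW[[d]]
      dWd[[d]] <- dWd[[d]] + dp[g] * crossprod(params$M, params$Wd[[g]])
      dM <- dM + dp[g] * tcrossprod(params$Wd[[g]], params$Wd[[d]])
    }
  }
  for (d in seq_len(D)) {
    dS <- dE[[d]] * lrelu_grad(cache$S[[d]], slope)
    dWd[[d]] <- dWd[[d]] + dS %*% t(cache$Hc)
  }
  list(Wd = dWd, M = dM, W = dW)
}

# single graph-convolution layer: Z = lrelu(W (Hc Ahat_sym) + bias)
gcn_forward_internal <- function(Hc, Ahat, W, bias, slope) {
  P <- Hc %*% Ahat
  S <- W %*% P + bias
  list(Z = lrelu(S, slope), cache = list(P = P, S = S))
}

gcn_backward_internal <- function(dZ, cache, slope) {
  dS <- dZ * lrelu_grad(cache$S, slope)
  list(dW = dS %*% t(cache$P), dbias = rowSums(dS))
}
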