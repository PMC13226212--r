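# per-pair scalar brute-force oracles for the three couplings; deliberately
# written mode-by-mode and pair-by-pair, independent of the vectorized paths

codir_oracle <- function(modes, i, j) {
  w <- 1 / modes$omega_sq
  num <- 0; den <- 0
  for (a in seq_along(w)) {
    xi <- modes$shapes[a, i, ]; xj <- modes$shapes[a, j, ]
    ni <- sqrt(sum(xi^2)); nj <- sqrt(sum(xj^2))
    if (ni < 1e-12 || nj < 1e-12) next
    num <- num + w[a] * sum(xi * xj) / (ni * nj)
    den <- den + w[a]
  }
  if (den == 0) NaN else num / den
}

coord_oracle <- function(modes, structure, i, j) {
  w <- 1 / modes$omega_sq
  u <- structure$coords[i, ] - structure$coords[j, ]
  u <- u / sqrt(sum(u^2))
  acc <- 0
  for (a in seq_along(w)) {
    acc <- acc + w[a] * sum(u * (modes$shapes[a, i, ] - modes$shapes[a, j, ]))^2
  }
  1 - 0.5 * acc
}

deform_F <- function(modes, i, j) {
  w <- 1 / modes$omega_sq
  FF <- matrix(0, 3, 3)
  for (m in 1:3) for (nn in 1:3) {
    FF[m, nn] <- sum(modes$shapes[, i, m] * modes$shapes[, j, nn] * w)
  }
  FF
}

random_symmetric_coupling <- function(n, seed, kind = "coordination") {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dynamelt:::new_coupling(m, kind)
}

edge_key <- function(es) {
  if (!nrow(es$edges)) return(character(0))
  paste(es$edges[, 1], es$edges[, 2])
}

# brute-force reference for every threshold scheme: direct sort/inequality
oracle_edges <- function(vals, scheme, p, ncont = NULL, stats = NULL) {
  n <- nrow(vals)
  ut <- which(upper.tri(vals), arr.ind = TRUE)
  cv <- vals[upper.tri(vals)]
  keep <- switch(scheme,
    N = cv >= min(cv) + (100 - p) / 100 * (max(cv) - min(cv)),
    DN = cv >= stats$coupling_min +
      (100 - p) / 100 * (stats$coupling_max - stats$coupling_min),
    SIGMA = {
      mu <- mean(cv); sig <- sqrt(mean((cv - mu)^2))
      cv > mu + p * sig
    },
    DSIGMA = cv > stats$mu + p * stats$sigma,
    CONT = , DCONT = , PAIR = {
      k <- switch(scheme,
                  CONT = round(p * ncont),
                  DCONT = round(p * stats$mean_contact_edges),
                  PAIR = round(p / 100 * length(cv)))
      k <- min(k, length(cv))
      o <- order(-cv, ut[, 1], ut[, 2])
      mask <- rep(FALSE, length(cv)); mask[o[seq_len(k)]] <- TRUE
      mask
    })
  sort(paste(ut[keep, 1] - 1L, ut[keep, 2] - 1L))
}
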