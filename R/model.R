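#' Model configuration
#'
#' Architecture and optimization settings for the melting-temperature
#' regressor: the graph feature extractor, which multigraph dimensions it
#' reads, and the training protocol (AdamW with learning rate 0.01, weight
#' decay 0.01, betas 0.9/0.999; 30 epochs; batch size 64; 10-fold
#' cross-validation with per-fold best-validation-epoch selection).
#'
#' Extractors: `S1` applies one graph-convolution layer (width 32) to a
#' single graph and max-pools over nodes; `M1` runs one independent width-32
#' convolution per dimension and concatenates before pooling; `M2` is the
#' multi-dimensional graph convolution ([mgcn_forward()]) with width 32.
#'
#' @param extractor `"S1"`, `"M1"` or `"M2"`.
#' @param dimensions Character vector of edge-set names the model consumes
#'   (default the study's best configuration: contact plus the three
#'   dynamical graphs). `S1` requires exactly one.
#' @param graph_feature_width Per-dimension convolution width (default 32).
#' @param ogt_widths Widths of the two OGT branch layers (default 20, 10).
#' @param activation_slope Leaky-rectifier slope (default 0.01).
#' @param lr,weight_decay,betas AdamW settings (defaults 0.01, 0.01,
#'   c(0.9, 0.999)).
#' @param epochs,batch_size,folds Training protocol (defaults 30, 64, 10).
#' @param seed Integer seed controlling initialization, fold assignment and
#'   batch shuffling.
#' @return A `dyn_model_config`.
#' @export
model_config <- function(extractor = c("M2", "S1", "M1"),
                         dimensions = c("contact", "codirectionality",
                                        "coordination", "deformation"),
                         graph_feature_width = 32L,
                         ogt_widths = c(20L, 10L),
                         activation_slope = 0.01,
                         lr = 0.01, weight_decay = 0.01,
                         betas = c(0.9, 0.999),
                         epochs = 30L, batch_size = 64L, folds = 10L,
                         seed = 1L) {
  extractor <- match.arg(extractor)
  if (extractor == "S1" && length(dimensions) != 1L) {
    stop("S1 operates on a single graph; give exactly one dimension")
  }
  if (folds < 2L) stop("'folds' must be at least 2")
  if (any(c(graph_feature_width, ogt_widths, epochs, batch_size) < 1L)) {
    stop("widths, epochs and batch size must be positive")
  }
  structure(
    list(extractor = extractor, dimensions = dimensions,
         graph_feature_width = as.integer(graph_feature_width),
         ogt_widths = as.integer(ogt_widths),
         activation_slope = activation_slope,
         lr = lr, weight_decay = weight_decay, betas = betas,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         folds = as.integer(folds), seed = as.integer(seed)),
    class = "dyn_model_config"
  )
}

graph_feature_dim <- function(config) {
  if (config$extractor == "M1") {
    config$graph_feature_width * length(config$dimensions)
  } else {
    config$graph_feature_width
  }
}

# head hidden widths: arithmetic interpolation of (w, 1) at thirds
head_widths <- function(w) {
  c(round(w * 2 / 3 + 1 / 3), round(w / 3 + 2 / 3))
}

# fresh parameter tree + batchnorm running state (uses the current RNG)
init_model <- function(config, n_features) {
  gw <- config$graph_feature_width
  D <- length(config$dimensions)
  extractor <- switch(config$extractor,
    S1 = list(W = glorot(gw, n_features), bias = rep(0, gw)),
    M1 = list(Wd = lapply(seq_len(D), function(d) glorot(gw, n_features)),
              bias = lapply(seq_len(D), function(d) rep(0, gw))),
    M2 = list(Wd = lapply(seq_len(D), function(d) glorot(gw, n_features)),
              M = glorot(gw, gw),
              W = glorot(gw, gw * D))
  )
  ow <- config$ogt_widths
  w_in <- graph_feature_dim(config) + ow[2L]
  hw <- head_widths(w_in)
  params <- list(
    extractor = extractor,
    ogt = list(W1 = glorot(ow[1L], 1L), b1 = rep(0, ow[1L]),
               W2 = glorot(ow[2L], ow[1L]), b2 = rep(0, ow[2L])),
    head = list(W1 = glorot(hw[1L], w_in), b1 = rep(0, hw[1L]),
                g1 = rep(1, hw[1L]), be1 = rep(0, hw[1L]),
                W2 = glorot(hw[2L], hw[1L]), b2 = rep(0, hw[2L]),
                g2 = rep(1, hw[2L]), be2 = rep(0, hw[2L]),
                W3 = glorot(1L, hw[2L]), b3 = 0)
  )
  list(params = params,
       bn_run = list(run1 = new_bn_run(hw[1L]), run2 = new_bn_run(hw[2L])),
       n_features = n_features, head_widths = hw, input_width = w_in)
}

# per-sample preprocessed tensors: transposed features + normalized
# adjacencies in the order config$dimensions
prepare_sample <- function(sample, config) {
  missing <- setdiff(config$dimensions, names(sample$edge_sets))
  if (length(missing)) {
    stop("sample ", sample$protein_id, " lacks edge set(s): ",
         paste(missing, collapse = ", "))
  }
  adj <- lapply(sample$edge_sets[config$dimensions], adjacency_matrix)
  Hc <- t(sample$node_features)
  if (config$extractor == "M2") {
    list(Hc = Hc, Ahat = lapply(adj, row_normalize))
  } else {
    list(Hc = Hc, Ahat = lapply(adj, sym_normalize))
  }
}

extractor_forward <- function(prep, params, config) {
  slope <- config$activation_slope
  if (config$extractor == "M2") {
    fw <- mgcn_forward_internal(prep$Hc, prep$Ahat, params, slope)
    pool <- max_pool_rows(fw$Hp)
    list(feature = pool$values, cache = list(fw = fw, pool = pool))
  } else if (config$extractor == "S1") {
    fw <- gcn_forward_internal(prep$Hc, prep$Ahat[[1L]], params$W, params$bias, slope)
    pool <- max_pool_rows(fw$Z)
    list(feature = pool$values, cache = list(fw = list(fw), pool = list(pool)))
  } else {
    D <- length(prep$Ahat)
    fws <- vector("list", D); pools <- vector("list", D)
    feats <- vector("list", D)
    for (d in seq_len(D)) {
      fws[[d]] <- gcn_forward_internal(prep$Hc, prep$Ahat[[d]],
                                       params$Wd[[d]], params$bias[[d]], slope)
      pools[[d]] <- max_pool_rows(fws[[d]]$Z)
      feats[[d]] <- pools[[d]]$values
    }
    list(feature = unlist(feats), cache = list(fw = fws, pool = pools))
  }
}

extractor_backward <- function(dfeat, params, cache, prep, config) {
  slope <- config$activation_slope
  gw <- config$graph_feature_width
  if (config$extractor == "M2") {
    Hp <- cache$fw$Hp
    dHp <- Hp * 0
    dHp[cbind(seq_len(nrow(Hp)), cache$pool$idx)] <- dfeat
    mgcn_backward_internal(dHp, params, cache$fw$cache, slope)
  } else if (config$extractor == "S1") {
    Z <- cache$fw[[1L]]$Z
    dZ <- Z * 0
    dZ[cbind(seq_len(nrow(Z)), cache$pool[[1L]]$idx)] <- dfeat
    g <- gcn_backward_internal(dZ, cache$fw[[1L]]$cache, slope)
    list(W = g$dW, bias = g$dbias)
  } else {
    D <- length(prep$Ahat)
    dWd <- vector("list", D); dbias <- vector("list", D)
    for (d in seq_len(D)) {
      Z <- cache$fw[[d]]$Z
      dZ <- Z * 0
      seg <- dfeat[((d - 1L) * gw + 1L):(d * gw)]
      dZ[cbind(seq_len(nrow(Z)), cache$pool[[d]]$idx)] <- seg
      g <- gcn_backward_internal(dZ, cache$fw[[d]]$cache, slope)
      dWd[[d]] <- g$dW; dbias[[d]] <- g$dbias
    }
    list(Wd = dWd, bias = dbias)
  }
}

# full batch forward; samples/preps are lists, ogt/labels vectors.
# Returns normalized predictions (1 x B), caches, updated bn state.
model_forward <- function(model, preps, ogt, config, train) {
  p <- model$params
  slope <- config$activation_slope
  B <- length(preps)
  ex <- lapply(preps, extractor_forward, params = p$extractor, config = config)
  G <- vapply(ex, function(e) e$feature, numeric(graph_feature_dim(config)))
  G <- matrix(G, graph_feature_dim(config), B)
  O0 <- matrix(ogt / 100, 1L, B)
  So1 <- p$ogt$W1 %*% O0 + p$ogt$b1
  O1 <- lrelu(So1, slope)
  So2 <- p$ogt$W2 %*% O1 + p$ogt$b2
  O2 <- lrelu(So2, slope)
  Z <- rbind(G, O2)
  Sh1 <- p$head$W1 %*% Z + p$head$b1
  A1 <- lrelu(Sh1, slope)
  bn1 <- batchnorm_forward(A1, p$head$g1, p$head$be1, model$bn_run$run1, train)
  Sh2 <- p$head$W2 %*% bn1$out + p$head$b2
  A2 <- lrelu(Sh2, slope)
  bn2 <- batchnorm_forward(A2, p$head$g2, p$head$be2, model$bn_run$run2, train)
  Y <- p$head$W3 %*% bn2$out + p$head$b3
  model$bn_run <- list(run1 = bn1$run, run2 = bn2$run)
  list(yhat = as.numeric(Y), model = model,
       cache = list(ex = ex, G = G, O0 = O0, So1 = So1, O1 = O1, So2 = So2,
                    O2 = O2, Z = Z, Sh1 = Sh1, bn1 = bn1$cache, B1 = bn1$out,
                    Sh2 = Sh2, bn2 = bn2$cache, B2 = bn2$out))
}

# dLdy: length-B gradient of the loss w.r.t. the normalized prediction
model_backward <- function(model, preps, config, cache, dLdy) {
  p <- model$params
  slope <- config$activation_slope
  dY <- matrix(dLdy, 1L)
  g_head <- list()
  g_head$W3 <- dY %*% t(cache$B2)
  g_head$b3 <- sum(dY)
  dB2 <- crossprod(p$head$W3, dY)
  bb2 <- batchnorm_backward(dB2, cache$bn2)
  g_head$g2 <- bb2$dgamma; g_head$be2 <- bb2$dbeta
  dSh2 <- bb2$dX * lrelu_grad(cache$Sh2, slope)
  g_head$W2 <- dSh2 %*% t(cache$B1)
  g_head$b2 <- rowSums(dSh2)
  dB1 <- crossprod(p$head$W2, dSh2)
  bb1 <- batchnorm_backward(dB1, cache$bn1)
  g_head$g1 <- bb1$dgamma; g_head$be1 <- bb1$dbeta
  dSh1 <- bb1$dX * lrelu_grad(cache$Sh1, slope)
  g_head$W1 <- dSh1 %*% t(cache$Z)
  g_head$b1 <- rowSums(dSh1)
  dZ <- crossprod(p$head$W1, dSh1)
  gd <- graph_feature_dim(config)
  dG <- dZ[seq_len(gd), , drop = FALSE]
  dO2 <- dZ[(gd + 1L):nrow(dZ), , drop = FALSE]
  g_ogt <- list()
  dSo2 <- dO2 * lrelu_grad(cache$So2, slope)
  g_ogt$W2 <- dSo2 %*% t(cache$O1)
  g_ogt$b2 <- rowSums(dSo2)
  dO1 <- crossprod(p$ogt$W2, dSo2)
  dSo1 <- dO1 * lrelu_grad(cache$So1, slope)
  g_ogt$W1 <- dSo1 %*% t(cache$O0)
  g_ogt$b1 <- rowSums(dSo1)
  g_ex <- zeros_like(p$extractor)
  for (s in seq_along(preps)) {
    gs <- extractor_backward(dG[, s], p$extractor, cache$ex[[s]]$cache,
                             preps[[s]], config)
    g_ex <- param_map2(g_ex, gs, `+`)
  }
  # field order must mirror the parameter tree for the optimizer
  list(extractor = g_ex, ogt = g_ogt[c("W1", "b1", "W2", "b2")],
       head = g_head[c("W1", "b1", "g1", "be1", "W2", "b2", "g2", "be2", "W3", "b3")])
}

#' Extract a pooled graph-level feature from a multigraph sample
#'
#' Runs the configured extractor on one sample and max-pools over nodes:
#' `S1` gives a width-32 vector from a single graph, `M1` a width-32*D
#' vector (one independent convolution per dimension, concatenated), `M2` a
#' width-32 vector from the multi-dimensional graph convolution.
#'
#' @param sample A `dyn_multigraph`.
#' @param config A [model_config()].
#' @param weights Extractor parameter list (e.g. `model$params$extractor`
#'   from a trained model, or fresh ones from internal initialization).
#' @return Numeric feature vector.
#' @export
extract_graph_feature <- function(sample, config, weights) {
  prep <- prepare_sample(sample, config)
  extractor_forward(prep, weights, config)$feature
}

#' Min-max label scaler
#'
#' Labels are normalized to `[0, 1]` independently within each training fold;
#' predictions are mapped back with the same fold's scaler.
#'
#' @param labels Numeric melting temperatures (Celsius).
#' @return A `dyn_label_scaler` with `min` and `max`.
#' @export
label_scaler <- function(labels) {
  lo <- min(labels); hi <- max(labels)
  if (hi <= lo) stop("degenerate label normalization: min == max")
  structure(list(min = lo, max = hi), class = "dyn_label_scaler")
}

scale_labels <- function(scaler, y) (y - scaler$min) / (scaler$max - scaler$min)
unscale_labels <- function(scaler, y) y * (scaler$max - scaler$min) + scaler$min

#' Predict melting temperatures
#'
#' Runs the trained model in evaluation mode (frozen batch-normalization
#' statistics) on one or more multigraph samples and maps the normalized
#' output back to Celsius with the training fold's label scaler.
#'
#' @param samples A `dyn_multigraph` or list of them.
#' @param model A trained model (the `released` element of [train_model()]'s
#'   result, carrying params, batch-norm state and scaler).
#' @param config The `dyn_model_config` used in training.
#' @return Numeric vector of predicted melting temperatures (Celsius).
#' @export
predict_tm <- function(samples, model, config) {
  if (inherits(samples, "dyn_multigraph")) samples <- list(samples)
  if (is.null(model$scaler)) stop("model carries no label scaler")
  preps <- lapply(samples, prepare_sample, config = config)
  ogt <- vapply(samples, function(s) s$ogt, numeric(1L))
  fw <- model_forward(model, preps, ogt, config, train = FALSE)
  unscale_labels(model$scaler, fw$yhat)
}

#' Train the melting-temperature model with k-fold cross-validation
#'
#' Implements the study's training protocol: samples are shuffled into
#' `config$folds` folds; for each fold a fresh model is trained on the
#' remaining folds with AdamW (mean-squared error on labels min-max
#' normalized within the training fold), the held-out fold serves as
#' validation, and the epoch with the best validation RMSE is kept as that
#' fold's representative. The representative with the lowest validation RMSE
#' across folds is released. Out-of-fold predictions (each fold's
#' representative applied to its held-out fold) give the cross-validated
#' metrics.
#'
#' @param dataset List of labeled `dyn_multigraph` samples.
#' @param config A [model_config()].
#' @param verbose Print per-fold progress (default FALSE).
#' @return A `dyn_model_cv`: list with `released` (best model: params,
#'   bn_run, scaler, fold), `folds` (per-fold representative weights,
#'   scaler, best epoch, validation RMSE, indices), `oof` (out-of-fold
#'   predictions and labels), `metrics` ([evaluate()] on the out-of-fold
#'   predictions), `history` (per fold x epoch train/validation RMSE) and
#'   `config`.
#' @export
train_model <- function(dataset, config, verbose = FALSE) {
  if (!length(dataset)) stop("empty dataset")
  labels <- vapply(dataset, function(s) {
    if (is.null(s$label_tm)) stop("unlabeled sample in training set: ", s$protein_id)
    s$label_tm
  }, numeric(1L))
  nS <- length(dataset)
  if (nS < config$folds) stop("dataset smaller than the number of folds")
  set.seed(config$seed)
  fold_of <- sample(rep(seq_len(config$folds), length.out = nS))
  preps <- lapply(dataset, prepare_sample, config = config)
  ogt <- vapply(dataset, function(s) s$ogt, numeric(1L))
  nF <- ncol(dataset[[1L]]$node_features)

  folds <- vector("list", config$folds)
  history <- vector("list", config$folds)
  oof_pred <- numeric(nS)
  for (k in seq_len(config$folds)) {
    val_idx <- which(fold_of == k)
    tr_idx <- which(fold_of != k)
    scaler <- label_scaler(labels[tr_idx])
    y_tr <- scale_labels(scaler, labels[tr_idx])
    model <- init_model(config, nF)
    opt <- adamw_init(model$params)
    best <- list(rmse = Inf, epoch = NA_integer_, model = NULL)
    hist <- matrix(NA_real_, config$epochs, 2L,
                   dimnames = list(NULL, c("train_rmse", "val_rmse")))
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(length(tr_idx))
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      # avoid a trailing batch of size 1 (degenerate batch statistics)
      nb <- length(batches)
      if (nb > 1L && length(batches[[nb]]) == 1L) {
        batches[[nb - 1L]] <- c(batches[[nb - 1L]], batches[[nb]])
        batches[[nb]] <- NULL
      }
      ep_sse <- 0
      for (bt in batches) {
        idx <- tr_idx[bt]
        fw <- model_forward(model, preps[idx], ogt[idx], config, train = TRUE)
        model <- fw$model
        resid <- fw$yhat - y_tr[bt]
        ep_sse <- ep_sse + sum(resid^2)
        dLdy <- 2 * resid / length(bt)
        grads <- model_backward(model, preps[idx], config, fw$cache, dLdy)
        step <- adamw_step(model$params, grads, opt, lr = config$lr,
                           weight_decay = config$weight_decay,
                           betas = config$betas)
        model$params <- step$params
        opt <- step$state
      }
      fw_val <- model_forward(model, preps[val_idx], ogt[val_idx], config,
                              train = FALSE)
      val_pred <- unscale_labels(scaler, fw_val$yhat)
      val_rmse <- sqrt(mean((val_pred - labels[val_idx])^2))
      hist[epoch, ] <- c(sqrt(ep_sse / length(tr_idx)) *
                           (scaler$max - scaler$min), val_rmse)
      if (val_rmse < best$rmse) {
        best <- list(rmse = val_rmse, epoch = epoch,
                     model = list(params = model$params, bn_run = model$bn_run,
                                  scaler = scaler))
      }
    }
    rep_model <- best$model
    fw_rep <- model_forward(rep_model, preps[val_idx], ogt[val_idx], config,
                            train = FALSE)
    oof_pred[val_idx] <- unscale_labels(scaler, fw_rep$yhat)
    folds[[k]] <- list(model = rep_model, best_epoch = best$epoch,
                       val_rmse = best$rmse, val_indices = val_idx)
    history[[k]] <- hist
    if (verbose) {
      message(sprintf("fold %d/%d: best epoch %d, validation RMSE %.3f C",
                      k, config$folds, best$epoch, best$rmse))
    }
  }
  val_rmses <- vapply(folds, function(f) f$val_rmse, numeric(1L))
  best_fold <- which.min(val_rmses)
  released <- folds[[best_fold]]$model
  released$fold <- best_fold
  structure(
    list(released = released, folds = folds,
         oof = list(predictions = oof_pred, labels = labels, fold = fold_of),
         metrics = evaluate(oof_pred, labels),
         history = history, config = config),
    class = "dyn_model_cv"
  )
}

#' @export
print.dyn_model_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<dyn_model_cv> %s on {%s}: %d folds\n",
                     "  out-of-fold: PCC %.3f, RMSE %.3f C, MAE %.3f C, R2 %.3f\n",
                     "  released model: fold %d (validation RMSE %.3f C)\n"),
              x$config$extractor, paste(x$config$dimensions, collapse = ", "),
              x$config$folds, m$pcc, m$rmse, m$mae, m$r2,
              x$released$fold, x$folds[[x$released$fold]]$val_rmse))
  invisible(x)
}

#' Regression metrics
#'
#' Pearson correlation, root-mean-square error, mean absolute error, and the
#' coefficient of determination R2 = 1 - SS_res/SS_tot between predicted and
#' true melting temperatures.
#'
#' @param predictions,labels Equal-length numeric vectors (Celsius).
#' @return List with `pcc`, `rmse`, `mae`, `r2`.
#' @export
evaluate <- function(predictions, labels) {
  if (length(predictions) != length(labels)) stop("unequal lengths")
  if (length(labels) < 2L) stop("need at least 2 observations")
  if (stats::sd(labels) == 0) stop("constant labels: R2 undefined")
  if (stats::sd(predictions) == 0) {
    warning("constant predictions: PCC undefined, reported as NaN")
    pcc <- NaN
  } else {
    pcc <- stats::cor(predictions, labels)
  }
  resid <- predictions - labels
  list(pcc = pcc,
       rmse = sqrt(mean(resid^2)),
       mae = mean(abs(resid)),
       r2 = 1 - sum(resid^2) / sum((labels - mean(labels))^2))
}

#' Paired-bootstrap comparison of two models' absolute errors
#'
#' Resamples proteins with replacement `n_resamples` times and computes the
#' mean paired difference of absolute errors (model A minus model B) in each
#' resample. Negative differences favor model A. Reports the mean difference
#' over resamples, the 95 percent percentile confidence interval, and the
#' fraction of resamples in which A outperformed B (mean difference below
#' zero).
#'
#' @param abs_errors_a,abs_errors_b Paired absolute errors (same proteins,
#'   same order).
#' @param n_resamples Number of bootstrap resamples (default 10000).
#' @param seed Integer RNG seed.
#' @return List with `mean_difference`, `ci` (length-2), `fraction_a_better`,
#'   `observed_difference`, `n_resamples`.
#' @export
bootstrap_compare <- function(abs_errors_a, abs_errors_b,
                              n_resamples = 10000L, seed = 1L) {
  if (length(abs_errors_a) != length(abs_errors_b)) {
    stop("paired error lists must have equal length")
  }
  n <- length(abs_errors_a)
  diffs <- abs_errors_a - abs_errors_b
  set.seed(seed)
  means <- vapply(seq_len(n_resamples), function(r) {
    mean(diffs[sample.int(n, n, replace = TRUE)])
  }, numeric(1L))
  list(mean_difference = mean(means),
       ci = stats::quantile(means, c(0.025, 0.975), names = FALSE),
       fraction_a_better = mean(means < 0),
       observed_difference = mean(diffs),
       n_resamples = as.integer(n_resamples))
}
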