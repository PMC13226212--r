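mk_cfg <- function(extractor = "M2", dims = c("contact", "codirectionality",
                                              "coordination", "deformation"),
                   ...) {
  model_config(extractor = extractor, dimensions = dims, ...)
}

test_that("mGCN attention weights are a softmax: columns sum to 1, D = 1 collapses", {
  set.seed(21)
  H <- matrix(stats::rnorm(12), 4, 3)
  A <- lapply(1:3, function(k) {
    es <- random_edge_set(4, 0.5, seed = k)
    dynamelt:::adjacency_matrix(es)
  })
  params <- list(Wd = lapply(1:3, function(k) dynamelt:::glorot(2, 3)),
                 M = dynamelt:::glorot(2, 2),
                 W = dynamelt:::glorot(2, 6))
  out <- mgcn_forward(H, A, params)
  expect_equal(colSums(out$b), rep(1, 3), tolerance = 1e-8)

  # single dimension: b = 1 and the across term equals E itself
  p1 <- list(Wd = params$Wd[1], M = params$M, W = dynamelt:::glorot(2, 2))
  out1 <- mgcn_forward(H, A[1], p1)
  expect_equal(out1$b, matrix(1, 1, 1))
  slope <- 0.01
  E1 <- dynamelt:::lrelu(p1$Wd[[1]] %*% t(H), slope)
  Ah <- dynamelt:::row_normalize(A[[1]])
  Hd <- 0.5 * (E1 %*% Ah + E1)
  expect_equal(out1$H_new, t(dynamelt:::lrelu(p1$W %*% Hd, slope)),
               tolerance = 1e-12)
})

test_that("mGCN matches the frozen step-by-step fixture (D=2, n=3, width 2)", {
  H <- rbind(c(1, 0), c(0, 1), c(1, 1))
  params <- list(
    Wd = list(rbind(c(0.1, 0.2), c(0.3, -0.1)),
              rbind(c(-0.2, 0.4), c(0.5, 0.1))),
    M = rbind(c(1, 0.5), c(-0.5, 2)),
    W = rbind(c(0.2, -0.3, 0.1, 0.4), c(-0.1, 0.2, 0.3, -0.2)))
  A1 <- matrix(0, 3, 3); A1[1, 2] <- A1[2, 1] <- 1; A1[2, 3] <- A1[3, 2] <- 1
  A2 <- matrix(0, 3, 3); A2[1, 3] <- A2[3, 1] <- 1
  out <- mgcn_forward(H, list(A1, A2), params)
  expect_equal(out$b,
               rbind(c(0.49875000260416014, 0.42678022732016507),
                     c(0.50124999739583975, 0.57321977267983482)),
               tolerance = 1e-10)
  expect_equal(out$H_new,
               rbind(c(0.16993012017121348, -0.00032703283040962588),
                     c(0.014692299622300847, 0.061457198476068294),
                     c(0.17287898313327885, -0.00034320837614578147)),
               tolerance = 1e-6)
})

test_that("extractor output widths follow the architecture", {
  ds <- small_dataset()
  sm <- ds[[1]]
  set.seed(31)
  cfg2 <- mk_cfg("M2")
  m2 <- dynamelt:::init_model(cfg2, 20L)
  expect_length(extract_graph_feature(sm, cfg2, m2$params$extractor), 32L)
  cfg1 <- mk_cfg("M1")
  m1 <- dynamelt:::init_model(cfg1, 20L)
  expect_length(extract_graph_feature(sm, cfg1, m1$params$extractor), 128L)
  cfgS <- mk_cfg("S1", dims = "contact")
  mS <- dynamelt:::init_model(cfgS, 20L)
  expect_length(extract_graph_feature(sm, cfgS, mS$params$extractor), 32L)
})

test_that("pooled graph features and predictions are node-permutation invariant", {
  ds <- small_dataset()
  sm <- ds[[2]]
  n <- nrow(sm$node_features)
  set.seed(41)
  perm <- sample(n)
  sm_p <- sm
  sm_p$node_features <- sm$node_features[perm, , drop = FALSE]
  sm_p$edge_sets <- lapply(sm$edge_sets, function(es) {
    inv <- order(perm)   # old index -> new position
    remap <- t(apply(es$edges + 1L, 1, function(e) sort(inv[e]) - 1L))
    dynamelt:::new_edge_set(remap, es$edge_type, es$n)
  })
  for (ex in c("M2", "M1")) {
    cfg <- mk_cfg(ex)
    set.seed(51)
    model <- dynamelt:::init_model(cfg, 20L)
    f1 <- extract_graph_feature(sm, cfg, model$params$extractor)
    f2 <- extract_graph_feature(sm_p, cfg, model$params$extractor)
    expect_equal(f1, f2, tolerance = 1e-10)
    model$scaler <- label_scaler(c(30, 90))
    expect_equal(predict_tm(sm, model, cfg), predict_tm(sm_p, model, cfg),
                 tolerance = 1e-8)
  }
})

test_that("head widths interpolate linearly to 1 and OGT branch is 20 -> 10", {
  cfg <- mk_cfg("M2")
  m <- dynamelt:::init_model(cfg, 20L)
  expect_equal(dim(m$params$ogt$W1), c(20L, 1L))
  expect_equal(dim(m$params$ogt$W2), c(10L, 20L))
  w_in <- 32 + 10
  expect_equal(m$input_width, w_in)
  expect_equal(m$head_widths, round(c(w_in * 2 / 3 + 1 / 3, w_in / 3 + 2 / 3)))
  expect_equal(dim(m$params$head$W3), c(1L, m$head_widths[2]))
})

test_that("analytic gradients match finite differences on a 3-protein batch", {
  ds <- small_dataset()
  cfg <- mk_cfg("M2")
  preps <- lapply(ds[1:3], dynamelt:::prepare_sample, config = cfg)
  ogt <- vapply(ds[1:3], function(s) s$ogt, numeric(1))
  y <- c(0.2, 0.7, 0.5)
  set.seed(11)
  model <- dynamelt:::init_model(cfg, 20L)
  loss_fn <- function(model) {
    fw <- dynamelt:::model_forward(model, preps, ogt, cfg, train = TRUE)
    mean((fw$yhat - y)^2)
  }
  fw <- dynamelt:::model_forward(model, preps, ogt, cfg, train = TRUE)
  grads <- dynamelt:::model_backward(model, preps, cfg, fw$cache,
                                     2 * (fw$yhat - y) / 3)
  flat_paths <- function(p, prefix = character()) {
    if (is.list(p)) {
      nm <- names(p); if (is.null(nm)) nm <- as.character(seq_along(p))
      unlist(lapply(seq_along(p), function(k)
        flat_paths(p[[k]], c(prefix, nm[k]))), recursive = FALSE)
    } else list(list(path = prefix, len = length(p)))
  }
  get_at <- function(p, path) {
    for (k in path) p <- p[[if (grepl("^[0-9]+$", k)) as.integer(k) else k]]
    p
  }
  set_at <- function(p, path, val) {
    k <- path[1]; k <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
    if (length(path) == 1) { p[[k]] <- val; return(p) }
    p[[k]] <- set_at(p[[k]], path[-1], val)
    p
  }
  paths <- flat_paths(model$params)
  set.seed(99)
  h <- 1e-5
  for (rep in 1:60) {
    pp <- paths[[sample(length(paths), 1)]]
    idx <- sample(pp$len, 1)
    v <- get_at(model$params, pp$path); v[idx] <- v[idx] + h
    mp <- model; mp$params <- set_at(model$params, pp$path, v)
    v2 <- get_at(model$params, pp$path); v2[idx] <- v2[idx] - h
    mm <- model; mm$params <- set_at(model$params, pp$path, v2)
    num <- (loss_fn(mp) - loss_fn(mm)) / (2 * h)
    ana <- get_at(grads, pp$path)[idx]
    expect_lt(abs(num - ana), 1e-4 * max(1, abs(num) + abs(ana)))
  }
})

test_that("evaluate computes the four metrics and their edge cases", {
  perfect <- evaluate(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect[c("pcc", "rmse", "mae", "r2")],
               list(pcc = 1, rmse = 0, mae = 0, r2 = 1))
  m <- evaluate(c(1, 9), c(0, 10))
  expect_equal(m$rmse, 1); expect_equal(m$mae, 1)
  set.seed(8)
  for (k in 1:5) {
    pr <- stats::rnorm(10); la <- stats::rnorm(10)
    mm <- evaluate(pr, la)
    expect_gte(mm$rmse, mm$mae)
    expect_equal(mm$pcc, stats::cor(pr, la))
  }
  expect_error(evaluate(c(1, 2), c(5, 5)), "constant labels")
  expect_warning(mc <- evaluate(c(3, 3, 3), c(1, 2, 3)), "constant predictions")
  expect_true(is.nan(mc$pcc))
})

test_that("paired bootstrap: constant shift, determinism, and identity", {
  set.seed(2)
  a <- stats::runif(30, 0, 5)
  shift <- bootstrap_compare(a, a + 1, n_resamples = 500, seed = 3)
  expect_equal(shift$mean_difference, -1)
  expect_equal(shift$ci, c(-1, -1))
  expect_equal(shift$fraction_a_better, 1)
  same <- bootstrap_compare(a, a, n_resamples = 500, seed = 3)
  expect_equal(same$mean_difference, 0)
  expect_true(same$ci[1] <= 0 && same$ci[2] >= 0)
  r1 <- bootstrap_compare(a, rev(a), n_resamples = 200, seed = 11)
  r2 <- bootstrap_compare(a, rev(a), n_resamples = 200, seed = 11)
  expect_identical(r1, r2)
  expect_error(bootstrap_compare(a, a[-1]), "equal length")
})

test_that("training is deterministic under the seed and rejects unlabeled samples", {
  ds <- small_dataset()
  cfg <- mk_cfg("M2", epochs = 2L, folds = 3L, batch_size = 8L, seed = 17L)
  cv1 <- train_model(ds, cfg)
  cv2 <- train_model(ds, cfg)
  expect_identical(cv1$oof$fold, cv2$oof$fold)
  expect_equal(cv1$oof$predictions, cv2$oof$predictions, tolerance = 1e-12)
  bad <- ds
  bad[[3]]$label_tm <- NULL
  expect_error(train_model(bad, cfg), "unlabeled")
  expect_error(label_scaler(c(5, 5)), "degenerate")
})

test_that("checkpoints round-trip through JSON and reproduce predictions", {
  ds <- small_dataset()
  cfg <- mk_cfg("M2", epochs = 2L, folds = 3L, batch_size = 8L, seed = 17L)
  cv <- train_model(ds, cfg)
  tmp <- tempfile(fileext = ".json")
  save_checkpoint(cv, tmp)
  ck <- load_checkpoint(tmp)
  p1 <- predict_tm(ds[1:4], cv$released, cfg)
  p2 <- predict_tm(ds[1:4], ck$model, ck$config)
  expect_equal(p1, p2, tolerance = 1e-12)
})
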