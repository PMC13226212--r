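test_that("contact edges follow the distance cutoff exactly", {
  near <- dyn_structure(matrix(c(0, 0, 0, 11.9, 0, 0), 2, 3, byrow = TRUE), "AA")
  expect_equal(nrow(contact_edges(near, 12)$edges), 1L)
  far <- dyn_structure(matrix(c(0, 0, 0, 12.1, 0, 0), 2, 3, byrow = TRUE), "AA")
  expect_equal(nrow(contact_edges(far, 12)$edges), 0L)
  hx <- make_helix(20)
  dmat <- as.matrix(dist(hx$coords))
  expect_equal(nrow(contact_edges(hx, 12)$edges),
               sum(dmat[upper.tri(dmat)] <= 12))
})

test_that("backbone edges form the n-1 edge path graph", {
  expect_equal(backbone_edges(2)$edges, matrix(c(0L, 1L), 1, 2,
                                               dimnames = list(NULL, c("i", "j"))))
  for (n in c(5L, 17L)) {
    es <- backbone_edges(n)
    expect_equal(nrow(es$edges), n - 1L)
    expect_equal(es$edges[, 2] - es$edges[, 1], rep(1L, n - 1L))
  }
  expect_error(backbone_edges(1), "at least 2")
})

test_that("every threshold scheme reproduces its sort/inequality oracle", {
  # pooled stats from a small training set of random couplings
  train <- lapply(1:5, function(k) random_symmetric_coupling(8, 500 + k))
  train_s <- lapply(1:5, function(k) random_structure(8, 600 + k))
  st <- dataset_stats(train, train_s)
  for (seed in 1:20) {
    n <- sample(5:10, 1)
    cp <- random_symmetric_coupling(n, seed)
    s <- random_structure(n, seed + 1000, spread = 6)
    ncont <- nrow(contact_edges(s, 12)$edges)
    for (case in list(list("N", 20), list("N", 5), list("SIGMA", 1.5),
                      list("SIGMA", 3), list("CONT", 1), list("CONT", 0.5),
                      list("PAIR", 10), list("PAIR", 30), list("DN", 20),
                      list("DSIGMA", 2), list("DCONT", 1))) {
      spec <- threshold_spec(case[[1]], case[[2]])
      got <- apply_threshold(cp, spec, structure = s, stats = st)
      expect_identical(sort(edge_key(got)),
                       oracle_edges(cp$values, case[[1]], case[[2]],
                                    ncont = ncont, stats = st),
                       info = paste(case[[1]], case[[2]], "seed", seed))
    }
  }
})

test_that("PAIR keeps round(p/100 * n(n-1)/2) edges and N hits the range point", {
  cp <- random_symmetric_coupling(6, 3)
  got <- apply_threshold(cp, threshold_spec("PAIR", 20))
  expect_equal(nrow(got$edges), round(0.2 * 15))   # 3 edges
  # couplings spanning [0, 1]: scheme N, parameter 20 -> threshold 0.8
  v <- matrix(0, 5, 5)
  v[upper.tri(v)] <- seq(0, 1, length.out = 10)
  v <- v + t(v)
  cp2 <- dynamelt:::new_coupling(v, "coordination")
  got2 <- apply_threshold(cp2, threshold_spec("N", 20))
  kept <- cp2$values[upper.tri(v)][cp2$values[upper.tri(v)] >= 0.8]
  expect_equal(nrow(got2$edges), length(kept))
})

test_that("count-based ties break deterministically by (lower i, lower j)", {
  v <- matrix(0, 4, 4)
  v[upper.tri(v)] <- c(5, 5, 5, 1, 1, 1)   # (1,2) (1,3) (2,3) tie at 5
  v <- v + t(v)
  cp <- dynamelt:::new_coupling(v, "deformation")
  got <- apply_threshold(cp, threshold_spec("PAIR", 100 * 2 / 6))  # 2 edges
  expect_equal(unname(got$edges), rbind(c(0L, 1L), c(0L, 2L)))
})

test_that("requesting more edges than pairs keeps all with a warning", {
  cp <- random_symmetric_coupling(4, 8)
  expect_warning(got <- apply_threshold(cp, threshold_spec("CONT", 10),
                                        structure = random_structure(4, 9, spread = 3)),
                 "keeping all")
  expect_equal(nrow(got$edges), 6L)
})

test_that("dataset-wide schemes demand stats", {
  cp <- random_symmetric_coupling(5, 1)
  expect_error(apply_threshold(cp, threshold_spec("DSIGMA", 2)), "stats")
})

test_that("thresholding commutes with node relabeling", {
  n <- 7
  cp <- random_symmetric_coupling(n, 12)
  set.seed(13)
  perm <- sample(n)
  cpp <- dynamelt:::new_coupling(cp$values[perm, perm], cp$kind)
  a <- apply_threshold(cp, threshold_spec("PAIR", 30))
  b <- apply_threshold(cpp, threshold_spec("PAIR", 30))
  # map b's edges back through the permutation
  inv <- order(perm)
  back <- t(apply(b$edges + 1L, 1, function(e) sort(perm[e]) - 1L))
  expect_setequal(paste(back[, 1], back[, 2]), edge_key(a))
})

test_that("connectivity screen fails strictly below 10 mean edges", {
  mk <- function(k) random_edge_set(30, 0.5, seed = k)
  sets <- lapply(1:4, mk)
  # force exact means by trimming
  trim <- function(es, k) {
    es$edges <- es$edges[seq_len(k), , drop = FALSE]
    es
  }
  s99 <- lapply(sets, trim, k = 9);  s99[[1]] <- trim(sets[[1]], 12)  # mean 9.75
  expect_false(screen_connectivity(s99)$pass)
  s10 <- lapply(sets, trim, k = 10)
  expect_true(screen_connectivity(s10)$pass)
  empty <- lapply(sets, trim, k = 0)
  res <- screen_connectivity(empty)
  expect_false(res$pass)
  expect_equal(res$mean_edges, 0)
})

test_that("multigraph assembly validates shapes and carries all dimensions", {
  ds <- small_dataset()
  sm <- ds[[1]]
  expect_setequal(names(sm$edge_sets),
                  c("contact", "codirectionality", "coordination", "deformation"))
  n <- nrow(sm$node_features)
  expect_true(all(vapply(sm$edge_sets, function(e) e$n, integer(1)) == n))
  s <- sm$meta$structure
  expect_error(assemble_multigraph(s, sm$edge_sets, ogt = 37,
                                   node_features = matrix(0, n + 1, 20)),
               "rows")
  one <- assemble_multigraph(s, list(contact = sm$edge_sets$contact), ogt = 37)
  expect_equal(names(one$edge_sets), "contact")
})
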