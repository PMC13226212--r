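test_that("co-directionality handles parallel, antiparallel, and weighted cases", {
  sh <- array(0, c(1, 2, 3)); sh[1, 1, ] <- c(1, 0, 0); sh[1, 2, ] <- c(1, 0, 0)
  expect_equal(codirectionality(dyn_modes(1, sh))$values[1, 2], 1)
  sh[1, 2, ] <- c(-1, 0, 0)
  expect_equal(codirectionality(dyn_modes(1, sh))$values[1, 2], -1)
  # two modes: omega1^2 = 1 with cos 1, omega2^2 = 4 with cos 0 -> 0.8
  sh2 <- array(0, c(2, 2, 3))
  sh2[1, 1, ] <- c(1, 0, 0); sh2[1, 2, ] <- c(2, 0, 0)
  sh2[2, 1, ] <- c(1, 0, 0); sh2[2, 2, ] <- c(0, 3, 0)
  expect_equal(codirectionality(dyn_modes(c(1, 4), sh2))$values[1, 2], 0.8)
})

test_that("static residues drop mode terms; all-static pairs give NaN with warning", {
  sh <- array(0, c(2, 3, 3))
  sh[1, 1, ] <- c(1, 0, 0); sh[1, 2, ] <- c(1, 1, 0)   # residue 3 static in mode 1
  sh[2, 1, ] <- c(0, 1, 0); sh[2, 2, ] <- c(0, 1, 0); sh[2, 3, ] <- c(1, 0, 0)
  m <- dyn_modes(c(1, 2), sh)
  C <- codirectionality(m)$values
  expect_equal(C[1, 3], codir_oracle(m, 1, 3))          # only mode 2 counts
  expect_equal(C[1, 2], codir_oracle(m, 1, 2))
  # a residue static in all modes: every pair term drops
  sh_all <- array(0, c(1, 2, 3)); sh_all[1, 1, ] <- c(1, 0, 0)
  expect_warning(C2 <- codirectionality(dyn_modes(1, sh_all))$values, "NaN")
  expect_true(is.nan(C2[1, 2]))
})

test_that("all three couplings match scalar brute-force oracles on random mode sets", {
  for (seed in 1:5) {
    n <- sample(3:6, 1)
    modes <- random_modeset(n, M = sample(4:10, 1), seed = seed)
    s <- random_structure(n, seed = seed + 50)
    C1 <- codirectionality(modes)$values
    C2 <- coordination(modes, s)$values
    C3 <- deformation(modes)$values
    for (i in 1:n) for (j in 1:n) {
      if (i != j) {
        expect_equal(C1[i, j], codir_oracle(modes, i, j), tolerance = 1e-10)
        expect_equal(C2[i, j], coord_oracle(modes, s, i, j), tolerance = 1e-10)
      }
      G <- crossprod(deform_F(modes, i, j))
      expect_equal(C3[i, j], max(eigen(G, symmetric = TRUE)$values),
                   tolerance = 1e-10)
    }
  }
})

test_that("coordination is 1 on the diagonal and for rigidly co-moving pairs", {
  n <- 4
  sh <- array(0, c(3, n, 3))
  for (a in 1:3) sh[a, , ] <- matrix(rep(stats::rnorm(3), each = n), n, 3)
  s <- random_structure(n, seed = 2)
  C <- coordination(dyn_modes(c(1, 2, 3), sh), s)$values
  expect_equal(C, matrix(1, n, n))
})

test_that("coordination single-mode plug-in example gives 0.5", {
  # unit relative displacement exactly along the pair axis, omega^2 = 1
  s <- dyn_structure(matrix(c(0, 0, 0, 4, 0, 0), 2, 3, byrow = TRUE), "AA")
  sh <- array(0, c(1, 2, 3)); sh[1, 1, ] <- c(1, 0, 0)  # x_1 - x_2 = (1,0,0)
  C <- coordination(dyn_modes(1, sh), s)$values
  expect_equal(C[1, 2], 0.5)
})

test_that("deformation: single-mode closed form and force-grid brute force", {
  m1 <- random_modeset(3, M = 1, seed = 9)
  C <- deformation(m1)$values
  mag <- rowSums(m1$shapes[1, , ]^2)
  expect_equal(C, outer(mag, mag) / m1$omega_sq^2, tolerance = 1e-12)

  # grid of ~10,000 unit force vectors: max |F f|^2 approximates lambda_max
  modes <- random_modeset(3, M = 3, seed = 10)
  Cd <- deformation(modes)$values
  set.seed(1)
  fs <- matrix(stats::rnorm(3 * 10000), 10000, 3)
  fs <- fs / sqrt(rowSums(fs^2))
  for (i in 1:3) for (j in 1:3) {
    FF <- deform_F(modes, i, j)
    grid_max <- max(rowSums((fs %*% t(FF))^2))
    expect_equal(Cd[i, j], grid_max, tolerance = 1e-3)
    expect_gte(Cd[i, j] + 1e-12, grid_max)   # grid can only undershoot
  }
})

test_that("coupling bounds and symmetry hold on random systems", {
  for (seed in 1:4) {
    n <- 6
    modes <- random_modeset(n, M = 8, seed = 200 + seed)
    s <- random_structure(n, seed = 300 + seed)
    C1 <- codirectionality(modes)$values
    C2 <- coordination(modes, s)$values
    C3 <- deformation(modes)$values
    for (C in list(C1, C2, C3)) expect_lt(max(abs(C - t(C))), 1e-8)
    expect_true(all(C1 >= -1 - 1e-12 & C1 <= 1 + 1e-12))
    expect_true(all(diag(C1) == 1))
    expect_true(all(C2 <= 1 + 1e-12))
    expect_true(all(C3 >= 0))
  }
})

test_that("constant cosine across modes is reproduced exactly (weighted average)", {
  n <- 3
  sh <- array(0, c(4, n, 3))
  set.seed(4)
  for (a in 1:4) {
    dir <- stats::rnorm(3)
    for (i in 1:n) sh[a, i, ] <- dir * stats::runif(1, 0.5, 2)  # all parallel
  }
  C <- codirectionality(dyn_modes(c(0.5, 1, 2, 4), sh))$values
  expect_equal(C, matrix(1, n, n), tolerance = 1e-12)
})

test_that("couplings from a structure are rigid-transform invariant", {
  # generic (degeneracy-free) geometry: a jittered helix
  s <- make_helix(12)
  set.seed(77)
  s$coords <- s$coords + matrix(stats::rnorm(36, 0, 0.3), 12, 3)
  m <- compute_modes(build_hessian(s, 15))
  ref <- list(codirectionality(m)$values,
              coordination(m, s)$values,
              deformation(m)$values)
  for (k in 1:5) {
    s2 <- apply_rigid(s, random_rigid_transform(400 + k))
    m2 <- compute_modes(build_hessian(s2, 15))
    got <- list(codirectionality(m2)$values,
                coordination(m2, s2)$values,
                deformation(m2)$values)
    for (q in 1:3) {
      expect_lt(max(abs(got[[q]] - ref[[q]])) / max(abs(ref[[q]])), 1e-6)
    }
  }
})
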