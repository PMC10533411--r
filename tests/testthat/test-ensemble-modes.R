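toy_labels <- function(n_atoms) {
  data.frame(chain = "A", resno = seq_len(n_atoms), resid = "GLY", atom = "CA")
}

random_unit_3n <- function(n3, seed) {
  set.seed(seed)
  v <- rnorm(n3)
  v / sqrt(sum(v^2))
}

test_that("two-frame PCA pins the covariance normalization (lambda = |d|^2/4)", {
  n <- 30L
  base <- rnorm(3 * n)
  d <- random_unit_3n(3 * n, 1) * 6  # |d| = 6
  ens <- atom_ensemble(toy_labels(n), rbind(base, base + d))
  ms <- ensemble_pca(ens)
  expect_equal(ms$eigenvalues[1], sum(d^2) / 4, tolerance = 1e-9)
  expect_equal(abs(sum(ms$eigenvectors[, 1] * d / sqrt(sum(d^2)))), 1,
               tolerance = 1e-9)
  expect_lt(max(abs(ms$eigenvalues[-1])), 1e-12)
  # identical frames give zero variance; single frame errors
  ens0 <- atom_ensemble(toy_labels(n), rbind(base, base, base))
  expect_lt(max(ensemble_pca(ens0)$eigenvalues), 1e-18)
  expect_error(ensemble_pca(atom_ensemble(toy_labels(n), rbind(base))), ">= 2 frames")
})

test_that("PCA conserves variance and satisfies the projection property", {
  set.seed(5)
  n <- 40L; M <- 25L
  X <- matrix(rnorm(M * 3 * n), M)
  ens <- atom_ensemble(toy_labels(n), X)
  ms <- ensemble_pca(ens)
  Xc <- sweep(X, 2, colMeans(X))
  total_var <- sum(Xc^2) / M
  expect_equal(sum(ms$eigenvalues), total_var, tolerance = 1e-6 * total_var)
  # variance of projections onto mode k equals lambda_k (population form)
  for (k in 1:3) {
    proj <- Xc %*% ms$eigenvectors[, k]
    expect_equal(sum(proj^2) / M, ms$eigenvalues[k],
                 tolerance = 1e-9 * ms$eigenvalues[1])
  }
  # orthonormal eigenvectors
  G <- crossprod(ms$eigenvectors[, 1:5])
  expect_equal(G, diag(5), tolerance = 1e-9)
})

test_that("planted orthogonal modes are recovered from 50 frames", {
  n <- 50L
  v1 <- random_unit_3n(3 * n, 2)
  v2 <- random_unit_3n(3 * n, 3)
  v2 <- v2 - sum(v1 * v2) * v1
  v2 <- v2 / sqrt(sum(v2^2))
  set.seed(4)
  mean_coords <- rnorm(3 * n) * 5
  c1 <- rnorm(50, 0, 2)   # variance 4
  c2 <- rnorm(50, 0, 1)   # variance 1
  X <- t(vapply(1:50, function(i) mean_coords + c1[i] * v1 + c2[i] * v2,
                numeric(3 * n)))
  ms <- ensemble_pca(atom_ensemble(toy_labels(n), X))
  expect_lt(abs(ms$eigenvalues[1] - 4) / 4, 0.25)
  expect_lt(abs(ms$eigenvalues[2] - 1) / 1, 0.25)
  expect_gt(abs(sum(ms$eigenvectors[, 1] * v1)), 0.99)
  expect_gt(abs(sum(ms$eigenvectors[, 2] * v2)), 0.99)
})

test_that("PCA without alignment is translation-covariant", {
  set.seed(9)
  n <- 20L; M <- 10L
  X <- matrix(rnorm(M * 3 * n), M)
  shift <- rep(c(3, -1, 2), n)
  X2 <- sweep(X, 2, shift, "+")
  a <- ensemble_pca(atom_ensemble(toy_labels(n), X))
  b <- ensemble_pca(atom_ensemble(toy_labels(n), X2))
  expect_equal(a$eigenvalues, b$eigenvalues, tolerance = 1e-9)
  expect_equal(abs(colSums(a$eigenvectors * b$eigenvectors))[1:5], rep(1, 5),
               tolerance = 1e-9)
  expect_equal(b$mean_coords - a$mean_coords, shift, tolerance = 1e-9)
})

test_that("superpose_first removes a planted per-frame rigid wobble", {
  ref <- build_scaffold()
  ca <- select_calpha(ref)
  base <- as.vector(t(ca$coords))
  set.seed(21)
  frames <- t(vapply(1:12, function(i) {
    R <- confscape:::rotation_matrix(rnorm(3), rnorm(1, 0, 0.2))
    co <- sweep(ca$coords, 2, colMeans(ca$coords))
    as.vector(t(sweep(co %*% t(R), 2, colMeans(ca$coords) + rnorm(3, 0, 2), "+")))
  }, numeric(length(base))))
  ens <- atom_ensemble(ca$labels, frames)
  aligned <- ensemble_pca(ens, superpose_first = TRUE)
  raw <- ensemble_pca(ens, superpose_first = FALSE)
  # rigid-body variance dominates unaligned PCA; alignment removes nearly all
  expect_lt(sum(aligned$eigenvalues), 0.01 * sum(raw$eigenvalues))
})

test_that("displacement RMSD follows the closed form scale/sqrt(N)", {
  expect_equal(rmsd_of_displacement(random_unit_3n(300, 6), 0), 0)
  expect_equal(rmsd_of_displacement(random_unit_3n(300, 6), 20), 2.0,
               tolerance = 1e-12)
  # brute-force oracle: per-atom RMSD of the displaced structure vs mean
  v <- random_unit_3n(3 * 77, 7)
  s <- 13.3
  disp <- matrix(s * v, ncol = 3, byrow = TRUE)
  oracle <- sqrt(mean(rowSums(disp^2)))
  expect_equal(rmsd_of_displacement(v, s), oracle, tolerance = 1e-9)
  expect_error(rmsd_of_displacement(2 * v, 1), "unit")
})

planted_mode_set <- function(n = 100L, lambda = c(9, 4, 1), M = 64L, seed = 8,
                             basis_seed = 8) {
  set.seed(basis_seed)
  V <- qr.Q(qr(matrix(rnorm((3 * n) * 3), ncol = 3)))
  mean_coords <- rnorm(3 * n) * 3
  set.seed(seed)
  scores <- sapply(seq_along(lambda), function(k) rnorm(M, 0, sqrt(lambda[k])))
  X <- t(vapply(seq_len(M), function(i) {
    mean_coords + as.vector(V %*% scores[i, ])
  }, numeric(3 * n)))
  ensemble_pca(atom_ensemble(toy_labels(n), X))
}

test_that("mode scaling honours both amplitude conventions", {
  ms <- planted_mode_set()
  N <- ms$n_atoms
  # target-RMSD convention
  sm <- scale_mode(ms, morph_spec(mode = 1, target_rmsd = 20))
  expect_equal(sm$rmsd, 20, tolerance = 1e-9)
  expect_equal(sqrt(mean(rowSums(matrix(sm$displacement, ncol = 3,
                                        byrow = TRUE)^2))), 20,
               tolerance = 1e-9)
  # scale-factor convention: c * sqrt(lambda_k), RMSD = c * sqrt(lambda_k/N)
  lam2 <- ms$eigenvalues[2]
  sm2 <- scale_mode(ms, morph_spec(mode = 2, scale_factor = 0.5))
  expect_equal(sm2$rmsd, 0.5 * sqrt(lam2 / N), tolerance = 1e-9)
  # zero scale factor -> zero displacement
  sm0 <- scale_mode(ms, morph_spec(mode = 1, scale_factor = 0))
  expect_equal(sm0$rmsd, 0)
  expect_equal(max(abs(sm0$displacement)), 0)
})

test_that("closed morphs start/end at the mean and hit the exact extremes", {
  ms <- planted_mode_set()
  spec <- morph_spec(mode = 1, n_frames = 20, target_rmsd = 20)
  morph <- make_morph(ms, spec)
  expect_equal(n_frames(morph), 20L)
  expect_equal(morph$xyz[1, ], ms$mean_coords, tolerance = 1e-12)
  expect_equal(morph$xyz[20, ], ms$mean_coords, tolerance = 1e-12)
  # max-amplitude frame RMSD equals the requested target exactly
  rmsds <- vapply(1:20, function(i) {
    sqrt(mean(rowSums((frame_coords(morph, i) -
                         matrix(ms$mean_coords, ncol = 3, byrow = TRUE))^2)))
  }, numeric(1))
  expect_equal(max(rmsds), 20, tolerance = 1e-9)
  # both directions of motion are sampled
  proj <- sweep(morph$xyz, 2, ms$mean_coords) %*% ms$eigenvectors[, 1]
  expect_lt(min(proj), -1)
  expect_gt(max(proj), 1)
  expect_error(make_morph(ms, morph_spec(n_frames = 3, target_rmsd = 1)),
               "at least 4")
})

test_that("a zero-eigenvalue mode yields a zero-motion morph with a warning", {
  n <- 10L
  base <- rnorm(3 * n)
  d <- random_unit_3n(3 * n, 11)
  ens <- atom_ensemble(toy_labels(n), rbind(base, base + d))
  ms <- ensemble_pca(ens)
  expect_warning(m0 <- make_morph(ms, morph_spec(mode = 2, scale_factor = 0.076)),
                 "zero")
  expect_lt(max(abs(sweep(m0$xyz, 2, ms$mean_coords))), 1e-9)
})

test_that("cosine overlaps behave as inner products of mode subspaces", {
  ms <- planted_mode_set()
  self <- cosine_overlap(ms, ms, k = 3)
  expect_equal(self, diag(3), tolerance = 1e-9)
  # resampled ensembles from the same planted modes overlap strongly
  a <- planted_mode_set(M = 200, seed = 13, basis_seed = 99)
  b <- planted_mode_set(M = 200, seed = 14, basis_seed = 99)
  ov <- cosine_overlap(a, b, k = 3)
  expect_true(all(ov >= 0 & ov <= 1))
  expect_true(all(apply(ov, 1, max) > 0.9))
  # orthogonal planted first modes give zero overlap
  n <- 30L
  v1 <- c(1, rep(0, 3 * n - 1))
  v2 <- c(0, 1, rep(0, 3 * n - 2))
  mk <- function(v, seed) {
    set.seed(seed)
    c1 <- rnorm(20, 0, 2)
    X <- t(vapply(1:20, function(i) c1[i] * v, numeric(3 * n)))
    ensemble_pca(atom_ensemble(toy_labels(n), X))
  }
  ov12 <- cosine_overlap(mk(v1, 1), mk(v2, 2), k = 1)
  expect_equal(ov12[1, 1], 0, tolerance = 1e-9)
  # label mismatch errors
  other <- planted_mode_set(n = 99L)
  expect_error(cosine_overlap(ms, other), "different atom labels")
})

test_that("morph round trip: PCA of a mode-k morph returns that mode first", {
  ms <- planted_mode_set()
  morph <- make_morph(ms, morph_spec(mode = 2, n_frames = 24, target_rmsd = 5))
  ms2 <- ensemble_pca(morph)
  ov <- abs(sum(ms2$eigenvectors[, 1] * ms$eigenvectors[, 2]))
  expect_gt(ov, 0.999)
})
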