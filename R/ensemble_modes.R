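# PCA of CA coordinate ensembles (optionally without superposition, matching
# classification-derived ensembles that share one alignment already), mode
# scaling to a target RMSD, closed morph trajectories, and cosine overlaps.

#' Principal component analysis of a coordinate ensemble
#'
#' Eigen-decomposes the mean-centred positional covariance of an
#' atom-matched ensemble. The covariance is normalized by the number of
#' frames M (population form), which the two-frame identity
#' lambda = |d|^2 / 4 pins down. With `superpose_first = TRUE`, frames are
#' iteratively Kabsch-fitted to the running mean before decomposition
#' (at most 10 iterations, or until the mean shifts by < 1e-6 Angstrom);
#' the default is no alignment, appropriate when the frames already share a
#' common reference frame from classification.
#'
#' @param ensemble An [atom_ensemble()] with >= 2 frames.
#' @param superpose_first Iteratively superpose frames onto the mean first?
#' @return Object of class `mode_set`: `labels`, `mean_coords` (3N),
#'   `eigenvalues` (descending, Angstrom^2), `eigenvectors` (3N x K, unit
#'   columns with deterministic sign), `n_frames`, `n_atoms`.
#' @export
ensemble_pca <- function(ensemble, superpose_first = FALSE) {
  stopifnot(inherits(ensemble, "atom_ensemble"))
  X <- ensemble$xyz
  M <- nrow(X)
  if (M < 2L) stop("ensemble PCA needs >= 2 frames")
  n_atoms <- ncol(X) / 3L
  if (superpose_first) {
    mean_c <- matrix(colMeans(X), ncol = 3L, byrow = TRUE)
    for (iter in 1:10) {
      for (f in seq_len(M)) {
        P <- matrix(X[f, ], ncol = 3L, byrow = TRUE)
        pc <- colMeans(P); qc <- colMeans(mean_c)
        R <- kabsch_rotation(sweep(P, 2, pc), sweep(mean_c, 2, qc))
        Pf <- sweep(sweep(P, 2, pc) %*% R, 2, qc, "+")
        X[f, ] <- as.vector(t(Pf))
      }
      new_mean <- matrix(colMeans(X), ncol = 3L, byrow = TRUE)
      shift <- sqrt(mean(rowSums((new_mean - mean_c)^2)))
      mean_c <- new_mean
      if (shift < 1e-6) break
    }
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  lambda <- sv$d^2 / M
  V <- sv$v
  # deterministic sign: first component with |.| > 1e-12 made positive
  for (j in seq_len(ncol(V))) {
    k <- which(abs(V[, j]) > 1e-12)[1]
    if (!is.na(k) && V[k, j] < 0) V[, j] <- -V[, j]
  }
  keep <- seq_len(min(ncol(V), M))
  structure(list(labels = ensemble$labels, mean_coords = mu,
                 eigenvalues = lambda[keep],
                 eigenvectors = V[, keep, drop = FALSE],
                 n_frames = M, n_atoms = n_atoms),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat("<mode_set> ", x$n_frames, " frames x ", x$n_atoms, " atoms; ",
      "leading eigenvalues (A^2): ",
      paste(sprintf("%.3g", utils::head(x$eigenvalues, 3L)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' RMSD of a scaled unit-mode displacement
#'
#' Displacing every atom by `scale * mode` (a unit 3N-vector) moves the
#' structure by RMSD `|scale| / sqrt(N)` — the closed form used to convert a
#' target RMSD into a mode scale.
#'
#' @param mode Unit 3N-vector.
#' @param scale Scalar multiplier (Angstrom, since the mode is unit).
#' @return RMSD in Angstrom.
#' @export
rmsd_of_displacement <- function(mode, scale) {
  n_atoms <- length(mode) / 3
  if (n_atoms < 1) stop("empty mode vector")
  if (abs(sqrt(sum(mode^2)) - 1) > 1e-6) stop("mode vector must be unit length")
  abs(scale) / sqrt(n_atoms)
}

#' Specify a morph along one principal component
#'
#' The amplitude is given either as `target_rmsd` (Angstrom; the maximum
#' frame's RMSD from the mean) or as a dimensionless `scale_factor` c with
#' the variance-weighted meaning: maximum displacement c * sqrt(lambda_k)
#' along the unit eigenvector, hence maximum RMSD c * sqrt(lambda_k / N).
#'
#' @param mode Principal component index (1-based).
#' @param n_frames Number of frames over one closed cycle (default 20).
#' @param target_rmsd Maximum RMSD amplitude in Angstrom (exclusive with
#'   `scale_factor`).
#' @param scale_factor Dimensionless amplitude (exclusive with `target_rmsd`).
#' @param closed Start and end at the mean conformation?
#' @return Object of class `morph_spec`.
#' @export
morph_spec <- function(mode = 1L, n_frames = 20L, target_rmsd = NULL,
                       scale_factor = NULL, closed = TRUE) {
  if (is.null(target_rmsd) == is.null(scale_factor)) {
    stop("give exactly one of target_rmsd or scale_factor")
  }
  stopifnot(mode >= 1L)
  structure(list(mode = as.integer(mode), n_frames = as.integer(n_frames),
                 target_rmsd = target_rmsd, scale_factor = scale_factor,
                 closed = isTRUE(closed)),
            class = "morph_spec")
}

#' Maximum displacement vector for a morph
#'
#' @param mode_set A [ensemble_pca()] result.
#' @param spec A [morph_spec()].
#' @return List with `displacement` (3N-vector at maximum amplitude) and
#'   `rmsd` (the achieved maximum RMSD in Angstrom).
#' @export
scale_mode <- function(mode_set, spec) {
  stopifnot(inherits(mode_set, "mode_set"), inherits(spec, "morph_spec"))
  k <- spec$mode
  if (k > length(mode_set$eigenvalues)) {
    stop("mode ", k, " not available (", length(mode_set$eigenvalues), " modes)")
  }
  v <- mode_set$eigenvectors[, k]
  N <- mode_set$n_atoms
  if (!is.null(spec$target_rmsd)) {
    scale <- spec$target_rmsd * sqrt(N)
  } else {
    lam <- mode_set$eigenvalues[k]
    if (lam <= 1e-12 * max(mode_set$eigenvalues[1], 1e-12)) {
      warning("mode ", k, " has zero eigenvalue: zero-motion morph")
      lam <- 0
    }
    scale <- spec$scale_factor * sqrt(lam)
  }
  list(displacement = scale * v, rmsd = abs(scale) / sqrt(N))
}

# Phase grid over one cycle: uniform, but with the extreme and nodal phases
# (pi/2, pi, 3*pi/2) snapped to their nearest grid points so that a closed
# morph contains the exact +max, mean and -max frames for any n >= 5.
morph_phases <- function(n_frames, closed) {
  phi <- if (closed) seq(0, 2 * pi, length.out = n_frames)
         else seq(0, 2 * pi, length.out = n_frames + 1L)[seq_len(n_frames)]
  used <- if (closed) c(1L, n_frames) else 1L  # endpoints stay exact
  for (target in c(pi / 2, 3 * pi / 2, pi)) {
    free <- setdiff(seq_len(n_frames), used)
    if (!length(free)) break
    i <- free[which.min(abs(phi[free] - target))]
    phi[i] <- target
    used <- c(used, i)
  }
  sort(phi)
}

#' Build a morph trajectory along one principal component
#'
#' Samples one closed cycle of motion, mean -> +max -> mean -> -max -> mean,
#' on a sinusoidal amplitude schedule. With `closed = TRUE` (the default) the
#' first and last frames equal the mean conformation, and the schedule is
#' guaranteed to contain frames at exactly the +max and -max amplitudes.
#'
#' @param mode_set A [ensemble_pca()] result.
#' @param spec A [morph_spec()]; `n_frames` must be >= 4.
#' @return An [atom_ensemble()] of `n_frames` structures.
#' @export
make_morph <- function(mode_set, spec) {
  stopifnot(inherits(mode_set, "mode_set"), inherits(spec, "morph_spec"))
  if (spec$n_frames < 4L) stop("a morph needs at least 4 frames")
  sm <- scale_mode(mode_set, spec)
  phi <- morph_phases(spec$n_frames, spec$closed)
  amps <- sin(phi)
  xyz <- t(vapply(amps, function(a) mode_set$mean_coords + a * sm$displacement,
                  numeric(length(mode_set$mean_coords))))
  atom_ensemble(mode_set$labels, xyz)
}

#' Cosine overlaps between two mode sets
#'
#' Absolute dot products |v_i . w_j| between the first k eigenvectors of two
#' mode sets sharing one atom labelling; entries lie in [0, 1], and the
#' self-overlap matrix is the identity.
#'
#' @param modes_a,modes_b [ensemble_pca()] results over identical labels.
#' @param k Number of leading modes to compare.
#' @return k x k numeric matrix.
#' @export
cosine_overlap <- function(modes_a, modes_b, k = 3L) {
  stopifnot(inherits(modes_a, "mode_set"), inherits(modes_b, "mode_set"))
  key_a <- paste(modes_a$labels$chain, modes_a$labels$resno, modes_a$labels$atom, sep = "|")
  key_b <- paste(modes_b$labels$chain, modes_b$labels$resno, modes_b$labels$atom, sep = "|")
  if (!identical(key_a, key_b)) stop("mode sets are over different atom labels")
  k <- min(k, length(modes_a$eigenvalues), length(modes_b$eigenvalues))
  abs(crossprod(modes_a$eigenvectors[, seq_len(k), drop = FALSE],
                modes_b$eigenvectors[, seq_len(k), drop = FALSE]))
}
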