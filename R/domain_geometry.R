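# Geometry of rigid domains: centres of mass, principal axes, and the tilt
# (splay) angles of NTD dimers against a reference receptor's global axis.

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

clamp1 <- function(x) pmin(1, pmax(-1, x))

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector where a direction was expected")
  v / n
}

# rotation matrix for angle theta (radians) about unit axis n (Rodrigues)
rotation_matrix <- function(axis, theta) {
  n <- unit(axis)
  K <- matrix(c(0, n[3], -n[2], -n[3], 0, n[1], n[2], -n[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Centre of mass of a coordinate set
#'
#' @param coords n x 3 matrix (Angstrom).
#' @param weights Optional per-point weights; default equal (appropriate for
#'   CA-only analyses).
#' @return Length-3 numeric vector.
#' @export
center_of_mass <- function(coords, weights = NULL) {
  coords <- rbind(coords)
  if (nrow(coords) == 0L) stop("empty coordinate set")
  if (is.null(weights)) return(colMeans(coords))
  stopifnot(length(weights) == nrow(coords), all(weights >= 0), sum(weights) > 0)
  as.vector(crossprod(weights, coords)) / sum(weights)
}

#' Principal axes of a point cloud
#'
#' Eigen-decomposition of the 3 x 3 positional covariance about the centre of
#' mass (equal weights, population normalization). Axes are returned in
#' descending-variance order with a deterministic sign: the first component of
#' each axis exceeding 1e-12 in magnitude is made positive.
#'
#' @param coords n x 3 matrix, n >= 3.
#' @return Object of class `principal_axes`: `origin` (COM), `axes` (3 x 3,
#'   columns are unit axes), `variances` (descending, Angstrom^2), and a
#'   `collinear` flag when the second variance is negligible.
#' @export
principal_axes <- function(coords) {
  coords <- rbind(coords)
  if (nrow(coords) < 3L) stop("need >= 3 points for principal axes")
  com <- colMeans(coords)
  X <- sweep(coords, 2, com)
  C <- crossprod(X) / nrow(X)
  if (max(abs(C)) < 1e-18) stop("degenerate point set: all points identical")
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (j in 1:3) {
    v <- vecs[, j]
    k <- which(abs(v) > 1e-12)[1]
    if (!is.na(k) && v[k] < 0) vecs[, j] <- -v
  }
  structure(list(origin = com, axes = vecs, variances = vals,
                 collinear = vals[2] < 1e-9 * max(vals[1], 1e-12)),
            class = "principal_axes")
}

#' @export
print.principal_axes <- function(x, ...) {
  cat("<principal_axes> origin (", paste(sprintf("%.2f", x$origin), collapse = ", "),
      ") A; variances ", paste(sprintf("%.3g", x$variances), collapse = ", "),
      " A^2\n", sep = "")
  invisible(x)
}

#' Tilt angle of an NTD dimer against a reference axis
#'
#' The angle between the dimer's second principal axis (which runs along the
#' dimer local two-fold axis) and the reference structure's first principal
#' axis, as the arccosine of the dot product of unit vectors.
#'
#' Eigenvectors are sign-ambiguous, so both axes are first canonically
#' oriented: the reference first axis toward `reference_top` (the NTD end of
#' the receptor), and the dimer second axis so that its dot product with
#' (dimer COM - reference COM) is positive, i.e. pointing outward/up away
#' from the receptor core. The reported angle is then the arccosine of the
#' canonical dot product, covering the full [0, 180] degree range so that
#' dimers splayed past horizontal stay distinguishable. `corrected = TRUE`
#' records that the raw (solver-signed) dimer axis pointed down toward the
#' LBD and the reported angle is the 180-degree complement of the naive value.
#'
#' @param dimer_axes [principal_axes()] of the dimer CA atoms.
#' @param reference_axes [principal_axes()] of the whole reference receptor.
#' @param dimer_com Dimer centre of mass (length-3).
#' @param reference_top A point on the NTD side of the reference, used to
#'   orient the reference axis.
#' @return List with `angle_deg` in [0, 180] and logical `corrected`.
#' @export
dimer_tilt_angle <- function(dimer_axes, reference_axes, dimer_com, reference_top) {
  stopifnot(inherits(dimer_axes, "principal_axes"),
            inherits(reference_axes, "principal_axes"))
  r_axis <- reference_axes$axes[, 1]
  up <- reference_top - reference_axes$origin
  if (sqrt(sum(up^2)) < 1e-9) stop("reference_top coincides with reference COM")
  if (sum(r_axis * up) < 0) r_axis <- -r_axis

  d_axis <- dimer_axes$axes[, 2]
  w <- dimer_com - reference_axes$origin
  if (sqrt(sum(w^2)) < 1e-9) stop("dimer COM coincides with reference COM")
  s <- sum(d_axis * w)
  if (abs(s) < 1e-12) stop("dimer axis orientation undetermined (axis orthogonal to outward direction)")
  corrected <- s < 0
  if (corrected) d_axis <- -d_axis

  angle <- deg(acos(clamp1(sum(unit(d_axis) * unit(r_axis)))))
  list(angle_deg = angle, corrected = corrected)
}

#' Splay-angle landscape over an ensemble of fitted models
#'
#' For each model, measures the two NTD dimer tilt angles (a, b) against a
#' reference receptor, producing the conformational-landscape table. The
#' dimer-to-angle assignment is fixed by the order of `dimer_selections`
#' (first = a, second = b), so it is config-driven and deterministic.
#'
#' @param models List of [structure_model()] objects (pre-aligned to the
#'   reference frame).
#' @param reference Reference [structure_model()] providing the global axis.
#' @param dimer_selections Named list of exactly two [domain_selection()]
#'   objects with role `"ntd_dimer"`.
#' @param reference_top Optional point orienting the reference axis; defaults
#'   to the mean of the two dimer COMs on the reference (the NTD end).
#' @return Data frame: `model_id`, `angle_a_deg`, `angle_b_deg`,
#'   `corrected_a`, `corrected_b`.
#' @export
splay_landscape <- function(models, reference, dimer_selections,
                            reference_top = NULL) {
  if (length(dimer_selections) != 2L) {
    stop("exactly two dimer selections required (angles a and b)")
  }
  ref_ca <- select_calpha(reference)
  ref_axes <- principal_axes(ref_ca$coords)
  ref_dimer_coms <- lapply(dimer_selections, function(sel) {
    center_of_mass(select_calpha(reference, sel)$coords)
  })
  if (is.null(reference_top)) {
    reference_top <- colMeans(do.call(rbind, ref_dimer_coms))
  }
  rows <- lapply(models, function(m) {
    per_dimer <- lapply(dimer_selections, function(sel) {
      ca <- tryCatch(select_calpha(m, sel), error = function(e) {
        stop("model '", m$model_id, "': missing dimer annotation '",
             sel$name, "': ", conditionMessage(e), call. = FALSE)
      })
      ax <- principal_axes(ca$coords)
      dimer_tilt_angle(ax, ref_axes, center_of_mass(ca$coords), reference_top)
    })
    data.frame(model_id = m$model_id,
               angle_a_deg = per_dimer[[1]]$angle_deg,
               angle_b_deg = per_dimer[[2]]$angle_deg,
               corrected_a = per_dimer[[1]]$corrected,
               corrected_b = per_dimer[[2]]$corrected,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
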