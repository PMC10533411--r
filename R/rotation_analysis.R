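# LBD rotation-angle protocol: each subunit's linker anchor residue (K501 in
# GluA1, K505 in GluA2 numbering) defines a vertical rotation axis; the
# helix-G centre of mass is the proxy point that swings about it. Angles are
# measured at a per-chain reference point against a reference structure.

com_by_chain <- function(model, sel) {
  mask <- selection_mask(model, sel)
  atoms <- model$atoms[mask, , drop = FALSE]
  if (nrow(atoms) == 0L) {
    stop("selection '", sel$name, "' matches no atoms in model '",
         model$model_id, "'")
  }
  chains <- sort(unique(atoms$chain))
  out <- t(vapply(chains, function(ch) {
    colMeans(as.matrix(atoms[atoms$chain == ch, c("x", "y", "z")]))
  }, numeric(3)))
  rownames(out) <- chains
  out
}

#' Build per-chain rotation frames
#'
#' Pools the anchor-residue and helix-G centres of mass per chain across all
#' structures (models plus reference, one equal-weight contribution per
#' structure), and assembles each chain's reference point from the x, y of
#' the combined anchor COM and the z of the combined helix-G COM. The
#' reference proxy is the reference structure's own helix-G COM for that
#' chain. All structures must already share the common frame with the global
#' symmetry axis along z.
#'
#' @param models List of [structure_model()] objects.
#' @param reference Reference [structure_model()].
#' @param anchors [domain_selection()] with role `"anchor_residue"`.
#' @param helix_g [domain_selection()] with role `"helix_g"`.
#' @return Named list (by chain) of `rotation_frame` objects with fields
#'   `chain`, `anchor_com`, `reference_point`, `reference_proxy`.
#' @export
build_rotation_frames <- function(models, reference, anchors, helix_g) {
  structures <- c(models, list(reference))
  anchor_coms <- lapply(structures, com_by_chain, sel = anchors)
  helixg_coms <- lapply(structures, com_by_chain, sel = helix_g)
  chains <- rownames(anchor_coms[[length(structures)]])
  for (i in seq_along(structures)) {
    for (tbl in list(anchor_coms[[i]], helixg_coms[[i]])) {
      missing <- setdiff(chains, rownames(tbl))
      extra <- setdiff(rownames(tbl), chains)
      if (length(missing) || length(extra)) {
        stop("chain pairing error in structure '", structures[[i]]$model_id,
             "': missing ", paste(missing, collapse = ","),
             "; unexpected ", paste(extra, collapse = ","))
      }
    }
  }
  ref_helixg <- helixg_coms[[length(structures)]]
  frames <- lapply(chains, function(ch) {
    anchor_pool <- colMeans(do.call(rbind, lapply(anchor_coms, function(t) t[ch, ])))
    helixg_pool <- colMeans(do.call(rbind, lapply(helixg_coms, function(t) t[ch, ])))
    structure(list(chain = ch,
                   anchor_com = anchor_pool,
                   reference_point = c(anchor_pool[1], anchor_pool[2], helixg_pool[3]),
                   reference_proxy = ref_helixg[ch, ]),
              class = "rotation_frame")
  })
  names(frames) <- chains
  frames
}

#' Rotation angle of one subunit's LBD
#'
#' The vertex angle at the chain's reference point between the vector to the
#' model's helix-G COM and the vector to the reference structure's helix-G
#' COM, as the arccosine of the normalized dot product (clamped to [-1, 1]).
#' `"vertex3d"` uses the full 3D vectors; `"projected_xy"` zeroes the z
#' components first, isolating rotation about the vertical anchor axis. The
#' two agree exactly whenever the three points share one z value.
#'
#' @param frame A `rotation_frame` from [build_rotation_frames()].
#' @param helix_g_com Helix-G COM of the model chain being measured.
#' @param mode `"vertex3d"` (default) or `"projected_xy"`.
#' @return List with `chain`, `angle_deg` in [0, 180] and `mode`.
#' @export
rotation_angle <- function(frame, helix_g_com, mode = c("vertex3d", "projected_xy")) {
  mode <- match.arg(mode)
  stopifnot(inherits(frame, "rotation_frame"))
  v1 <- helix_g_com - frame$reference_point
  v2 <- frame$reference_proxy - frame$reference_point
  if (mode == "projected_xy") {
    v1[3] <- 0
    v2[3] <- 0
  }
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-6 || n2 < 1e-6) {
    stop("degenerate geometry for chain ", frame$chain,
         ": a vertex vector is shorter than 1e-6 A")
  }
  list(chain = frame$chain,
       angle_deg = deg(acos(clamp1(sum(v1 * v2) / (n1 * n2)))),
       mode = mode)
}

#' Rotation-angle table over an ensemble of models
#'
#' One row per (model, chain), in model order then chain order. All models
#' and the reference contribute to the pooled rotation frames.
#'
#' @inheritParams build_rotation_frames
#' @param mode Angle mode passed to [rotation_angle()].
#' @return Data frame: `model_id`, `chain`, `angle_deg`, `mode`.
#' @export
rotation_table <- function(models, reference, anchors, helix_g,
                           mode = c("vertex3d", "projected_xy")) {
  mode <- match.arg(mode)
  frames <- build_rotation_frames(models, reference, anchors, helix_g)
  rows <- lapply(models, function(m) {
    hg <- com_by_chain(m, helix_g)
    per_chain <- lapply(names(frames), function(ch) {
      res <- rotation_angle(frames[[ch]], hg[ch, ], mode = mode)
      data.frame(model_id = m$model_id, chain = ch,
                 angle_deg = res$angle_deg, mode = mode,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_chain)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
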