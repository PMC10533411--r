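# ---- StructureModel ---------------------------------------------------------

#' Construct a structure model
#'
#' A `structure_model` holds the labelled atomic coordinates of one conformer:
#' a model identifier plus one row per atom with chain, residue number,
#' residue name, atom name and Cartesian coordinates in Angstrom.
#'
#' @param model_id Character scalar naming the conformer.
#' @param atoms Data frame with columns `chain`, `resno`, `resid`, `atom`,
#'   `x`, `y`, `z`. `resno` is the author residue numbering of the source
#'   file, kept verbatim.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(model_id, atoms) {
  stopifnot(is.character(model_id), length(model_id) == 1L)
  req <- c("chain", "resno", "resid", "atom", "x", "y", "z")
  if (!all(req %in% names(atoms))) {
    stop("atoms must have columns: ", paste(req, collapse = ", "))
  }
  atoms <- as.data.frame(atoms)[, req]
  if (nrow(atoms) == 0L) stop("empty model: no atoms")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in model '", model_id, "'")
  key <- paste(atoms$chain, atoms$resno, atoms$atom, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (chain, resno, atom) labels in model '", model_id, "': ",
         paste(utils::head(key[duplicated(key)], 3L), collapse = "; "))
  }
  structure(list(model_id = model_id, atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model> ", x$model_id, "\n", sep = "")
  cat("  atoms:  ", nrow(x$atoms), "\n", sep = "")
  cat("  chains: ", paste(sort(unique(x$atoms$chain)), collapse = " "), "\n", sep = "")
  invisible(x)
}

atom_xyz <- function(model) as.matrix(model$atoms[, c("x", "y", "z")])

set_atom_xyz <- function(model, xyz) {
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

# ---- Domain selections ------------------------------------------------------

#' Define a domain selection
#'
#' Names a set of atoms by chain and residue range, optionally restricted to
#' one atom name. Selections carry a `role` so that downstream geometry knows
#' what the atoms stand for (an NTD dimer, an LBD subunit, the helix-G proxy
#' segment, a linker anchor residue, or a reference rigid body).
#'
#' @param name Selection name.
#' @param members Data frame with columns `chain`, `res_start`, `res_end` and
#'   optionally `atom` (NA = any atom name).
#' @param role One of `"ntd_dimer"`, `"lbd_subunit"`, `"helix_g"`,
#'   `"anchor_residue"`, `"reference_body"`.
#' @return An object of class `domain_selection`.
#' @export
domain_selection <- function(name, members,
                             role = c("ntd_dimer", "lbd_subunit", "helix_g",
                                      "anchor_residue", "reference_body")) {
  role <- match.arg(role)
  members <- as.data.frame(members)
  if (!all(c("chain", "res_start", "res_end") %in% names(members)) ||
      nrow(members) == 0L) {
    stop("members must be a non-empty data frame with chain, res_start, res_end")
  }
  if (is.null(members$atom)) members$atom <- NA_character_
  if (any(members$res_end < members$res_start)) stop("empty residue range in selection '", name, "'")
  structure(list(name = name, members = members, role = role),
            class = "domain_selection")
}

#' Read domain selections from a YAML config
#'
#' The file maps selection names to a `role` and a list of members, e.g.
#' ```yaml
#' helix_g_A: {role: helix_g, members: [{chain: A, res_start: 50, res_end: 60, atom: CA}]}
#' ```
#'
#' @param path Path to a YAML file.
#' @return Named list of [domain_selection()] objects.
#' @export
read_selections <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(nm) {
    entry <- cfg[[nm]]
    mem <- do.call(rbind, lapply(entry$members, function(m) {
      data.frame(chain = as.character(m$chain),
                 res_start = as.integer(m$res_start),
                 res_end = as.integer(m$res_end),
                 atom = if (is.null(m$atom)) NA_character_ else as.character(m$atom))
    }))
    domain_selection(nm, mem, role = entry$role)
  })
  names(out) <- names(cfg)
  out
}

# logical index of model atoms matched by a selection
selection_mask <- function(model, sel) {
  missing_chains <- setdiff(unique(sel$members$chain), unique(model$atoms$chain))
  if (length(missing_chains)) {
    stop("selection '", sel$name, "' names chains absent from model '",
         model$model_id, "': ", paste(missing_chains, collapse = ", "))
  }
  mask <- rep(FALSE, nrow(model$atoms))
  for (i in seq_len(nrow(sel$members))) {
    m <- sel$members[i, ]
    hit <- model$atoms$chain == m$chain &
      model$atoms$resno >= m$res_start & model$atoms$resno <= m$res_end
    if (!is.na(m$atom)) hit <- hit & model$atoms$atom == m$atom
    mask <- mask | hit
  }
  mask
}

#' Select C-alpha atoms
#'
#' Restricts a model to the CA atoms inside a selection, ordered by
#' (chain, residue number). At least 3 atoms must match: downstream axis and
#' superposition geometry is degenerate below that.
#'
#' @param model A [structure_model()].
#' @param sel A [domain_selection()]; if `NULL`, the whole model.
#' @return List with `labels` (data frame chain/resno/resid/atom) and
#'   `coords` (n x 3 matrix, Angstrom).
#' @export
select_calpha <- function(model, sel = NULL) {
  atoms <- model$atoms
  if (!is.null(sel)) atoms <- atoms[selection_mask(model, sel), , drop = FALSE]
  atoms <- atoms[atoms$atom == "CA", , drop = FALSE]
  if (nrow(atoms) < 3L) {
    stop("degenerate selection: ", nrow(atoms), " CA atom(s) matched",
         if (!is.null(sel)) paste0(" by '", sel$name, "'") else "",
         " in model '", model$model_id, "' (need >= 3)")
  }
  ord <- order(atoms$chain, atoms$resno)
  atoms <- atoms[ord, , drop = FALSE]
  list(labels = atoms[, c("chain", "resno", "resid", "atom")],
       coords = as.matrix(atoms[, c("x", "y", "z")]))
}

# ---- Reading ----------------------------------------------------------------

#' Read an atomic model from PDB or mmCIF
#'
#' Parses ATOM records into a [structure_model()]. Alternate locations are
#' resolved deterministically by keeping the first altloc in identifier order
#' for each (chain, resno, atom), with one warning per affected residue.
#' Atoms carrying insertion codes beyond the first occurrence of a label are
#' dropped the same way. Residue numbering is kept verbatim.
#'
#' @param path File path.
#' @param format `"pdb"`, `"cif"`, or `"auto"` (by file extension).
#' @param model_id Identifier; defaults to the file base name.
#' @return A [structure_model()].
#' @export
read_model <- function(path, format = c("auto", "pdb", "cif"), model_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") suppressWarnings(
      bio3d::read.pdb(path, verbose = FALSE, multi = FALSE, rm.alt = FALSE))
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) stop("could not parse ", format, " file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("empty model: no ATOM records in '", path, "'")
  if (is.null(model_id)) model_id <- sub("\\.[^.]+$", "", basename(path))
  # deterministic altloc/insert resolution: sort by identifier, keep first
  alt <- if (is.null(at$alt)) rep(NA_character_, nrow(at)) else at$alt
  ins <- if (is.null(at$insert)) rep(NA_character_, nrow(at)) else at$insert
  alt[is.na(alt)] <- ""
  ins[is.na(ins)] <- ""
  ord <- order(at$chain, at$resno, at$elety, ins, alt)
  at <- at[ord, ]; alt <- alt[ord]; ins <- ins[ord]
  key <- paste(at$chain, at$resno, at$elety, sep = "|")
  dup <- duplicated(key)
  if (any(dup)) {
    res_affected <- unique(paste(at$chain[dup], at$resno[dup]))
    for (r in res_affected) {
      warning("altloc/insertion conflict at residue ", r,
              ": keeping first by identifier order", call. = FALSE)
    }
    at <- at[!dup, ]
  }
  at <- at[order(at$chain, at$resno, at$elety), ]
  structure_model(model_id, data.frame(
    chain = as.character(at$chain), resno = as.integer(at$resno),
    resid = as.character(at$resid), atom = as.character(at$elety),
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE))
}

# ---- Superposition ----------------------------------------------------------

# Kabsch: optimal proper rotation for row-vector points (already centred),
# i.e. Q ~ P %*% R. SVD sign correction guarantees det(R) = +1 (no
# reflection); deterministic for degenerate singular values via svd's fixed
# ordering.
kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$u, sv$v)))
  D <- diag(c(1, 1, d))
  sv$u %*% D %*% t(sv$v)
}

#' Superpose one model onto another
#'
#' Least-squares rigid-body superposition (rotation + translation, never a
#' reflection) of `mobile` onto `reference` over the paired CA atoms of a fit
#' selection. Pairing is by (chain, resno, atom) label; the whole mobile model
#' is transformed, and the reported RMSD is over the fit selection.
#'
#' @param mobile,reference [structure_model()] objects.
#' @param fit_selection A [domain_selection()] or `NULL` for all CA atoms.
#' @return List with `model` (transformed mobile), `rmsd` (Angstrom),
#'   `rotation` (3 x 3) and `translation` (length-3).
#' @export
superpose <- function(mobile, reference, fit_selection = NULL) {
  cm <- select_calpha(mobile, fit_selection)
  cr <- select_calpha(reference, fit_selection)
  km <- paste(cm$labels$chain, cm$labels$resno, cm$labels$atom, sep = "|")
  kr <- paste(cr$labels$chain, cr$labels$resno, cr$labels$atom, sep = "|")
  if (!identical(km, kr)) {
    unmatched <- union(setdiff(km, kr), setdiff(kr, km))
    stop("atom pairing mismatch between '", mobile$model_id, "' and '",
         reference$model_id, "'; unmatched labels: ",
         paste(utils::head(unmatched, 5L), collapse = "; "),
         if (length(unmatched) > 5L) " ..." else "")
  }
  P <- cm$coords; Q <- cr$coords
  pc <- colMeans(P); qc <- colMeans(Q)
  R <- kabsch_rotation(sweep(P, 2, pc), sweep(Q, 2, qc))
  t_vec <- qc - as.vector(pc %*% R)
  transform_xyz <- function(X) sweep(X %*% R, 2, t_vec, "+")
  fitted <- transform_xyz(P)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  out <- set_atom_xyz(mobile, transform_xyz(atom_xyz(mobile)))
  list(model = out, rmsd = rmsd, rotation = R, translation = t_vec)
}

# ---- Atom-matched ensembles -------------------------------------------------

#' Construct an atom-matched ensemble
#'
#' Stacks conformers that share one ordered atom labelling. Coordinates are
#' stored as a frames x 3N matrix with columns interleaved (x1, y1, z1, x2, ...).
#'
#' @param labels Data frame with `chain`, `resno`, `resid`, `atom` (one row
#'   per atom, order defines the coordinate layout).
#' @param xyz Numeric matrix, one row per frame, `3 * nrow(labels)` columns.
#' @return An object of class `atom_ensemble`.
#' @export
atom_ensemble <- function(labels, xyz) {
  labels <- as.data.frame(labels)
  if (is.null(labels$resid)) labels$resid <- "GLY"
  xyz <- rbind(xyz)  # keep matrix shape for a single frame
  if (ncol(xyz) != 3L * nrow(labels)) {
    stop("xyz has ", ncol(xyz), " columns; expected ", 3L * nrow(labels))
  }
  if (nrow(xyz) < 1L) stop("ensemble needs at least one frame")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in ensemble")
  structure(list(labels = labels[, c("chain", "resno", "resid", "atom")],
                 xyz = unname(as.matrix(xyz))),
            class = "atom_ensemble")
}

#' @export
print.atom_ensemble <- function(x, ...) {
  cat("<atom_ensemble> ", nrow(x$xyz), " frame(s) x ", nrow(x$labels),
      " atoms\n", sep = "")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble An [atom_ensemble()].
#' @return Integer frame count.
#' @export
n_frames <- function(ensemble) nrow(ensemble$xyz)

#' Coordinates of one frame as an n x 3 matrix
#' @param ensemble An [atom_ensemble()].
#' @param i Frame index.
#' @return n x 3 coordinate matrix.
#' @export
frame_coords <- function(ensemble, i) {
  matrix(ensemble$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' Build an atom-matched ensemble from models
#'
#' Extracts the CA atoms of a selection from every model and stacks them.
#' All models must resolve to the identical ordered label set.
#'
#' @param models List of [structure_model()] objects.
#' @param sel Optional [domain_selection()].
#' @return An [atom_ensemble()].
#' @export
as_ensemble <- function(models, sel = NULL) {
  cas <- lapply(models, select_calpha, sel = sel)
  keys <- lapply(cas, function(ca)
    paste(ca$labels$chain, ca$labels$resno, ca$labels$atom, sep = "|"))
  for (i in seq_along(keys)[-1]) {
    if (!identical(keys[[i]], keys[[1]])) {
      stop("atom pairing mismatch: model '", models[[i]]$model_id,
           "' does not share the label set of model '", models[[1]]$model_id, "'")
    }
  }
  xyz <- do.call(rbind, lapply(cas, function(ca) as.vector(t(ca$coords))))
  atom_ensemble(cas[[1]]$labels, xyz)
}

# ---- Writing ----------------------------------------------------------------

format_atom_record <- function(serial, atom, resid, chain, resno, x, y, z) {
  # PDB v3 fixed columns; atom names of <4 chars start in column 14
  name_fmt <- if (nchar(atom) >= 4L) substr(atom, 1, 4) else paste0(" ", formatC(atom, width = -3))
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial %% 100000L, name_fmt, substr(resid, 1, 3), substr(chain, 1, 1),
          resno %% 10000L, x, y, z, 1, 0)
}

#' Write an ensemble as a multi-model PDB trajectory
#'
#' One MODEL/ENDMDL block per frame, frame order preserved. Coordinates are
#' written at PDB precision (0.001 Angstrom), which bounds round-trip error.
#'
#' @param ensemble An [atom_ensemble()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_trajectory <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "atom_ensemble"))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  lab <- ensemble$labels
  for (f in seq_len(n_frames(ensemble))) {
    co <- frame_coords(ensemble, f)
    writeLines(sprintf("MODEL     %4d", f), con)
    lines <- vapply(seq_len(nrow(lab)), function(i) {
      format_atom_record(i, lab$atom[i], lab$resid[i], lab$chain[i],
                         lab$resno[i], co[i, 1], co[i, 2], co[i, 3])
    }, character(1))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB trajectory back as an ensemble
#'
#' @param path Path to a multi-model PDB file.
#' @return An [atom_ensemble()].
#' @export
read_trajectory <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, multi = TRUE),
                  error = function(e) stop("could not parse trajectory '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  labels <- data.frame(chain = as.character(at$chain),
                       resno = as.integer(at$resno),
                       resid = as.character(at$resid),
                       atom = as.character(at$elety),
                       stringsAsFactors = FALSE)
  atom_ensemble(labels, pdb$xyz)
}

#' Write one model as a single-frame PDB file
#'
#' @param model A [structure_model()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_model <- function(model, path) {
  lab <- model$atoms
  lines <- vapply(seq_len(nrow(lab)), function(i) {
    format_atom_record(i, lab$atom[i], lab$resid[i], lab$chain[i],
                       lab$resno[i], lab$x[i], lab$y[i], lab$z[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
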