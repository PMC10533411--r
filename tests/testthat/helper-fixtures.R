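# Fixtures built in code: toy models, rigid transforms, tiny PDB text.

# grid-of-points toy model: n_chains chains x n_res residues, CA only
make_toy_model <- function(n_chains = 4L, n_res = 10L, model_id = "toy") {
  chains <- LETTERS[seq_len(n_chains)]
  atoms <- do.call(rbind, lapply(seq_along(chains), function(ci) {
    data.frame(chain = chains[ci], resno = seq_len(n_res), resid = "ALA",
               atom = "CA",
               x = seq_len(n_res) * 1.5, y = ci * 4.0,
               z = sin(seq_len(n_res)) + ci,
               stringsAsFactors = FALSE)
  }))
  structure_model(model_id, atoms)
}

# apply a rigid transform (rotation about given axis + translation)
transform_model <- function(model, axis = c(0, 0, 1), angle_deg = 0,
                            translation = c(0, 0, 0)) {
  R <- confscape:::rotation_matrix(axis, angle_deg * pi / 180)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, translation, "+")
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

# minimal hand-written 3-atom PDB text
write_tiny_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00",
    "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00  0.00",
    "ATOM      3  C   ALA A   1       3.700   2.900   3.000  1.00  0.00",
    "END"), path)
  path
}

# minimal mmCIF with the same three atoms
write_tiny_cif <- function(path) {
  writeLines(c(
    "data_tiny",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 1.000 2.000 3.000 1.00 0.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 2.500 2.000 3.000 1.00 0.00 ? 1 ALA A CA 1",
    "ATOM 3 C C . ALA A 1 1 ? 3.700 2.900 3.000 1.00 0.00 ? 1 ALA A C 1"),
    path)
  path
}

# PDB text with an altloc conflict on one CA
write_altloc_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.50  0.00",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.50  0.00",
    "ATOM      3  CA  ALA A   2       2.000   0.000   0.000  1.00  0.00",
    "ATOM      4  CA  ALA A   3       3.000   1.000   0.000  1.00  0.00",
    "END"), path)
  path
}

atom_xyz_test <- function(m) as.matrix(m$atoms[, c("x", "y", "z")])

whole_selection <- function(model) {
  chains <- sort(unique(model$atoms$chain))
  domain_selection("all", data.frame(chain = chains,
                                     res_start = min(model$atoms$resno),
                                     res_end = max(model$atoms$resno)),
                   role = "reference_body")
}
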