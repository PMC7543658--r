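# Shared fixtures: published mixture parameter sets used as simulation
# ground truths, and small hand-built structure models.

trimodal_mixture <- function() {
  sigd_mixture(c(0.52, 0.37, 0.11),
               alpha = c(3.55, 10.06, 7.5),
               beta = c(53.59, 481.24, 373.23),
               b0 = c(10.82, 6.13, 59.56))
}

bimodal_mixture <- function() {
  sigd_mixture(c(0.79, 0.21),
               alpha = c(3.74, 10.65),
               beta = c(122.74, 726.67),
               b0 = c(28.26, 99.82))
}

# narrow unimodal background for anomaly fixtures: a well-ordered
# structure (mean B ~ 35 A^2, sd ~ 5 A^2) so a factor-2 planted ADP
# anomaly cannot be matched by a chance draw
anomaly_background <- function() sigd_mixture(1, 50, 1470, 5)

# minimal structure_model built directly (no file round trip)
make_model <- function(xyz, b, d_max = 2.0, resname = "GLY",
                       atom_name = "CA", element = "C", resno = NULL,
                       hetero = FALSE) {
  n <- nrow(xyz)
  atoms <- data.frame(
    chain_id = "A",
    residue_name = rep_len(resname, n),
    residue_seq = if (is.null(resno)) seq_len(n) else resno,
    insertion_code = "",
    atom_name = rep_len(atom_name, n),
    alt_loc = "",
    element = rep_len(element, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    b_iso = b,
    occupancy = 1,
    is_hetero = rep_len(hetero, n),
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms, d_max = d_max, s_max = 1 / d_max,
                 source_path = "<in-memory>", metadata = list()),
            class = "structure_model")
}

# literal fixed-column PDB fixture: 10 heavy atoms + 1 hydrogen + one
# site with two alt-locs (A occ 0.60, B occ 0.40)
write_tiny_pdb <- function(path, resolution_line = TRUE) {
  fmt <- function(serial, name, alt, resn, resno, x, y, z, occ, b, ele) {
    sprintf("ATOM  %5d %-4s%1s%3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, alt, resn, resno, x, y, z, occ, b, ele)
  }
  lines <- character(0)
  if (resolution_line)
    lines <- "REMARK   2 RESOLUTION.    2.00 ANGSTROMS."
  xs <- seq(0, by = 1.8, length.out = 10)
  for (i in 1:10)
    lines <- c(lines, fmt(i, " CA ", " ", "GLY", i, xs[i], 0, 0, 1,
                          20 + i, "C"))
  # hydrogen (must be dropped)
  lines <- c(lines, fmt(11, " H  ", " ", "GLY", 1, 0.5, 0.5, 0, 1, 21,
                        "H"))
  # alt-loc pair on a new site (A kept, B dropped)
  lines <- c(lines, fmt(12, " CB ", "A", "GLY", 11, 0, 2, 0, 0.60, 30,
                        "C"))
  lines <- c(lines, fmt(13, " CB ", "B", "GLY", 11, 0.2, 2, 0, 0.40, 40,
                        "C"))
  lines <- c(lines, "END")
  writeLines(lines, path)
  path
}

# minimal mmCIF fixture with a resolution item
write_tiny_cif <- function(path) {
  writeLines(c(
    "data_toy",
    "_reflns.d_resolution_high 1.75",
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
    "ATOM 1 C CA . GLY A 1 1 ? 0.000 0.000 0.000 1.00 21.00 ? 1 GLY A CA 1",
    "ATOM 2 C CA . GLY A 1 2 ? 1.800 0.000 0.000 1.00 22.00 ? 2 GLY A CA 1",
    "ATOM 3 C CA . GLY A 1 3 ? 3.600 0.000 0.000 1.00 23.00 ? 3 GLY A CA 1"
  ), path)
  path
}

# quadrature oracle for the defining integrals (independent of the
# closed forms under test)
quad_peak_height <- function(b, s_max) {
  stats::integrate(function(s) 4 * pi * s^2 * exp(-b * s^2 / 4),
                   0, s_max, rel.tol = 1e-12, abs.tol = 0)$value
}
quad_occ_total <- function(b1, b2, s_max) {
  num <- stats::integrate(function(s) s^2 * exp(-(b1 + b2) * s^2 / 4),
                          0, s_max, rel.tol = 1e-12, abs.tol = 0)$value
  den <- stats::integrate(function(s) s^2 * exp(-b2 * s^2 / 2),
                          0, s_max, rel.tol = 1e-12, abs.tol = 0)$value
  num / den
}
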