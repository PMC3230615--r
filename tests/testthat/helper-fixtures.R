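# Programmatic fixtures: tiny PDB files and in-memory families.

pdb_atom_line <- function(serial, name, resid, chain, resno, xyz,
                          occ = 1, b = 0, element = substr(name, 1, 1),
                          record = "ATOM", alt = " ") {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else substr(name, 1, 4)
  sprintf("%-6s%5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, alt,
          resid, chain, resno, xyz[1], xyz[2], xyz[3], occ, b, element)
}

# A 2-residue glycine-alanine peptide on chain A plus 1 glycine on chain B.
write_two_chain_pdb <- function(path) {
  lines <- c(
    pdb_atom_line(1, "N",  "GLY", "A", 1, c(0.000, 1.000, 0.000)),
    pdb_atom_line(2, "CA", "GLY", "A", 1, c(1.458, 1.000, 0.000)),
    pdb_atom_line(3, "C",  "GLY", "A", 1, c(2.000, 2.400, 0.000)),
    pdb_atom_line(4, "O",  "GLY", "A", 1, c(1.300, 3.400, 0.000)),
    pdb_atom_line(5, "N",  "ALA", "A", 2, c(3.300, 2.500, 0.000)),
    pdb_atom_line(6, "CA", "ALA", "A", 2, c(4.000, 3.800, 0.100)),
    pdb_atom_line(7, "CB", "ALA", "A", 2, c(5.400, 3.600, 0.700)),
    pdb_atom_line(8, "N",  "GLY", "B", 1, c(10.000, 0.000, 0.000)),
    pdb_atom_line(9, "CA", "GLY", "B", 1, c(11.458, 0.000, 0.000)),
    "END")
  writeLines(lines, path)
  path
}

# Single glycine with four atoms; used for mass-center hand checks.
write_glycine_pdb <- function(path) {
  lines <- c(
    pdb_atom_line(1, "N",  "GLY", "A", 1, c(-0.525, 1.362, 0.000)),
    pdb_atom_line(2, "CA", "GLY", "A", 1, c(0.000, 0.000, 0.000)),
    pdb_atom_line(3, "C",  "GLY", "A", 1, c(1.520, 0.000, 0.000)),
    pdb_atom_line(4, "O",  "GLY", "A", 1, c(2.153, 1.062, 0.000)),
    "END")
  writeLines(lines, path)
  path
}

# CA-only structure_record from an L x 3 coordinate matrix.
make_structure <- function(id, coords, resid = NULL) {
  coords <- as.matrix(coords)
  L <- nrow(coords)
  structure_record(
    id = id,
    resid = resid %||% rep("ALA", L),
    ca = coords,
    atoms = data.frame(res = seq_len(L), elesy = "C", mass = 12.011,
                       x = coords[, 1], y = coords[, 2], z = coords[, 3])
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Ungapped family from a list of L x 3 coordinate matrices.
make_family <- function(coord_list, seqs = NULL) {
  L <- nrow(coord_list[[1]])
  n <- length(coord_list)
  if (is.null(seqs)) seqs <- matrix("A", n, L)
  ids <- sprintf("s%02d", seq_len(n))
  rownames(seqs) <- ids
  # structures carry only the non-gap residues
  structures <- lapply(seq_len(n), function(i) {
    keep <- seqs[i, ] != "-"
    make_structure(ids[i], coord_list[[i]][keep, , drop = FALSE],
                   resid = spca:::aa_one_to_three(seqs[i, keep]))
  })
  build_family(structures, seqs)
}

rigid_move <- function(coords, rot, shift) {
  sweep(as.matrix(coords) %*% rot, 2, shift, `+`)
}
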