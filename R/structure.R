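#' Construct a structure record
#'
#' Low-level constructor for the per-protein container used throughout the
#' package: an ordered list of residues, each with a single alpha-carbon
#' coordinate and a non-empty atom table from which the residue mass center
#' is computed.
#'
#' @param id Character label for the structure (e.g. the PDB file stem).
#' @param resid Character vector of 3-letter residue names, in chain order.
#' @param ca Numeric n x 3 matrix of alpha-carbon coordinates (Angstrom).
#' @param atoms Data frame with columns `res` (1-based residue index),
#'   `elesy` (element symbol), `mass` (unified atomic mass) and `x`, `y`,
#'   `z` coordinates. Every residue must own at least one atom.
#'
#' @return An object of class `spca_structure` with fields `id`, `resid`,
#'   `ca`, `atoms` and the precomputed `mass_center` (n x 3).
#' @export
structure_record <- function(id, resid, ca, atoms) {
  ca <- as.matrix(ca)
  n <- length(resid)
  stopifnot(nrow(ca) == n, ncol(ca) == 3)
  if (!all(is.finite(ca))) stop("non-finite alpha-carbon coordinates in '", id, "'")
  need <- c("res", "elesy", "mass", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("atom table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(seq_len(n) %in% atoms$res)) {
    stop("every residue needs at least one atom in '", id, "'")
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates in '", id, "'")
  }
  mc <- t(vapply(seq_len(n), function(l) {
    a <- atoms[atoms$res == l, , drop = FALSE]
    residue_mass_center(a)
  }, numeric(3)))
  dimnames(ca) <- NULL
  dimnames(mc) <- NULL
  structure(
    list(id = id, resid = as.character(resid), ca = ca,
         atoms = atoms, mass_center = mc),
    class = "spca_structure"
  )
}

#' @export
print.spca_structure <- function(x, ...) {
  cat("<spca_structure> ", x$id, ": ", length(x$resid), " residues, ",
      nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

# Standard atomic masses (unified atomic mass units) for the elements seen
# in protein structures.
ELEMENT_MASS <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  SE = 78.971, P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  FE = 55.845, ZN = 65.38, MG = 24.305, MN = 54.938, CA = 40.078,
  "NA" = 22.990, K = 39.098, CU = 63.546, NI = 58.693, CO = 58.933
)

element_mass <- function(elesy) {
  unname(ELEMENT_MASS[match(toupper(elesy), names(ELEMENT_MASS))])
}

# Element symbols from PDB columns 77-78 when present, else inferred from
# the atom name (first alphabetic character; "SE" for selenium names).
infer_elements <- function(elety, elesy = NULL) {
  ele <- if (is.null(elesy)) rep("", length(elety)) else
    toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  guess <- toupper(gsub("[^A-Za-z].*", "", gsub("^[^A-Za-z]*", "", elety)))
  two <- substr(guess, 1, 2) == "SE"
  guess <- ifelse(two, "SE", substr(guess, 1, 1))
  ifelse(ele == "", guess, ele)
}

#' Mass center of a residue
#'
#' Mass-weighted mean of the atomic coordinates of one residue,
#' `sum(m * x) / sum(m)` per Cartesian component.
#'
#' @param atoms Data frame with columns `mass`, `x`, `y`, `z` (one row per
#'   atom); masses must be positive with a positive total.
#'
#' @return Numeric length-3 vector (Angstrom).
#' @export
residue_mass_center <- function(atoms) {
  if (nrow(atoms) == 0L) stop("empty atom list")
  m <- atoms$mass
  if (any(!is.finite(m)) || sum(m) <= 0) stop("non-positive total atomic mass")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  as.numeric(colSums(xyz * m) / sum(m))
}

#' Read a protein chain from a PDB file
#'
#' Parses a PDB file (via [bio3d::read.pdb()]) into a [structure_record()].
#' Only the first MODEL is used; for alternate locations the highest
#' occupancy wins, ties going to altloc "A"; HETATM records are kept only
#' for the 20 standard amino acids (so e.g. selenomethionine is dropped);
#' insertion-coded residues stay in chain order. Residues lacking an
#' alpha-carbon ("CA") atom are dropped with a warning.
#'
#' @param path Path to a PDB file.
#' @param chain Optional single chain identifier; default uses all chains in
#'   file order.
#' @param id Label for the record; defaults to the file stem.
#'
#' @return An `spca_structure`.
#' @export
read_structure <- function(path, chain = NULL, id = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  keep <- at$type == "ATOM" | (at$type == "HETATM" & at$resid %in% AA3)
  at <- at[keep, , drop = FALSE]
  if (!is.null(chain)) {
    if (!chain %in% at$chain) stop("chain '", chain, "' not found in ", path)
    at <- at[at$chain == chain, , drop = FALSE]
  }
  if (nrow(at) == 0L) stop("no amino-acid atoms in ", path)

  # Residue key preserving file order, including insertion codes.
  ins <- ifelse(is.na(at$insert), "", at$insert)
  key <- paste(at$chain, at$resno, ins, sep = "|")
  rle_first <- !duplicated(key)
  res_keys <- key[rle_first]
  at$res <- match(key, res_keys)

  # Altloc resolution: per residue and atom name keep the highest occupancy,
  # ties broken in favour of altloc "A", then file order.
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(at$res, at$elety, -occ, alt != "A", seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$res, at$elety)), , drop = FALSE]
  at <- at[order(at$res, as.numeric(rownames(at))), , drop = FALSE]

  elesy <- infer_elements(at$elety, at$elesy)
  mass <- element_mass(elesy)
  bad_mass <- is.na(mass)
  if (any(bad_mass)) {
    warning("dropping ", sum(bad_mass), " atom(s) of unknown element (",
            paste(sort(unique(elesy[bad_mass])), collapse = ", "),
            ") in ", basename(path))
    at <- at[!bad_mass, , drop = FALSE]
    elesy <- elesy[!bad_mass]
    mass <- mass[!bad_mass]
  }

  has_ca <- tapply(at$elety == "CA", at$res, any)
  missing_ca <- as.integer(names(has_ca))[!has_ca]
  if (length(missing_ca)) {
    warning("dropping ", length(missing_ca), " residue(s) without CA in ",
            basename(path), " (residue index ",
            paste(missing_ca, collapse = ", "), ")")
    keep_res <- !(at$res %in% missing_ca)
    at <- at[keep_res, , drop = FALSE]
    elesy <- elesy[keep_res]
    mass <- mass[keep_res]
    at$res <- match(at$res, sort(unique(at$res)))
  }
  if (nrow(at) == 0L) stop("no residues with CA atoms in ", path)

  ca_rows <- at[at$elety == "CA", , drop = FALSE]
  ca_rows <- ca_rows[order(ca_rows$res), , drop = FALSE]
  resid <- ca_rows$resid
  ca <- as.matrix(ca_rows[, c("x", "y", "z")])

  atoms <- data.frame(res = at$res, elesy = elesy, mass = mass,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  structure_record(
    id = id %||% sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE),
    resid = resid, ca = ca, atoms = atoms
  )
}
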