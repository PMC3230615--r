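#' Combine structures and a gapped alignment into an aligned family
#'
#' Scatters each structure's alpha-carbon and residue mass-center
#' coordinates into the columns of a gapped multiple alignment. The
#' alignment defines the position correspondence across the family; gap
#' cells carry no coordinates (`NA`).
#'
#' @param structures List of [structure_record()] objects.
#' @param alignment One of: a character matrix (proteins x columns, one
#'   character per cell, `-` for gap) with rownames matching structure ids;
#'   a named character vector of gapped sequences; a `fasta` object from
#'   [bio3d::read.fasta()]; or a path to an aligned FASTA file. Rows are
#'   matched to structures by id.
#'
#' @return An object of class `spca_family` with fields `ids`, `seq`
#'   (N x L character matrix), `alpha` and `mass_center` (N x L x 3 arrays,
#'   `NA` at gaps), and `gap` (N x L logical matrix).
#' @export
build_family <- function(structures, alignment) {
  ali <- as_alignment_matrix(alignment)
  ids <- vapply(structures, function(s) s$id, character(1))
  if (is.null(rownames(ali))) {
    if (nrow(ali) != length(structures))
      stop("alignment has ", nrow(ali), " rows but ", length(structures),
           " structures were given")
    rownames(ali) <- ids
  }
  if (!setequal(rownames(ali), ids) || anyDuplicated(ids)) {
    stop("alignment row names must match structure ids 1:1")
  }
  ali <- ali[ids, , drop = FALSE]
  n <- length(ids)
  L <- ncol(ali)
  gap <- ali == "-"
  alpha <- array(NA_real_, c(n, L, 3))
  mcen <- array(NA_real_, c(n, L, 3))
  for (i in seq_len(n)) {
    s <- structures[[i]]
    cols <- which(!gap[i, ])
    if (length(cols) != length(s$resid)) {
      stop("alignment row '", ids[i], "' has ", length(cols),
           " non-gap columns but the structure has ", length(s$resid),
           " residues")
    }
    alpha[i, cols, ] <- s$ca
    mcen[i, cols, ] <- s$mass_center
  }
  new_family(ids, ali, alpha, mcen, gap)
}

new_family <- function(ids, seq, alpha, mcen, gap) {
  dimnames(seq) <- list(ids, NULL)
  dimnames(gap) <- list(ids, NULL)
  structure(
    list(ids = ids, seq = seq, alpha = alpha, mass_center = mcen, gap = gap),
    class = "spca_family"
  )
}

#' @export
print.spca_family <- function(x, ...) {
  cat("<spca_family> ", length(x$ids), " proteins x ", ncol(x$seq),
      " alignment columns (", sum(x$gap), " gap cells)\n", sep = "")
  invisible(x)
}

#' Number of proteins and alignment columns of a family
#' @param family An `spca_family`.
#' @return Integer.
#' @export
n_proteins <- function(family) length(family$ids)

#' @rdname n_proteins
#' @export
n_positions <- function(family) ncol(family$seq)

# Normalise the accepted alignment representations to a character matrix.
as_alignment_matrix <- function(alignment) {
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment)) {
    alignment <- bio3d::read.fasta(alignment, rm.dup = FALSE)
  }
  if (inherits(alignment, "fasta")) {
    m <- alignment$ali
    m[m == "."] <- "-"
    return(toupper(m))
  }
  if (is.matrix(alignment)) return(toupper(alignment))
  if (is.character(alignment)) {
    w <- unique(nchar(alignment))
    if (length(w) != 1L) stop("alignment rows have unequal widths")
    m <- do.call(rbind, strsplit(alignment, ""))
    rownames(m) <- names(alignment)
    return(toupper(m))
  }
  stop("unsupported alignment representation")
}

# Extract one protein's non-gap coordinates (inverse of build_family).
family_coords <- function(family, i, flavor = c("alpha", "mass_center")) {
  flavor <- match.arg(flavor)
  cols <- which(!family$gap[i, ])
  matrix(family[[flavor]][i, cols, ], ncol = 3)
}

# Apply a rigid transform to every coordinate (both flavors) of protein i.
transform_protein <- function(family, i, tf) {
  for (f in c("alpha", "mass_center")) {
    cols <- which(!family$gap[i, ])
    if (!length(cols)) next
    xyz <- matrix(family[[f]][i, cols, ], ncol = 3)
    family[[f]][i, cols, ] <- apply_transform(tf, xyz)
  }
  family
}
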