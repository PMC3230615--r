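#' Standard protein of a family
#'
#' The family's hypothetical representative: the consensus (most frequent)
#' amino acid and the unweighted average coordinate at every alignment
#' column. Gap cells are excluded from the average — a gap carries no
#' coordinates, and imputing any would manufacture displacement signal.
#' The family must already be superposed for the average structure to be
#' meaningful; this is the caller's responsibility.
#'
#' @param family A superposed `spca_family`.
#' @param table The matching `spca_freqs` (recomputed if omitted).
#' @return Object of class `spca_standard`: `consensus` (length-L one-letter
#'   codes), `alpha` and `mass_center` (L x 3 average coordinates) and
#'   `support` (number of contributing proteins per column).
#' @export
standard_protein <- function(family, table = NULL) {
  if (is.null(table))
    table <- position_frequencies(composition_tensor(family))
  L <- n_positions(family)
  if (length(table$consensus) != L)
    stop("frequency table does not match the family's column count")
  support <- colSums(!family$gap)
  if (any(support == 0))
    stop("column(s) with no non-gap protein: ",
         paste(which(support == 0), collapse = ", "),
         " (run reduce_gaps first)")
  avg <- function(coords) {
    out <- matrix(NA_real_, L, 3)
    for (l in seq_len(L)) {
      rows <- which(!family$gap[, l])
      out[l, ] <- colMeans(matrix(coords[rows, l, ], ncol = 3))
    }
    out
  }
  structure(
    list(consensus = table$consensus,
         alpha = avg(family$alpha),
         mass_center = avg(family$mass_center),
         support = support),
    class = "spca_standard"
  )
}

#' @export
print.spca_standard <- function(x, ...) {
  cat("<spca_standard> ", length(x$consensus), " positions, consensus ",
      paste(x$consensus, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Position displacement matrix
#'
#' Per-protein, per-position Euclidean distances to the standard protein:
#' `d[i, l]` is the distance between protein i's residue at column l and
#' the standard protein's residue at l, using either alpha-carbon or
#' residue mass-center coordinates. Gap cells are `NA`.
#'
#' @param family A superposed `spca_family`.
#' @param p0 The matching [standard_protein()].
#' @param flavor `"alpha"` (alpha-carbon) or `"mass_center"`.
#' @return Object of class `spca_displacement`: `values` (N x L, Angstrom,
#'   `NA` at gaps), `flavor`, and `column_means` (average displacement per
#'   position over non-gap cells).
#' @export
displacement_matrix <- function(family, p0, flavor = c("alpha", "mass_center")) {
  flavor <- match.arg(flavor)
  L <- n_positions(family)
  if (nrow(p0$alpha) != L)
    stop("standard protein does not match the family's column count")
  ref <- p0[[flavor]]
  coords <- family[[flavor]]
  n <- n_proteins(family)
  d <- matrix(NA_real_, n, L, dimnames = list(family$ids, NULL))
  for (l in seq_len(L)) {
    rows <- which(!family$gap[, l])
    if (!length(rows)) next
    dev <- sweep(matrix(coords[rows, l, ], ncol = 3), 2, ref[l, ])
    d[rows, l] <- sqrt(rowSums(dev^2))
  }
  structure(
    list(values = d, flavor = flavor,
         column_means = colMeans(d, na.rm = TRUE)),
    class = "spca_displacement"
  )
}

#' @export
print.spca_displacement <- function(x, ...) {
  cat("<spca_displacement> ", nrow(x$values), " proteins x ",
      ncol(x$values), " positions (", x$flavor, "), mean ",
      format(mean(x$values, na.rm = TRUE), digits = 4), " A\n", sep = "")
  invisible(x)
}
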