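#' Binary amino-acid composition tensor
#'
#' Encodes the family's sequences as a binary N x M x L tensor over the
#' M = 21 symbol alphabet (gap plus the 20 natural amino acids in
#' alphabetical one-letter order): element `[i, k, l]` is 1 exactly when
#' protein i carries symbol k at alignment column l. Non-standard letters
#' (B, J, O, U, X, Z, ...) are mapped to the gap symbol with a warning.
#'
#' @param family An `spca_family`.
#' @return Integer N x 21 x L array with dimnames on the symbol axis.
#' @export
composition_tensor <- function(family) {
  n <- n_proteins(family)
  L <- n_positions(family)
  s <- family$seq
  bad <- !(s %in% ALPHABET)
  if (any(bad)) {
    warning(sum(bad), " non-standard residue code(s) (",
            paste(sort(unique(s[bad])), collapse = ", "),
            ") treated as gaps")
    s[bad] <- "-"
  }
  a <- array(0L, c(n, length(ALPHABET), L),
             dimnames = list(family$ids, ALPHABET, NULL))
  k <- match(s, ALPHABET)  # N x L in column-major order
  idx <- cbind(rep(seq_len(n), times = L), as.vector(k),
               rep(seq_len(L), each = n))
  a[idx] <- 1L
  a
}

#' Position frequency table
#'
#' Per-column relative frequencies of the 21 symbols, the consensus (most
#' frequent) symbol, its frequency, and the natural amino-acid occupancy
#' `q = 1 - f_gap` used for gap reduction.
#'
#' Tie-breaking for the consensus: when two amino acids share the maximal
#' frequency the alphabetically first one-letter code wins; when the gap
#' ties with an amino acid the amino acid wins (the consensus sequence is a
#' sequence of amino acids, so a gap is only consensus on a strict
#' majority).
#'
#' @param tensor Composition tensor from [composition_tensor()].
#' @return Object of class `spca_freqs`: list with `freqs` (21 x L, columns
#'   summing to 1), `consensus` (length-L character), `consensus_freq`,
#'   `natural_freq` (`q_l`) and `n_proteins`.
#' @export
position_frequencies <- function(tensor) {
  n <- dim(tensor)[1]
  if (is.na(n) || n == 0L) stop("empty composition tensor")
  L <- dim(tensor)[3]
  freqs <- apply(tensor, c(2, 3), sum) / n
  rownames(freqs) <- ALPHABET

  consensus <- character(L)
  consensus_freq <- numeric(L)
  for (l in seq_len(L)) {
    f <- freqs[, l]
    top <- max(f)
    cand <- ALPHABET[f == top]
    if (length(cand) > 1L && "-" %in% cand) cand <- setdiff(cand, "-")
    consensus[l] <- sort(cand)[1]
    consensus_freq[l] <- top
  }
  # occupancy as an exact count ratio (1 - f_gap would lose the strict
  # threshold semantics to floating-point cancellation)
  gap_count <- apply(tensor[, 1, , drop = FALSE], 3, sum)
  structure(
    list(freqs = freqs, consensus = consensus,
         consensus_freq = consensus_freq,
         natural_freq = (n - gap_count) / n,
         n_proteins = n),
    class = "spca_freqs"
  )
}

#' @export
print.spca_freqs <- function(x, ...) {
  cat("<spca_freqs> ", ncol(x$freqs), " columns over ", x$n_proteins,
      " proteins; consensus ", paste(x$consensus, collapse = ""), "\n",
      sep = "")
  invisible(x)
}

#' Most conservative positions
#'
#' Columns whose most frequent amino acid exceeds the conservation
#' threshold (strictly greater). A column whose consensus is the gap can
#' never be conservative: conservation is defined on amino acids, and the
#' conservative set seeds the structural core of the superposition.
#'
#' @param table An `spca_freqs`.
#' @param threshold Conservation cutoff in (0, 1); default 0.80.
#' @return Increasing integer vector of 1-based column indices (possibly
#'   empty).
#' @export
conservative_positions <- function(table, threshold = 0.80) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  which(table$consensus_freq > threshold & table$consensus != "-")
}

#' Remove gap-dominated alignment columns
#'
#' Deletes columns whose natural amino-acid occupancy `q_l` (the summed
#' frequency of the 20 amino acids, i.e. 1 minus the gap frequency) is
#' strictly below `q_threshold`. Such gap-dominated indel columns would
#' otherwise distort the displacement statistics.
#'
#' @param family An `spca_family`.
#' @param table The matching `spca_freqs` (recomputed if omitted).
#' @param q_threshold Occupancy cutoff in (0, 1); default 0.20. A column
#'   with `q_l` equal to the threshold is retained (strict `<` deletes).
#' @return List with `family` (columns removed) and `kept_columns`, the
#'   original 1-based column index of every retained column.
#' @export
reduce_gaps <- function(family, table = NULL, q_threshold = 0.20) {
  if (q_threshold <= 0 || q_threshold >= 1)
    stop("q_threshold must be in (0, 1)")
  if (is.null(table))
    table <- position_frequencies(composition_tensor(family))
  q <- as.numeric(table$natural_freq)
  keep <- which(q >= q_threshold)
  if (!length(keep)) stop("gap reduction removed every column")
  fam <- new_family(
    family$ids,
    family$seq[, keep, drop = FALSE],
    family$alpha[, keep, , drop = FALSE],
    family$mass_center[, keep, , drop = FALSE],
    family$gap[, keep, drop = FALSE]
  )
  list(family = fam, kept_columns = keep)
}
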