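#' Write a labelled numeric matrix as TSV
#'
#' Full-precision (round-trippable) tab-separated output with a header row
#' of column labels and a leading label column.
#'
#' @param matrix Numeric matrix (may be 0 x 0).
#' @param row_labels,col_labels Character vectors matching the dimensions.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_matrix <- function(matrix, row_labels, col_labels, path) {
  matrix <- as.matrix(matrix)
  if (length(row_labels) != nrow(matrix) ||
      length(col_labels) != ncol(matrix))
    stop("label counts do not match matrix dimensions")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", col_labels), collapse = "\t"), con)
  for (i in seq_len(nrow(matrix))) {
    writeLines(paste(c(row_labels[i],
                       sprintf("%.17g", matrix[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a TSV matrix written by [write_matrix()]
#' @param path File path.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                   check.names = FALSE, colClasses = "character")
  matrix(as.numeric(as.matrix(df)), nrow(df), ncol(df),
         dimnames = dimnames(df))
}

#' Write the standard protein as a PDB file
#'
#' One CA pseudo-atom per retained position; residue name is the consensus
#' amino acid (three-letter code, `UNK` where the consensus is a gap),
#' residue number the 1-based position index.
#'
#' @param p0 An [standard_protein()].
#' @param path Output PDB path.
#' @param position_labels Optional integer residue numbers (e.g. original
#'   column indices); default `1:L`.
#' @return The path, invisibly.
#' @export
write_standard_protein <- function(p0, path, position_labels = NULL) {
  L <- length(p0$consensus)
  resno <- position_labels %||% seq_len(L)
  resid <- ifelse(p0$consensus == "-", "UNK", aa_one_to_three(p0$consensus))
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(p0$alpha)),
                   resno = resno, resid = resid,
                   elety = rep("CA", L), chain = rep("A", L))
  invisible(path)
}

#' Write high-correlation pairs as a 3-column TSV
#' @param pairs Data frame with columns `i`, `j`, `r`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  write.table(pairs[, c("i", "j", "r")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pair TSV (columns i, j, r)
#' @param path File path.
#' @return Data frame with integer `i`, `j` and numeric `r`.
#' @export
read_pairs <- function(path) {
  df <- tryCatch(
    read.table(path, sep = "\t", header = TRUE),
    error = function(e) stop("cannot read pair file '", path, "': ",
                             conditionMessage(e))
  )
  if (!all(c("i", "j", "r") %in% names(df)))
    stop("pair file must have columns i, j, r")
  df$i <- as.integer(df$i)
  df$j <- as.integer(df$j)
  df$r <- as.numeric(df$r)
  df
}

#' Write a segment table as TSV
#' @param set An `spca_segments`.
#' @param path Output path.
#' @param column_map Optional integer map from current to original column
#'   numbers (e.g. `kept_columns` from [reduce_gaps()]); when given, extra
#'   columns with original start/end coordinates are written.
#' @return The path, invisibly.
#' @export
write_segment_table <- function(set, path, column_map = NULL) {
  df <- as.data.frame(set)
  if (!is.null(column_map)) {
    df$orig_start <- column_map[df$start]
    df$orig_end <- column_map[df$end]
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a structure record as a PDB file
#'
#' Writes every atom of an [structure_record()]; within each residue the
#' atom coinciding with the stored alpha-carbon coordinate is named `CA`,
#' remaining atoms are named by element with a per-residue counter (enough
#' to round-trip through [read_structure()]).
#'
#' @param s An `spca_structure`.
#' @param path Output PDB path.
#' @return The path, invisibly.
#' @export
write_structure_pdb <- function(s, path) {
  a <- s$atoms
  elety <- character(nrow(a))
  for (l in seq_along(s$resid)) {
    rows <- which(a$res == l)
    is_ca <- abs(a$x[rows] - s$ca[l, 1]) < 5e-4 &
      abs(a$y[rows] - s$ca[l, 2]) < 5e-4 &
      abs(a$z[rows] - s$ca[l, 3]) < 5e-4
    ca_row <- if (any(is_ca)) rows[which(is_ca)[1]] else rows[1]
    elety[ca_row] <- "CA"
    others <- setdiff(rows, ca_row)
    elety[others] <- paste0(a$elesy[others], "X", seq_along(others))
  }
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$res, resid = s$resid[a$res],
                   elety = elety, elesy = a$elesy,
                   chain = rep("A", nrow(a)))
  invisible(path)
}

#' Write the consensus sequence as FASTA
#' @param p0 An [standard_protein()].
#' @param path Output path.
#' @param id Sequence header; default "standard_protein".
#' @return The path, invisibly.
#' @export
write_consensus_fasta <- function(p0, path, id = "standard_protein") {
  writeLines(c(paste0(">", id), paste(p0$consensus, collapse = "")), path)
  invisible(path)
}
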