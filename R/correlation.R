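#' Displacement covariance between positions
#'
#' Sample covariance of the per-position displacement magnitudes across the
#' family. Column means are computed over each column's present (non-gap)
#' cells; each pair (i, j) is averaged over the proteins where both cells
#' are present, with divisor `N_ij - 1`. Pairs supported by fewer than 3
#' proteins, and columns with fewer than 3 present cells, are set to `NA`
#' with a message.
#'
#' The correlation (the thresholded quantity downstream) is identical under
#' the `N` and `N - 1` divisor conventions.
#'
#' @param D An `spca_displacement`, or a plain numeric N x L matrix of
#'   displacements with `NA` for missing cells. N >= 3 required.
#' @return Object of class `spca_correlation` with `covariance` (L x L),
#'   `column_means`, `valid_pairs` (L x L counts) and a `correlation` slot
#'   left `NULL` until [displacement_correlation()] fills it.
#' @export
displacement_covariance <- function(D) {
  v <- if (inherits(D, "spca_displacement")) D$values else as.matrix(D)
  n <- nrow(v)
  L <- ncol(v)
  if (n < 3) stop("need at least 3 proteins for covariance analysis")
  present <- !is.na(v)
  n_col <- colSums(present)
  means <- colSums(ifelse(present, v, 0)) / pmax(n_col, 1)

  centered <- sweep(v, 2, means)
  centered[!present] <- 0
  npair <- crossprod(present)          # N_ij
  cov <- crossprod(centered) / pmax(npair - 1, 1)
  cov[npair < 3] <- NA_real_

  thin <- which(n_col < 3)
  if (length(thin)) {
    message("column(s) with < 3 present cells set to NA in covariance: ",
            paste(thin, collapse = ", "))
    cov[thin, ] <- NA_real_
    cov[, thin] <- NA_real_
  }
  structure(
    list(covariance = cov, correlation = NULL,
         column_means = means, valid_pairs = npair),
    class = "spca_correlation"
  )
}

#' Displacement correlation between positions
#'
#' Normalizes a covariance matrix to Pearson correlations:
#' `r_ij = c_ij / sqrt(c_ii * c_jj)`, with unit diagonal wherever the
#' column variance is positive. Pairs involving a zero-variance (or
#' missing) column are `NA`.
#'
#' @param result An `spca_correlation` from [displacement_covariance()].
#' @return The same object with the `correlation` matrix filled.
#' @export
displacement_correlation <- function(result) {
  cov <- result$covariance
  if (is.null(cov)) stop("covariance not filled")
  sd <- sqrt(diag(cov))
  sd[!is.na(sd) & sd == 0] <- NA_real_
  r <- cov / outer(sd, sd)
  diag(r) <- ifelse(is.na(sd), NA_real_, 1)
  result$correlation <- r
  result
}

#' @export
print.spca_correlation <- function(x, ...) {
  cat("<spca_correlation> ", ncol(x$covariance), " positions; correlation ",
      if (is.null(x$correlation)) "not yet computed" else "computed",
      "\n", sep = "")
  invisible(x)
}

#' High-correlation position pairs
#'
#' All ordered off-diagonal pairs with correlation strictly above the
#' threshold. Both orientations (i, j) and (j, i) are reported — the
#' conventional symmetric listing — sorted by i then j.
#'
#' @param result An `spca_correlation` with the correlation filled.
#' @param threshold Correlation cutoff; default 0.60 (strict `>`).
#' @return Data frame with columns `i`, `j`, `r`.
#' @export
high_correlation_pairs <- function(result, threshold = 0.60) {
  r <- if (inherits(result, "spca_correlation")) result$correlation else
    as.matrix(result)
  if (is.null(r)) stop("correlation not filled")
  hit <- which(!is.na(r) & r > threshold & row(r) != col(r), arr.ind = TRUE)
  out <- data.frame(i = hit[, 1], j = hit[, 2],
                    r = r[hit])
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}
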