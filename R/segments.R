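#' Build structural segments from high-correlation pairs
#'
#' A structural segment is a maximal run of contiguous positions linked by
#' high displacement correlations. Links are restricted to nearby pairs
#' (`|i - j| <= window`) so that a strong correlation between distant
#' positions — an allosteric contact, not a contiguous unit — cannot fuse
#' separate regions. Connected components of the resulting graph are closed
#' to their full interval `[min, max]` (interior positions without a
#' qualifying pair of their own are swept in), overlapping or adjacent
#' intervals are merged, and every remaining column becomes a singleton
#' segment. Multi-position segments are labelled S1, S2, ... left to right;
#' singletons are labelled by their position (P<column>).
#'
#' @param pairs Data frame with columns `i`, `j` (1-based positions) and
#'   optionally `r`, e.g. from [high_correlation_pairs()].
#' @param length Number of alignment columns L.
#' @param window Maximum sequence separation of a linking pair; default 4.
#'
#' @return Object of class `spca_segments`: a data frame with columns `id`,
#'   `start`, `end`, `n_positions`, `multi`, one row per segment in
#'   left-to-right order. Attributes `total_count` (K) and `multi_count`.
#' @export
find_segments <- function(pairs, length, window = 4L) {
  if (window < 1) stop("window must be >= 1")
  L <- as.integer(length)
  if (L < 1) stop("length must be >= 1")
  if (nrow(pairs) > 0 &&
      (any(pairs$i < 1 | pairs$i > L) || any(pairs$j < 1 | pairs$j > L)))
    stop("pair indices out of range 1..", L)

  keep <- pairs[pairs$i != pairs$j & abs(pairs$i - pairs$j) <= window, ,
                drop = FALSE]
  intervals <- NULL
  if (nrow(keep) > 0) {
    g <- igraph::graph_from_edgelist(
      cbind(as.character(keep$i), as.character(keep$j)), directed = FALSE)
    comp <- igraph::components(g)
    members <- split(as.integer(igraph::V(g)$name), comp$membership)
    members <- Filter(function(m) base::length(m) >= 2, members)
    intervals <- t(vapply(members, range, integer(2)))
    intervals <- intervals[order(intervals[, 1]), , drop = FALSE]
    # Interval closure can create overlap/adjacency between components.
    merged <- list()
    for (k in seq_len(nrow(intervals))) {
      iv <- intervals[k, ]
      m <- base::length(merged)
      if (m > 0 && iv[1] <= merged[[m]][2] + 1L) {
        merged[[m]][2] <- max(merged[[m]][2], iv[2])
      } else {
        merged[[m + 1L]] <- iv
      }
    }
    intervals <- do.call(rbind, merged)
  }

  covered <- logical(L)
  if (!is.null(intervals))
    for (k in seq_len(nrow(intervals)))
      covered[intervals[k, 1]:intervals[k, 2]] <- TRUE

  start <- integer(0); end <- integer(0)
  if (!is.null(intervals)) {
    start <- intervals[, 1]; end <- intervals[, 2]
  }
  singles <- which(!covered)
  seg <- data.frame(start = c(start, singles), end = c(end, singles))
  seg <- seg[order(seg$start), , drop = FALSE]
  seg$n_positions <- seg$end - seg$start + 1L
  seg$multi <- seg$n_positions >= 2L
  seg$id <- character(nrow(seg))
  seg$id[seg$multi] <- paste0("S", seq_len(sum(seg$multi)))
  seg$id[!seg$multi] <- paste0("P", seg$start[!seg$multi])
  seg <- seg[, c("id", "start", "end", "n_positions", "multi")]
  rownames(seg) <- NULL
  structure(seg, class = c("spca_segments", "data.frame"),
            total_count = nrow(seg), multi_count = sum(seg$multi),
            length = L, window = as.integer(window))
}

#' @export
print.spca_segments <- function(x, ...) {
  cat("<spca_segments> K = ", attr(x, "total_count"), " segments over ",
      attr(x, "length"), " positions (", attr(x, "multi_count"),
      " multi-position, ",
      sum(x$n_positions[x$multi]), " member positions)\n", sep = "")
  print.data.frame(x[x$multi, , drop = FALSE], row.names = FALSE)
  invisible(x)
}

#' Per-protein segment coordinates
#'
#' The coordinate of a segment in one protein is the unweighted mean of the
#' alpha-carbon coordinates of its non-gap member positions; a singleton
#' segment's coordinate is its position's coordinate exactly. The cell is
#' missing if all member positions are gapped for that protein.
#'
#' @param family A superposed `spca_family`.
#' @param set An `spca_segments` partitioning the family's columns.
#' @return N x K x 3 array of segment coordinates (`NA` where undefined),
#'   with segment ids on the second dimension.
#' @export
segment_coordinates <- function(family, set) {
  L <- n_positions(family)
  if (sum(set$n_positions) != L)
    stop("segment set does not partition the family's ", L, " columns")
  n <- n_proteins(family)
  K <- nrow(set)
  coords <- array(NA_real_, c(n, K, 3),
                  dimnames = list(family$ids, set$id, NULL))
  for (k in seq_len(K)) {
    cols <- set$start[k]:set$end[k]
    for (i in seq_len(n)) {
      use <- cols[!family$gap[i, cols]]
      if (!length(use)) next
      coords[i, k, ] <- colMeans(matrix(family$alpha[i, use, ], ncol = 3))
    }
  }
  coords
}

#' Segment-level displacement and correlation analysis
#'
#' Applies the position-level machinery at segment resolution: the standard
#' segment structure is the per-segment mean over proteins, displacements
#' are Euclidean distances to it, and covariance/correlation are computed
#' by [displacement_covariance()] / [displacement_correlation()].
#'
#' @param coords N x K x 3 segment coordinates from [segment_coordinates()].
#' @param set The matching `spca_segments`.
#' @return List of class `spca_segment_analysis`: `standard` (K x 3 mean
#'   segment coordinates), `displacement` (N x K), `correlation` and
#'   `covariance` (K x K), `valid_pairs`, and the `segments` table.
#' @export
segment_analysis <- function(coords, set) {
  n <- dim(coords)[1]
  K <- dim(coords)[2]
  if (K != nrow(set)) stop("coordinate array does not match the segment set")
  standard <- matrix(NA_real_, K, 3)
  for (k in seq_len(K)) {
    rows <- which(!is.na(coords[, k, 1]))
    if (!length(rows)) stop("segment ", set$id[k], " has no defined cells")
    standard[k, ] <- colMeans(matrix(coords[rows, k, ], ncol = 3))
  }
  disp <- matrix(NA_real_, n, K, dimnames = dimnames(coords)[1:2])
  for (k in seq_len(K)) {
    rows <- which(!is.na(coords[, k, 1]))
    dev <- sweep(matrix(coords[rows, k, ], ncol = 3), 2, standard[k, ])
    disp[rows, k] <- sqrt(rowSums(dev^2))
  }
  res <- displacement_correlation(displacement_covariance(disp))
  dimnames(res$correlation) <- list(set$id, set$id)
  dimnames(res$covariance) <- list(set$id, set$id)
  structure(
    list(standard = standard, displacement = disp,
         covariance = res$covariance, correlation = res$correlation,
         valid_pairs = res$valid_pairs, segments = set),
    class = "spca_segment_analysis"
  )
}

#' @export
print.spca_segment_analysis <- function(x, ...) {
  cat("<spca_segment_analysis> ", ncol(x$displacement),
      " segments x ", nrow(x$displacement), " proteins\n", sep = "")
  invisible(x)
}
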