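#' Optimal rigid-body fit of one point set onto another
#'
#' Weighted least-squares superposition (Kabsch algorithm via SVD of the
#' weighted cross-covariance). The returned rotation is always proper
#' (determinant +1); an improper optimum is corrected by flipping the sign
#' of the smallest singular direction.
#'
#' @param mobile,target Numeric P x 3 coordinate matrices, P >= 3 and not
#'   collinear.
#' @param weights Optional non-negative weights of length P with a positive
#'   sum; default uniform.
#'
#' @return List with `transform` (a `rigid_transform`: `rotation` 3 x 3,
#'   `translation` length 3, applied as `x %*% rotation + translation`) and
#'   `rmsd`, the weighted root-mean-square deviation after fitting
#'   (Angstrom).
#' @export
kabsch_fit <- function(mobile, target, weights = NULL) {
  mobile <- as.matrix(mobile)
  target <- as.matrix(target)
  p <- nrow(mobile)
  stopifnot(ncol(mobile) == 3, ncol(target) == 3, nrow(target) == p)
  if (p < 3) stop("need at least 3 points to define a rigid fit")
  w <- weights %||% rep(1, p)
  if (length(w) != p || any(w < 0) || sum(w) <= 0)
    stop("weights must be non-negative with a positive sum")
  w <- w / sum(w)

  mbar <- colSums(mobile * w)
  tbar <- colSums(target * w)
  mc <- sweep(mobile, 2, mbar)
  tc <- sweep(target, 2, tbar)

  # Degenerate (collinear) configurations leave the rotation under-determined.
  sv <- svd(mc * sqrt(w))$d
  if (sv[2] < max(sv[1], 1) * 1e-9)
    stop("degenerate (collinear) point configuration")

  h <- crossprod(mc * w, tc)
  s <- svd(h)
  d <- sign(det(s$u) * det(s$v))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  trans <- tbar - as.numeric(mbar %*% rot)
  fitted <- mobile %*% rot
  fitted <- sweep(fitted, 2, trans, `+`)
  rmsd <- sqrt(sum(w * rowSums((fitted - target)^2)))
  tf <- structure(list(rotation = rot, translation = trans),
                  class = "rigid_transform")
  list(transform = tf, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#'
#' @param tf A `rigid_transform` from [kabsch_fit()].
#' @param coords Numeric P x 3 matrix.
#' @return Transformed P x 3 matrix.
#' @export
apply_transform <- function(tf, coords) {
  sweep(as.matrix(coords) %*% tf$rotation, 2, tf$translation, `+`)
}

#' Invert a rigid transform
#' @param tf A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  structure(list(rotation = t(tf$rotation),
                 translation = -as.numeric(tf$translation %*% t(tf$rotation))),
            class = "rigid_transform")
}

#' Iterative multi-body superposition of a family
#'
#' Superposes all family members onto their evolving mean structure:
#' (1) compute per-column mean coordinates over non-gap cells at the masked
#' columns, (2) rigid-fit every protein onto the mean using its non-gap
#' masked cells, (3) recompute the mean; repeat until the summed RMSD of the
#' superposition fails to improve by more than `tol` or `max_iter` is hit.
#' The first reference is the first protein's coordinates, which makes the
#' procedure deterministic. Each protein's fitted transform is applied to
#' ALL of its coordinates (alpha-carbon and mass-center, all columns), so
#' internal geometry is untouched.
#'
#' Columns where fewer than 2 proteins have coordinates are excluded from
#' the mean (and the RMSD) for that iteration.
#'
#' @param family An `spca_family`.
#' @param position_mask Optional logical vector of length L selecting the
#'   columns used for fitting; default all columns. At least 3 masked
#'   columns with >= 2 non-gap proteins each are required (when N >= 2).
#' @param tol Convergence tolerance on the RMSD improvement (Angstrom).
#' @param max_iter Maximum number of mean/fit iterations.
#'
#' @return List with `family` (superposed) and `report`, a
#'   `superposition_report` with `iterations`, `rmsd_trace` and `converged`.
#' @export
generalized_superpose <- function(family, position_mask = NULL,
                                  tol = 1e-4, max_iter = 100L) {
  n <- n_proteins(family)
  L <- n_positions(family)
  mask <- position_mask %||% rep(TRUE, L)
  if (length(mask) != L) stop("position_mask must have length ", L)
  if (n == 0L) stop("empty family")
  if (n == 1L) {
    report <- structure(list(iterations = 1L, rmsd_trace = 0, converged = TRUE),
                        class = "superposition_report")
    return(list(family = family, report = report))
  }
  support <- colSums(!family$gap)
  usable <- mask & support >= 2
  if (sum(usable) < 3)
    stop("fewer than 3 masked columns with >= 2 non-gap proteins")

  ref <- matrix(NA_real_, L, 3)
  cols1 <- which(!family$gap[1, ] & mask)
  ref[cols1, ] <- matrix(family$alpha[1, cols1, ], ncol = 3)

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      cols <- which(!family$gap[i, ] & mask & !is.na(ref[, 1]))
      if (length(cols) < 3)
        stop("protein '", family$ids[i],
             "' shares fewer than 3 usable columns with the reference")
      fit <- kabsch_fit(matrix(family$alpha[i, cols, ], ncol = 3),
                        ref[cols, , drop = FALSE])
      family <- transform_protein(family, i, fit$transform)
    }
    ref <- masked_mean(family, mask)
    rmsd <- masked_rmsd(family, mask, ref)
    trace <- c(trace, rmsd)
    if (iter > 1L && (trace[iter - 1L] - rmsd) < tol) {
      converged <- TRUE
      break
    }
  }
  report <- structure(list(iterations = iter, rmsd_trace = trace,
                           converged = converged),
                      class = "superposition_report")
  list(family = family, report = report)
}

# Per-column mean alpha coordinates over non-gap cells; NA where the column
# is outside the mask or has < 2 contributing proteins.
masked_mean <- function(family, mask) {
  L <- n_positions(family)
  ref <- matrix(NA_real_, L, 3)
  support <- colSums(!family$gap)
  for (l in which(mask & support >= 2)) {
    rows <- which(!family$gap[, l])
    ref[l, ] <- colMeans(matrix(family$alpha[rows, l, ], ncol = 3))
  }
  ref
}

# RMSD of all non-gap cells at defined masked columns about the mean.
masked_rmsd <- function(family, mask, ref) {
  total <- 0
  count <- 0L
  for (l in which(mask & !is.na(ref[, 1]))) {
    rows <- which(!family$gap[, l])
    dev <- sweep(matrix(family$alpha[rows, l, ], ncol = 3), 2, ref[l, ])
    total <- total + sum(dev^2)
    count <- count + length(rows)
  }
  if (count == 0L) return(0)
  sqrt(total / count)
}

#' Refinement superposition on the most conservative positions
#'
#' Second superposition stage: re-runs [generalized_superpose()] with the
#' fitting mask restricted to the most conservative positions, minimizing
#' the coordinate RMSD over those positions while transforming all
#' coordinates of each protein.
#'
#' @param family An `spca_family` (typically already globally superposed).
#' @param conservative_positions Integer vector of 1-based column indices
#'   (e.g. from [conservative_positions()]); at least 3 required.
#' @inheritParams generalized_superpose
#' @return As [generalized_superpose()].
#' @export
refine_on_conservative <- function(family, conservative_positions,
                                   tol = 1e-4, max_iter = 100L) {
  L <- n_positions(family)
  if (length(conservative_positions) < 3)
    stop("need at least 3 conservative positions to refine on")
  if (any(conservative_positions < 1 | conservative_positions > L))
    stop("conservative positions out of range 1..", L)
  mask <- rep(FALSE, L)
  mask[conservative_positions] <- TRUE
  generalized_superpose(family, position_mask = mask,
                        tol = tol, max_iter = max_iter)
}

#' @export
print.superposition_report <- function(x, ...) {
  cat("<superposition_report> ", x$iterations, " iterations, final RMSD ",
      format(x$rmsd_trace[length(x$rmsd_trace)], digits = 6), " A, ",
      if (x$converged) "converged" else "not converged", "\n", sep = "")
  invisible(x)
}
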