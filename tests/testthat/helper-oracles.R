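# Independent reference implementations used to check the package's
# numerics. These deliberately share no code with the package internals.

# Horn's quaternion method for the optimal weighted rigid superposition.
# Returns the minimal weighted RMSD and the (proper) rotation as a
# quaternion-derived matrix.
oracle_quaternion_fit <- function(mobile, target, weights = NULL) {
  p <- nrow(mobile)
  w <- if (is.null(weights)) rep(1, p) else weights
  w <- w / sum(w)
  mbar <- colSums(mobile * w)
  tbar <- colSums(target * w)
  x <- sweep(mobile, 2, mbar)
  y <- sweep(target, 2, tbar)
  s <- crossprod(x * w, y)  # 3x3 weighted cross-covariance
  sxx <- s[1, 1]; sxy <- s[1, 2]; sxz <- s[1, 3]
  syx <- s[2, 1]; syy <- s[2, 2]; syz <- s[2, 3]
  szx <- s[3, 1]; szy <- s[3, 2]; szz <- s[3, 3]
  key <- matrix(c(
    sxx + syy + szz, syz - szy,        szx - sxz,        sxy - syx,
    syz - szy,       sxx - syy - szz,  sxy + syx,        szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz,  syz + szy,
    sxy - syx,       szx + sxz,        syz + szy,       -sxx - syy + szz
  ), 4, 4, byrow = TRUE)
  e <- eigen(key, symmetric = TRUE)
  lam <- e$values[1]
  q <- e$vectors[, 1]
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  rot <- matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c + a * d),   2 * (b * d - a * c),
    2 * (b * c - a * d),   a^2 - b^2 + c^2 - d^2, 2 * (c * d + a * b),
    2 * (b * d + a * c),   2 * (c * d - a * b),   a^2 - b^2 - c^2 + d^2
  ), 3, 3)
  msd <- sum(w * rowSums(x^2)) + sum(w * rowSums(y^2)) - 2 * lam
  list(rmsd = sqrt(max(msd, 0)), rotation = rot)
}

# Brute-force double-loop covariance and Pearson correlation over the rows
# of a complete (no NA) displacement matrix, sample (n-1) divisor.
oracle_covariance <- function(d) {
  n <- nrow(d); L <- ncol(d)
  means <- numeric(L)
  for (j in seq_len(L)) means[j] <- sum(d[, j]) / n
  cc <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    acc <- 0
    for (k in seq_len(n)) acc <- acc + (d[k, i] - means[i]) * (d[k, j] - means[j])
    cc[i, j] <- acc / (n - 1)
  }
  cc
}

oracle_pearson <- function(d) {
  cc <- oracle_covariance(d)
  L <- ncol(cc)
  r <- matrix(NA_real_, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    denom <- sqrt(cc[i, i] * cc[j, j])
    if (denom > 0) r[i, j] <- cc[i, j] / denom
  }
  r
}

# Per-column symbol counting oracle for the frequency table.
oracle_frequencies <- function(seq_mat, alphabet) {
  n <- nrow(seq_mat); L <- ncol(seq_mat)
  f <- matrix(0, length(alphabet), L, dimnames = list(alphabet, NULL))
  for (l in seq_len(L)) for (i in seq_len(n)) {
    k <- seq_mat[i, l]
    if (!k %in% alphabet) k <- "-"
    f[k, l] <- f[k, l] + 1
  }
  f / n
}

# Independent generalized-Procrustes loop on a complete family (list of
# L x 3 matrices), run for a fixed number of iterations with the
# quaternion fitter. Returns the fitted coordinate list and the mean.
oracle_gpa <- function(coord_list, iters = 200) {
  ref <- coord_list[[1]]
  for (it in seq_len(iters)) {
    for (i in seq_along(coord_list)) {
      x <- coord_list[[i]]
      fit <- oracle_quaternion_fit(x, ref)
      xbar <- colMeans(x)
      rbar <- colMeans(ref)
      xr <- sweep(x, 2, xbar) %*% t(fit$rotation)  # row-vector convention
      coord_list[[i]] <- sweep(xr, 2, rbar, `+`)
    }
    ref <- Reduce(`+`, coord_list) / length(coord_list)
  }
  list(coords = coord_list, mean = ref)
}

# Random proper rotation for invariance tests.
random_rotation_oracle <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
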