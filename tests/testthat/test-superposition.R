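test_that("kabsch_fit recovers exact rigid motions", {
  set.seed(1)
  x <- matrix(rnorm(15), 5, 3)

  same <- kabsch_fit(x, x)
  expect_equal(same$rmsd, 0, tolerance = 1e-12)
  expect_equal(same$transform$rotation, diag(3), tolerance = 1e-9)

  rotz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # 90 deg about z
  y <- rigid_move(x, rotz, c(1, 2, 3))
  fit <- kabsch_fit(x, y)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(apply_transform(fit$transform, x), y, tolerance = 1e-9)
  expect_equal(det(fit$transform$rotation), 1, tolerance = 1e-9)

  # inverse composes back to identity
  inv <- invert_transform(fit$transform)
  expect_equal(apply_transform(inv, apply_transform(fit$transform, x)), x,
               tolerance = 1e-9)
})

test_that("kabsch_fit matches the quaternion oracle on random clouds", {
  set.seed(7)
  for (rep in 1:20) {
    x <- matrix(rnorm(15, sd = 3), 5, 3)
    y <- matrix(rnorm(15, sd = 3), 5, 3)
    w <- runif(5, 0.1, 2)
    fit <- kabsch_fit(x, y, weights = w)
    orc <- oracle_quaternion_fit(x, y, weights = w)
    expect_equal(fit$rmsd, orc$rmsd, tolerance = 1e-9)
  }
})

test_that("kabsch RMSD is invariant under a common rigid transform", {
  set.seed(2)
  x <- matrix(rnorm(24), 8, 3)
  y <- matrix(rnorm(24), 8, 3)
  base <- kabsch_fit(x, y)$rmsd
  for (rep in 1:5) {
    rot <- random_rotation_oracle()
    shift <- rnorm(3, sd = 10)
    moved <- kabsch_fit(rigid_move(x, rot, shift), rigid_move(y, rot, shift))
    expect_equal(moved$rmsd, base, tolerance = 1e-9)
  }
})

test_that("degenerate point sets are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_fit(line, line + 1), "collinear|degenerate")
  expect_error(kabsch_fit(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "at least 3")
  x <- matrix(rnorm(9), 3, 3)
  expect_error(kabsch_fit(x, x, weights = c(0, 0, 0)), "weights")
})

test_that("rigid copies of one structure superpose to zero scatter", {
  set.seed(3)
  base <- matrix(rnorm(30, sd = 5), 10, 3)
  copies <- lapply(1:20, function(i)
    rigid_move(base, random_rotation_oracle(), rnorm(3, sd = 20)))
  fam <- make_family(copies)
  out <- generalized_superpose(fam, tol = 1e-10, max_iter = 200)

  # per-position scatter about the mean
  for (l in 1:10) {
    cloud <- matrix(out$family$alpha[, l, ], ncol = 3)
    dev <- sweep(cloud, 2, colMeans(cloud))
    expect_lt(sqrt(mean(rowSums(dev^2))), 1e-6)
  }

  # intra-protein geometry untouched
  d_before <- dist(base)
  for (i in 1:20) {
    d_after <- dist(matrix(out$family$alpha[i, , ], ncol = 3))
    expect_equal(as.numeric(d_after), as.numeric(d_before), tolerance = 1e-9)
  }
})

test_that("single-protein families are returned unchanged", {
  fam <- make_family(list(matrix(rnorm(15), 5, 3)))
  out <- generalized_superpose(fam)
  expect_identical(out$family$alpha, fam$alpha)
  expect_equal(out$report$iterations, 1L)
  expect_true(out$report$converged)
})

test_that("superposed mean agrees with a long-iteration Procrustes oracle", {
  set.seed(4)
  base <- matrix(rnorm(36, sd = 4), 12, 3)
  clouds <- lapply(1:6, function(i) {
    noisy <- base + matrix(rnorm(36, sd = 0.2), 12, 3)
    rigid_move(noisy, random_rotation_oracle(), rnorm(3, sd = 10))
  })
  fam <- make_family(clouds)
  out <- generalized_superpose(fam, tol = 1e-12, max_iter = 500)
  pkg_mean <- spca:::masked_mean(out$family, rep(TRUE, 12))
  orc <- oracle_gpa(clouds, iters = 200)
  # Procrustes means are defined up to a global rigid motion: the two must
  # agree as shapes, i.e. superpose onto each other with ~zero residual.
  fit <- oracle_quaternion_fit(orc$mean, pkg_mean)
  expect_lt(fit$rmsd, 1e-6)
  # and the converged objective (scatter about the mean) must match
  pkg_rmsd <- spca:::masked_rmsd(out$family, rep(TRUE, 12), pkg_mean)
  orc_dev <- vapply(orc$coords, function(x) sum((x - orc$mean)^2), numeric(1))
  orc_rmsd <- sqrt(sum(orc_dev) / (12 * length(orc$coords)))
  expect_equal(pkg_rmsd, orc_rmsd, tolerance = 1e-6)
})

test_that("superposition RMSD trace is non-increasing and gaps untouched", {
  set.seed(5)
  base <- matrix(rnorm(24, sd = 4), 8, 3)
  seqs <- matrix("A", 5, 8)
  seqs[2, 3] <- "-"
  seqs[4, 7] <- "-"
  clouds <- lapply(1:5, function(i) {
    noisy <- base + matrix(rnorm(24, sd = 0.4), 8, 3)
    rigid_move(noisy[seqs[i, ] != "-", , drop = FALSE],
               random_rotation_oracle(), rnorm(3, sd = 5))
  })
  L <- 8
  fam0 <- make_family(lapply(1:5, function(i) {
    full <- matrix(NA_real_, L, 3)
    full[seqs[i, ] != "-", ] <- clouds[[i]]
    full
  }), seqs = seqs)
  out <- generalized_superpose(fam0, tol = 1e-8, max_iter = 100)
  tr <- out$report$rmsd_trace
  if (length(tr) > 1) expect_true(all(diff(tr) <= 1e-8))
  expect_identical(out$family$gap, fam0$gap)
  expect_identical(out$family$seq, fam0$seq)
})

test_that("refinement on all columns equals an unmasked superposition", {
  set.seed(6)
  base <- matrix(rnorm(18, sd = 3), 6, 3)
  clouds <- lapply(1:4, function(i)
    rigid_move(base + matrix(rnorm(18, sd = 0.3), 6, 3),
               random_rotation_oracle(), rnorm(3, sd = 5)))
  fam <- make_family(clouds)
  a <- generalized_superpose(fam, tol = 1e-8, max_iter = 200)
  b <- refine_on_conservative(fam, 1:6, tol = 1e-8, max_iter = 200)
  expect_equal(a$family$alpha, b$family$alpha, tolerance = 1e-12)
})

test_that("refinement reduces RMSD over the conservative columns", {
  set.seed(8)
  base <- matrix(rnorm(30, sd = 4), 10, 3)
  cons <- 1:5
  # rigid noise plus large scatter restricted to NON-conservative columns
  clouds <- lapply(1:8, function(i) {
    x <- base
    x[6:10, ] <- x[6:10, ] + matrix(rnorm(15, sd = 2.0), 5, 3)
    x[cons, ] <- x[cons, ] + matrix(rnorm(15, sd = 0.05), 5, 3)
    rigid_move(x, random_rotation_oracle(), rnorm(3, sd = 5))
  })
  fam <- make_family(clouds)
  first <- generalized_superpose(fam, tol = 1e-8, max_iter = 200)$family

  rmsd_cons <- function(f) {
    mask <- rep(FALSE, 10); mask[cons] <- TRUE
    spca:::masked_rmsd(f, mask, spca:::masked_mean(f, mask))
  }
  before <- rmsd_cons(first)
  refined <- refine_on_conservative(first, cons, tol = 1e-8,
                                    max_iter = 200)$family
  expect_lte(rmsd_cons(refined), before + 1e-10)
})
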