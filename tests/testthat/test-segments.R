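pdz_pairs <- function() {
  read_pairs(system.file("extdata", "pdz_pair_table.tsv", package = "spca"))
}

test_that("the PDZ pair table yields the published segment partition", {
  segs <- find_segments(pdz_pairs(), length = 96, window = 4)
  multi <- segs[segs$multi, ]
  expect_equal(multi$start, c(4L, 26L, 50L, 65L, 75L, 90L))
  expect_equal(multi$end, c(7L, 34L, 51L, 66L, 83L, 92L))
  expect_equal(sum(multi$n_positions), 29L)
  expect_equal(attr(segs, "total_count"), 73L)
  expect_equal(attr(segs, "multi_count"), 6L)
  expect_equal(multi$id, paste0("S", 1:6))
})

test_that("segment construction degenerates and chains correctly", {
  empty <- data.frame(i = integer(0), j = integer(0), r = numeric(0))
  segs <- find_segments(empty, length = 10)
  expect_equal(attr(segs, "total_count"), 10L)
  expect_true(all(!segs$multi))

  chain <- data.frame(i = c(1L, 2L), j = c(2L, 3L), r = c(0.7, 0.7))
  segs2 <- find_segments(chain, length = 5)
  expect_equal(attr(segs2, "total_count"), 3L)
  expect_equal(segs2$start, c(1L, 4L, 5L))
  expect_equal(segs2$end, c(3L, 4L, 5L))

  # interval closure sweeps in interior positions without their own pair
  skip2 <- data.frame(i = 4L, j = 6L, r = 0.9)
  segs3 <- find_segments(skip2, length = 8)
  expect_equal(segs3$n_positions[segs3$multi], 3L)

  # a distant pair beyond the window cannot fuse separate regions
  distant <- data.frame(i = c(10L, 37L), j = c(11L, 78L), r = c(0.9, 0.9))
  segs4 <- find_segments(distant, length = 80, window = 4)
  expect_equal(sum(segs4$multi), 1L)
  expect_equal(segs4$start[segs4$multi], 10L)

  expect_error(find_segments(empty, length = 5, window = 0), "window")
  expect_error(find_segments(data.frame(i = 9L, j = 10L, r = 1), length = 5),
               "out of range")
})

test_that("every segment set partitions the columns", {
  set.seed(41)
  for (rep in 1:10) {
    L <- sample(10:60, 1)
    k <- sample(0:15, 1)
    pairs <- if (k > 0) {
      i <- sample(L, k, replace = TRUE)
      j <- pmin(L, i + sample(1:6, k, replace = TRUE))
      data.frame(i = i, j = j, r = runif(k, 0.6, 1))
    } else data.frame(i = integer(0), j = integer(0), r = numeric(0))
    pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
    segs <- find_segments(pairs, L)
    covered <- unlist(mapply(seq, segs$start, segs$end, SIMPLIFY = FALSE))
    expect_equal(sort(covered), 1:L)
    expect_equal(attr(segs, "total_count"),
                 L - sum(segs$n_positions[segs$multi]) + sum(segs$multi))
  }
})

test_that("segment coordinates average member positions per protein", {
  co1 <- rbind(c(0, 0, 0), c(2, 2, 2), c(9, 9, 9))
  co2 <- rbind(c(1, 0, 0), c(3, 2, 2), c(0, 0, 1))
  fam <- make_family(list(co1, co2))
  set <- find_segments(data.frame(i = 1L, j = 2L, r = 0.9), length = 3)
  coords <- segment_coordinates(fam, set)
  expect_equal(dim(coords), c(2L, 2L, 3L))
  expect_equal(coords[1, 1, ], c(1, 1, 1))      # midpoint of members
  expect_equal(coords[1, 2, ], c(9, 9, 9))      # singleton passes through
  expect_equal(coords[2, 2, ], c(0, 0, 1))

  # gapped members: mean over the non-gap subset, NA when all gapped
  seqs <- rbind(c("A", "A", "A"), c("A", "-", "A"), c("-", "-", "A"))
  co3 <- rbind(c(4, 4, 4), NA, c(5, 5, 5))
  fam2 <- make_family(list(co1, co3, rbind(NA, NA, c(7, 7, 7))), seqs = seqs)
  coords2 <- segment_coordinates(fam2, set)
  expect_equal(coords2[2, 1, ], c(4, 4, 4))     # only position 1 present
  expect_true(all(is.na(coords2[3, 1, ])))

  # brute-force per-segment mean oracle
  set.seed(42)
  clouds <- lapply(1:4, function(i) matrix(rnorm(24), 8, 3))
  fam3 <- make_family(clouds)
  set3 <- find_segments(data.frame(i = c(2L, 6L), j = c(4L, 7L),
                                   r = c(0.9, 0.9)), length = 8)
  coords3 <- segment_coordinates(fam3, set3)
  for (i in 1:4) for (k in seq_len(nrow(set3))) {
    cols <- set3$start[k]:set3$end[k]
    expect_equal(coords3[i, k, ],
                 colMeans(clouds[[i]][cols, , drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("segment-level analysis reduces to position analysis on singletons", {
  set.seed(43)
  clouds <- lapply(1:12, function(i) matrix(rnorm(15, sd = 1.5), 5, 3))
  fam <- make_family(clouds)
  empty <- data.frame(i = integer(0), j = integer(0), r = numeric(0))
  set <- find_segments(empty, length = 5)   # all singletons
  an <- segment_analysis(segment_coordinates(fam, set), set)

  d <- displacement_matrix(fam, standard_protein(fam), "alpha")
  pos <- displacement_correlation(displacement_covariance(d))
  expect_equal(unname(an$correlation), unname(pos$correlation),
               tolerance = 1e-12)
  expect_equal(unname(an$displacement), unname(d$values), tolerance = 1e-12)

  # symmetric, unit-diagonal correlation
  expect_equal(an$correlation, t(an$correlation), tolerance = 1e-12)
  expect_equal(unname(diag(an$correlation)), rep(1, 5), tolerance = 1e-12)
})

test_that("zero-displacement families give zero segment displacement", {
  co <- matrix(rnorm(18), 6, 3)
  fam <- make_family(rep(list(co), 5))
  set <- find_segments(data.frame(i = 2L, j = 3L, r = 0.8), length = 6)
  an <- segment_analysis(segment_coordinates(fam, set), set)
  expect_true(all(an$displacement == 0))
})

test_that("segments sharing a latent factor are strongly correlated", {
  spec <- family_spec(
    n_proteins = 300, length = 30,
    planted_blocks = list(list(start = 5, end = 9, rho = 0.9, factor = 1),
                          list(start = 20, end = 24, rho = 0.9, factor = 1)),
    base_noise_sd = 0.3, rigid_jitter = FALSE, seed = 101)
  fam <- generate_family(spec)$family
  d <- displacement_matrix(fam, standard_protein(fam), "alpha")
  res <- displacement_correlation(displacement_covariance(d))
  pairs <- high_correlation_pairs(res, 0.60)
  set <- find_segments(pairs, 30)
  an <- segment_analysis(segment_coordinates(fam, set), set)
  multi <- set$id[set$multi]
  expect_gte(length(multi), 2L)
  expect_gt(an$correlation[multi[1], multi[2]], 0.60)
})
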