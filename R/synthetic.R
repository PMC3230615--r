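#' Specification of a synthetic aligned structural family
#'
#' Describes a family to be simulated by [generate_family()]: a conserved
#' helical backbone shared by all members, per-position isotropic Gaussian
#' coordinate noise, designated conserved sequence columns, gap-dominated
#' columns, and "planted" blocks of positions whose displacements are
#' driven by shared latent factors, inducing correlated displacement
#' magnitudes within and between blocks that share a factor.
#'
#' @param n_proteins Number of family members N.
#' @param length Alignment length L.
#' @param conserved_columns Integer vector of columns emitting a fixed
#'   residue with probability `p_cons`.
#' @param p_cons Conservation level in (0, 1] at conserved columns.
#' @param gap_columns Integer vector of columns gapped independently per
#'   protein with probability `p_gap`.
#' @param p_gap Gap probability at gap columns.
#' @param planted_blocks List of blocks, each a list with `start`, `end`
#'   (1-based inclusive column interval), `rho` (latent strength in `[0, 1]`,
#'   the Angstrom scale of the shared displacement per latent standard
#'   deviation) and optional `factor` (integer id; blocks sharing an id
#'   share their per-protein latent draw). Intervals must be disjoint.
#' @param base_noise_sd Per-coordinate Gaussian noise, Angstrom.
#' @param rigid_jitter Apply a random rigid transform to every member
#'   (removed again by superposition)?
#' @param seed Integer seed; all randomness in [generate_family()] flows
#'   from it.
#'
#' @return Object of class `family_spec`.
#' @export
family_spec <- function(n_proteins = 50L, length = 60L,
                        conserved_columns = integer(0), p_cons = 0.95,
                        gap_columns = integer(0), p_gap = 0.5,
                        planted_blocks = list(),
                        base_noise_sd = 0.3, rigid_jitter = TRUE,
                        seed = 1L) {
  stopifnot(n_proteins >= 1, length >= 3,
            p_cons > 0, p_cons <= 1, p_gap >= 0, p_gap <= 1,
            base_noise_sd >= 0)
  chk_cols <- function(x) all(x >= 1 & x <= length)
  if (!chk_cols(conserved_columns) || !chk_cols(gap_columns))
    stop("column indices out of range 1..", length)
  occupied <- integer(0)
  for (b in planted_blocks) {
    if (is.null(b$start) || is.null(b$end) || is.null(b$rho))
      stop("each planted block needs start, end and rho")
    if (b$start < 1 || b$end > length || b$start > b$end)
      stop("planted block interval out of range")
    if (b$rho < 0 || b$rho > 1) stop("block rho must be in [0, 1]")
    cols <- b$start:b$end
    if (any(cols %in% occupied)) stop("planted block intervals must be disjoint")
    occupied <- c(occupied, cols)
  }
  structure(
    list(n_proteins = as.integer(n_proteins), length = as.integer(length),
         conserved_columns = as.integer(conserved_columns), p_cons = p_cons,
         gap_columns = as.integer(gap_columns), p_gap = p_gap,
         planted_blocks = planted_blocks, base_noise_sd = base_noise_sd,
         rigid_jitter = isTRUE(rigid_jitter), seed = as.integer(seed)),
    class = "family_spec"
  )
}

# Idealized alpha-helical backbone: 2.3 A radius, 100 degrees and 1.5 A
# rise per residue.
helix_backbone <- function(L) {
  t <- seq_len(L)
  ang <- t * 100 * pi / 180
  cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * t)
}

random_rotation <- function() {
  # uniform over SO(3) via normalized quaternion
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c + a * d), 2 * (b * d - a * c),
           2 * (b * c - a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d + a * b),
           2 * (b * d + a * c), 2 * (c * d - a * b), a^2 - b^2 - c^2 + d^2),
         3, 3)
}

#' Generate a synthetic aligned structural family
#'
#' Simulates N single-chain structures plus the gapped alignment relating
#' them, per a [family_spec()]. Each member's coordinates are the shared
#' helical backbone plus isotropic Gaussian noise; members of each planted
#' block are additionally displaced along the block's fixed unit direction
#' by `rho * z_i`, where `z_i` is the per-protein draw of the block's
#' latent factor — a common direction guarantees that displacement
#' MAGNITUDES (the quantity the analysis correlates) co-vary. Residues are
#' minimal: a CA atom at the position coordinate plus one offset CB carbon
#' so that residue mass centers are distinct from alpha-carbons.
#'
#' Output is byte-identical across calls with the same spec (seeded,
#' caller RNG state untouched).
#'
#' @param spec A [family_spec()].
#' @return List with `structures` (list of `spca_structure`), `alignment`
#'   (N x L character matrix), `family` (the assembled, un-superposed
#'   `spca_family`), and `truth` (see [ground_truth()]).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, {
    n <- spec$n_proteins
    L <- spec$length
    base <- helix_backbone(L)

    # fixed residue identity per conserved column, cycling a small motif
    motif <- c("G", "A", "D", "N", "P", "W")
    cons_res <- setNames(
      motif[(seq_along(spec$conserved_columns) - 1) %% length(motif) + 1],
      spec$conserved_columns)

    block_dir <- lapply(spec$planted_blocks, function(b) {
      u <- rnorm(3)
      u / sqrt(sum(u^2))
    })
    factor_ids <- vapply(seq_along(spec$planted_blocks), function(k)
      as.integer(spec$planted_blocks[[k]]$factor %||% k), integer(1))
    n_factors <- if (length(factor_ids)) max(factor_ids) else 0L
    latents <- if (n_factors) matrix(rnorm(n * n_factors), n, n_factors)

    seq_mat <- matrix("", n, L)
    for (l in seq_len(L)) {
      if (l %in% spec$conserved_columns) {
        res <- cons_res[as.character(l)]
        hit <- runif(n) < spec$p_cons
        other <- sample(setdiff(AA1, res), n, replace = TRUE)
        seq_mat[, l] <- ifelse(hit, res, other)
      } else {
        seq_mat[, l] <- sample(AA1, n, replace = TRUE)
      }
    }
    gap <- matrix(FALSE, n, L)
    for (l in spec$gap_columns) gap[, l] <- runif(n) < spec$p_gap
    # every protein keeps at least 3 residues by construction guard
    seq_mat[gap] <- "-"

    coord_list <- vector("list", n)
    for (i in seq_len(n)) {
      coords <- base + matrix(rnorm(L * 3, sd = spec$base_noise_sd), L, 3)
      for (k in seq_along(spec$planted_blocks)) {
        b <- spec$planted_blocks[[k]]
        z <- latents[i, factor_ids[k]]
        shift <- b$rho * z * block_dir[[k]]
        cols <- b$start:b$end
        coords[cols, ] <- sweep(coords[cols, , drop = FALSE], 2, shift, `+`)
      }
      coord_list[[i]] <- coords
    }
    # Jitter draws come last so that the pre-jitter family is identical
    # across rigid_jitter on/off for the same seed.
    if (spec$rigid_jitter) {
      for (i in seq_len(n)) {
        rot <- random_rotation()
        coord_list[[i]] <- sweep(coord_list[[i]] %*% rot, 2,
                                 runif(3, -20, 20), `+`)
      }
    }

    structures <- vector("list", n)
    for (i in seq_len(n)) {
      coords <- coord_list[[i]]
      cols <- which(!gap[i, ])
      ca <- coords[cols, , drop = FALSE]
      m <- length(cols)
      # CA plus an offset CB carbon per residue (gives a nontrivial mass center)
      atoms <- data.frame(
        res = rep(seq_len(m), each = 2),
        elesy = "C",
        mass = 12.011,
        x = as.vector(rbind(ca[, 1], ca[, 1] + 1.0)),
        y = as.vector(rbind(ca[, 2], ca[, 2] + 0.5)),
        z = as.vector(rbind(ca[, 3], ca[, 3])),
        stringsAsFactors = FALSE
      )
      structures[[i]] <- structure_record(
        id = sprintf("syn%03d", i),
        resid = aa_one_to_three(seq_mat[i, cols]),
        ca = ca, atoms = atoms
      )
    }
    rownames(seq_mat) <- vapply(structures, `[[`, character(1), "id")
    fam <- build_family(structures, seq_mat)
    list(structures = structures, alignment = seq_mat, family = fam,
         truth = ground_truth(spec))
  })
}

#' Ground truth of a synthetic family specification
#'
#' Machine-readable truth record for parameter-recovery tests: the
#' conserved column set, the gap columns expected to be removed by gap
#' reduction (those whose expected occupancy `1 - p_gap` is below 0.20),
#' and the planted block intervals with their latent factor ids.
#'
#' @param spec A [family_spec()].
#' @return List with `conserved_columns`, `expected_removed_columns`,
#'   `blocks` (data frame: start, end, rho, factor).
#' @export
ground_truth <- function(spec) {
  blocks <- if (length(spec$planted_blocks)) {
    data.frame(
      start = vapply(spec$planted_blocks, function(b) as.integer(b$start), integer(1)),
      end = vapply(spec$planted_blocks, function(b) as.integer(b$end), integer(1)),
      rho = vapply(spec$planted_blocks, function(b) as.numeric(b$rho), numeric(1)),
      factor = vapply(seq_along(spec$planted_blocks), function(k)
        as.integer(spec$planted_blocks[[k]]$factor %||% k), integer(1))
    )
  } else {
    data.frame(start = integer(0), end = integer(0),
               rho = numeric(0), factor = integer(0))
  }
  removed <- spec$gap_columns[(1 - spec$p_gap) < 0.20]
  list(conserved_columns = spec$conserved_columns,
       expected_removed_columns = removed,
       blocks = blocks)
}
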