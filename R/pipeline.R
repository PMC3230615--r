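#' Run the full structural position correlation analysis pipeline
#'
#' Drives every stage in order: read structures, assemble the aligned
#' family, global multi-body superposition, amino-acid frequencies, most
#' conservative positions, refinement superposition on those positions, gap
#' reduction, standard protein, displacement matrices (both alpha-carbon
#' and mass-center), position covariance/correlation, high-correlation
#' pairs, segment construction, and segment-level analysis. All artifacts
#' are written under `out_dir` together with a JSON run manifest.
#'
#' Position labels in output files use ORIGINAL (pre-gap-reduction) 1-based
#' alignment column numbers, so results stay citable against the input
#' alignment; the new-to-original index map is in the manifest.
#'
#' @param structures Either a list of `spca_structure` objects, a character
#'   vector of PDB file paths, or a directory containing `.pdb` files.
#' @param alignment Gapped alignment (any form accepted by
#'   [build_family()]).
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @param chain_map Optional named character vector mapping structure file
#'   stems to chain ids (used only when `structures` are paths).
#' @param cons_threshold Conservation cutoff (default 0.80).
#' @param gap_threshold Occupancy cutoff for gap reduction (default 0.20).
#' @param corr_threshold Correlation cutoff for segment links (default
#'   0.60).
#' @param segment_window Maximum sequence separation of a segment link
#'   (default 4).
#' @param flavor Displacement flavor driving segmentation: `"alpha"`
#'   (default) or `"mass_center"`.
#' @param tol,max_iter Superposition convergence controls.
#'
#' @return Invisibly, a list with all intermediate and final objects:
#'   `family` (reduced, superposed), `freqs`, `conservative`,
#'   `kept_columns`, `standard`, `displacement` (list alpha/mass_center),
#'   `correlation`, `pairs`, `segments`, `segment_analysis`, `reports`.
#' @export
run_pipeline <- function(structures, alignment, out_dir = NULL,
                         chain_map = NULL,
                         cons_threshold = 0.80, gap_threshold = 0.20,
                         corr_threshold = 0.60, segment_window = 4L,
                         flavor = c("alpha", "mass_center"),
                         tol = 1e-4, max_iter = 100L) {
  flavor <- match.arg(flavor)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  structures <- stage("read", {
    if (is.character(structures)) {
      paths <- structures
      if (length(paths) == 1L && dir.exists(paths))
        paths <- sort(list.files(paths, pattern = "\\.(pdb|ent)$",
                                 full.names = TRUE, ignore.case = TRUE))
      lapply(paths, function(p) {
        stem <- sub("\\.(pdb|ent)$", "", basename(p), ignore.case = TRUE)
        ch <- if (!is.null(chain_map) && stem %in% names(chain_map))
          chain_map[[stem]] else NULL
        read_structure(p, chain = ch)
      })
    } else structures
  })
  message("read ", length(structures), " structures")

  family <- stage("build_family", build_family(structures, alignment))
  L0 <- n_positions(family)
  message("family: ", n_proteins(family), " proteins x ", L0, " columns")

  sup1 <- stage("superpose", generalized_superpose(family, tol = tol,
                                                   max_iter = max_iter))
  family <- sup1$family

  freqs0 <- stage("frequencies",
                  position_frequencies(composition_tensor(family)))
  cons <- stage("conservative_positions",
                conservative_positions(freqs0, cons_threshold))
  message(length(cons), " most conservative positions")

  sup2 <- NULL
  if (length(cons) >= 3) {
    sup2 <- stage("refine", refine_on_conservative(family, cons,
                                                   tol = tol,
                                                   max_iter = max_iter))
    family <- sup2$family
  } else {
    message("fewer than 3 conservative positions; refinement skipped")
  }

  red <- stage("reduce_gaps", reduce_gaps(family, freqs0, gap_threshold))
  family <- red$family
  kept <- red$kept_columns
  message(L0 - length(kept), " gap-dominated columns removed; ",
          length(kept), " retained")

  freqs <- stage("frequencies",
                 position_frequencies(composition_tensor(family)))
  p0 <- stage("standard_protein", standard_protein(family, freqs))

  disp <- stage("displacement", list(
    alpha = displacement_matrix(family, p0, "alpha"),
    mass_center = displacement_matrix(family, p0, "mass_center")
  ))
  corr <- stage("correlation", lapply(disp, function(d)
    displacement_correlation(displacement_covariance(d))))
  pairs <- stage("pairs", high_correlation_pairs(corr[[flavor]],
                                                 corr_threshold))
  segs <- stage("segments", find_segments(pairs, length(kept),
                                          segment_window))
  message("K = ", attr(segs, "total_count"), " segments (",
          attr(segs, "multi_count"), " multi-position)")
  seg_coords <- stage("segment_coordinates", segment_coordinates(family, segs))
  seg_an <- stage("segment_analysis", segment_analysis(seg_coords, segs))

  result <- list(
    family = family, freqs = freqs, freqs_initial = freqs0,
    conservative = cons, kept_columns = kept, standard = p0,
    displacement = disp, correlation = corr, pairs = pairs,
    segments = segs, segment_analysis = seg_an,
    reports = list(superpose = sup1$report,
                   refine = if (!is.null(sup2)) sup2$report),
    config = list(cons_threshold = cons_threshold,
                  gap_threshold = gap_threshold,
                  corr_threshold = corr_threshold,
                  segment_window = segment_window, flavor = flavor,
                  tol = tol, max_iter = max_iter)
  )
  if (!is.null(out_dir)) write_artifacts(result, out_dir)
  invisible(result)
}

# Write every pipeline artifact plus the run manifest.
write_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  fam <- result$family
  kept <- result$kept_columns
  pos <- paste0("p", kept)
  ids <- fam$ids

  write_matrix(result$freqs$freqs, ALPHABET, pos, fp("frequencies.tsv"))
  writeLines(as.character(result$conservative),
             fp("conservative_positions.tsv"))
  write_consensus_fasta(result$standard, fp("consensus.fasta"))
  write_standard_protein(result$standard, fp("standard_protein.pdb"),
                         position_labels = kept)
  for (fl in names(result$displacement)) {
    write_matrix(result$displacement[[fl]]$values, ids, pos,
                 fp(paste0("displacement_", fl, ".tsv")))
    write_matrix(rbind(result$displacement[[fl]]$column_means), "mean", pos,
                 fp(paste0("displacement_", fl, "_column_means.tsv")))
    write_matrix(result$correlation[[fl]]$covariance, pos, pos,
                 fp(paste0("covariance_", fl, ".tsv")))
    write_matrix(result$correlation[[fl]]$correlation, pos, pos,
                 fp(paste0("correlation_", fl, ".tsv")))
  }
  pairs_orig <- result$pairs
  if (nrow(pairs_orig)) {
    pairs_orig$i <- kept[pairs_orig$i]
    pairs_orig$j <- kept[pairs_orig$j]
  }
  write_pairs(pairs_orig, fp("high_correlation_pairs.tsv"))
  write_segment_table(result$segments, fp("segments.tsv"), column_map = kept)
  write_matrix(result$segment_analysis$correlation,
               result$segments$id, result$segments$id,
               fp("segment_correlation.tsv"))
  write_matrix(result$segment_analysis$displacement, ids,
               result$segments$id, fp("segment_displacement.tsv"))

  manifest <- list(
    package = "spca",
    version = as.character(utils::packageVersion("spca")),
    config = result$config,
    n_proteins = n_proteins(fam),
    n_columns_initial = length(result$freqs_initial$consensus),
    n_columns_retained = length(kept),
    column_map = kept,
    conservative_positions = result$conservative,
    n_segments = attr(result$segments, "total_count"),
    n_multi_segments = attr(result$segments, "multi_count")
  )
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Reproduce the segment construction from a published pair table
#'
#' Entry point for re-deriving a segment partition from a transcribed
#' table of high-correlation position pairs, without any structures: runs
#' [find_segments()] only and prints the multi-position segments, their
#' member-position count, and the total segment count K.
#'
#' The package ships such a table for the PDZ domain family under
#' `system.file("extdata", "pdz_pair_table.tsv", package = "spca")`
#' (96 retained alignment columns).
#'
#' @param pairs_file Path to a 3-column TSV (i, j, r) as written by
#'   [write_pairs()].
#' @param length Alignment length L.
#' @param threshold Correlation cutoff applied to the table (default 0.60,
#'   strict `>`).
#' @param window Maximum link separation (default 4).
#' @param quiet Suppress the printed report?
#' @return The `spca_segments` object, invisibly.
#' @export
run_table_fixture <- function(pairs_file, length, threshold = 0.60,
                              window = 4L, quiet = FALSE) {
  pairs <- read_pairs(pairs_file)
  pairs <- pairs[pairs$r > threshold, , drop = FALSE]
  segs <- find_segments(pairs, length, window)
  if (!quiet) {
    print(segs)
  }
  invisible(segs)
}
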