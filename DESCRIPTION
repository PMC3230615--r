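Package: spca
Title: Structural Position Correlation Analysis for Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Correlation analysis of per-position structural displacements
    across a superposed protein family. Builds a family "standard protein"
    (consensus sequence plus average structure), computes alpha-carbon and
    residue mass-center displacement matrices of every family member against
    the standard protein, derives position-position displacement correlation
    matrices, organizes correlated contiguous positions into structural
    segments, and repeats the correlation analysis at segment level to map
    putative allosteric communication between segments. Includes generalized
    (multi-body) rigid superposition with a refinement stage restricted to
    the most conservative positions, gap-column reduction for indel-rich
    alignments, and a seedable synthetic-family generator with planted
    correlated blocks for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
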