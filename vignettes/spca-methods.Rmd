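---
title: "Structural position correlation analysis: model and methods"
author: "spca package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural position correlation analysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spca)
```

## The idea

Homologous proteins conserve their fold far more strictly than their
sequence. Within that conserved fold, however, individual family members
drift structurally, and the *pattern* of that drift is informative: when two
regions of the fold displace in a correlated way across the family, they are
mechanically or functionally coupled — in favourable cases this coupling
traces allosteric communication paths that pure sequence covariation cannot
see, because it lives in coordinates rather than in residue identities.

`spca` quantifies this with one elementary observable: the per-position
**displacement** of each family member from the family's average structure.
Everything else — covariance, correlation, segments, the segment
communication map — is classical statistics on top of that observable.

## The model, stage by stage

### Input and the aligned family

The input is a set of single-chain structures and a gapped multiple
alignment whose rows correspond 1:1 to the structures. The alignment is
authoritative for position correspondence: this package deliberately does
*not* compute a structure-based sequence alignment (that step admits many
algorithms and would make results alignment-method-dependent in an
uncontrolled way); users bring the alignment produced by whatever multiple
structure alignment tool they trust. The package's job starts at rigid-body
geometry: `build_family()` scatters α-carbon and residue mass-center
coordinates into alignment columns, with gap cells carrying no coordinates.

Residue mass centers are `Σ m·x / Σ m` over each residue's atoms, with
masses from a built-in element table; they give a second displacement flavor
that is sensitive to side-chain rearrangement, not only backbone motion.

### Generalized superposition

Displacements are only meaningful in a common frame. The multi-body
superposition iterates: (i) average the coordinates at each usable column
(non-gap in ≥ 2 members), (ii) Kabsch-fit each member onto that mean using
its own non-gap cells, (iii) re-average; it stops when the pooled RMSD
improves by less than `tol` or after `max_iter` rounds. The objective is
non-increasing, so the trace is a built-in sanity check. Defaults are
`tol = 1e-4` Å — far below the 3-decimal coordinate precision of PDB files —
and `max_iter = 100`, which in practice is never reached. The initial
reference is the first member's coordinates, which makes runs deterministic;
the converged mean is unique only up to a global rigid motion, which is
irrelevant because displacements are distances.

The fit of each member is applied to *all* of its coordinates (both
flavors, all columns), so superposition can never distort internal geometry
— a property the test suite asserts at 1e-9 Å.

### Conservation and the second superposition

From the composition tensor (one-hot over the 21-symbol alphabet: gap plus
the 20 amino acids in alphabetical one-letter order) come the per-column
frequencies. A column is **most conservative** when its top amino-acid
frequency strictly exceeds 0.80. Two conventions are fixed here because the
quantities feed thresholds: consensus ties between amino acids break
alphabetically, and a gap can be the consensus (on a strict majority) but a
gap-consensus column can never be conservative — the conservative set seeds
the structural core, and a gap has no structure.

The second superposition repeats the generalized fit restricted to the
conservative columns, minimizing RMSD over the family's structural core so
that displacement signal concentrates in the genuinely variable regions
rather than being smeared by frame error.

### Gap reduction

Indel-dominated columns would distort the statistics (their displacement
sample is tiny and unrepresentative), so columns with 20-amino-acid
occupancy `q_l` strictly below 0.20 are deleted. `q_l` is computed as an
exact count ratio, not as `1 − f_gap`: the subtraction loses one ulp and
would silently break the strict-inequality semantics at `q_l = 0.20`
exactly. All downstream artifacts are labelled with original column numbers
through the retained-column index map, so results remain citable against
the input alignment.

### Standard protein and displacements

The standard protein `P⁰` has the consensus residue and the unweighted mean
coordinate of the non-gap members at each column. Gap cells are excluded
from the mean and left missing in the displacement matrices — imputing
coordinates for a residue that does not exist would manufacture signal.
Displacements are plain Euclidean distances to `P⁰`, one matrix per
coordinate flavor.

### Correlation and segments

Covariance uses the sample divisor (`N_ij − 1`) over pairwise-complete
observations, with column means taken over each column's present cells and
per-pair support recorded in `valid_pairs`; pairs or columns supported by
fewer than 3 members are set missing rather than reported on vapors. The
correlation — the thresholded quantity — is divisor-convention-free.

Segments are built from the pairs with `r > 0.60`, using only links of
sequence separation ≤ `window` (default 4). The window encodes the notion
that a segment is a *contiguous* unit: a strong correlation between distant
positions is exactly the allosteric signal one wants to read from the final
map, not a license to fuse remote regions into one segment. Connected
components are closed to their full interval — an interior position without
a qualifying pair of its own still belongs to the unit that surrounds it —
and touching intervals merge. Every remaining column is a singleton
segment, so segments always partition the columns and
`K = L − (members of multi segments) + (number of multi segments)`.

Segment coordinates are member-position means per protein; the
displacement → covariance → correlation machinery then reruns unchanged at
segment level, giving the K × K communication map. For singleton segments
this reduces exactly (to 1e-12) to the position-level result, which the
suite checks.

## The synthetic generator

`generate_family()` emulates the statistical structure the analysis
assumes, with known ground truth:

- a shared backbone (an idealized α-helical curve: 2.3 Å radius, 100°/1.5 Å
  per residue) so superposition has a realistic, non-degenerate shape;
- per-position isotropic Gaussian noise (default 0.3 Å, the scale of
  coordinate scatter in well-resolved crystal-structure families);
- designated conserved columns emitting a fixed residue with probability
  `p_cons`, and gap columns gapped per member with probability `p_gap`;
- planted blocks displaced along a fixed random unit direction by
  `rho · z_i`, where `z_i` is a per-member standard-normal latent draw;
  blocks sharing a latent factor co-displace. The common direction matters:
  displacements are norms, and only a shared direction guarantees that
  displacement *magnitudes* correlate, which is what the analysis measures;
- optionally a random rigid transform per member, which the superposition
  must remove. Jitter draws are taken after all noise draws, so the same
  seed yields the identical pre-jitter family with jitter on or off — that
  is what makes "superposition removes rigid motion" testable as an exact
  statement.

What the generator does *not* emulate: real side-chain geometry and packing
(residues are a CA atom plus one offset carbon), correlated *sequence*
evolution, alignment errors, and non-rigid (hinge/shear) family motion.
Passing the recovery tests therefore shows the statistical machinery is
sound, not that any particular biological family will yield clean segments.

## Numerical choices and degenerate inputs

- Kabsch fits require ≥ 3 non-collinear points; collinearity is detected on
  the second singular value and rejected, and improper optima (reflections)
  are corrected to proper rotations.
- Superposition requires ≥ 3 masked columns with ≥ 2 non-gap members; a
  single-member family is returned unchanged.
- Zero-variance displacement columns get missing correlations (never NaN),
  and their diagonal is missing rather than 1.
- All thresholds are strict in the documented direction: conservation
  `> 0.80`, occupancy deletion `< 0.20`, correlation `> 0.60`.
- Consensus gap at a retained column is written as residue `UNK` in the
  standard-protein PDB.
- TSV matrices are written with 17 significant digits (round-trippable).

## Problem sizes used in the test suite

The suite exercises the full pipeline on synthetic families of up to 300
members × 50 columns (the latent-factor recovery study, 20 seeds) and on
the packaged PDZ pair table (96 columns); unit tests use desk-scale
fixtures (5–20 members) against independently coded oracles — a quaternion
(Horn) superposition, double-loop covariance/Pearson, counting and
brute-force scan oracles — rather than against the implementation itself.

## Known limitations

- Rigid-body superposition only; families with large hinge motions will
  show that motion as displacement at all moving positions rather than
  isolating the hinge.
- The alignment is trusted as given; misaligned columns become spurious
  displacement and correlation.
- No significance model for `r`: the 0.60 cutoff is a fixed operating
  point, and no multiple-testing control is applied.
- Correlation of displacement *magnitudes* discards direction: two regions
  moving with correlated amplitude but unrelated directions are still
  reported as coupled.
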