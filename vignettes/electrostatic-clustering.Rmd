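---
title: "Clustering pMHC complexes by electrostatic potential: model and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering pMHC complexes by electrostatic potential: model and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the scientific model behind `mepsim`, the defaults
and units of every stage, and the numerical conventions that make runs
reproducible to the byte. It is written for readers who want to understand
*why* the pipeline gives the answer it gives, not just how to call it.

## The scientific question

T-cell receptors engage the composite surface of a peptide bound to an MHC
class I molecule. Cross-reactivity — one receptor recognizing several
distinct pMHC complexes — is better predicted by the physical resemblance of
that surface than by peptide sequence identity. The dominant long-range
contribution to that resemblance is the molecular electrostatic potential
(MEP) above the binding cleft. `mepsim` therefore asks: *for a set of pMHC
structures, which subsets have mutually similar cleft potentials, and is
that grouping statistically solid?*

## Pipeline stages, defaults, and units

All lengths are in Ångström, charges in elementary charges (e), potentials
in kcal mol⁻¹ e⁻¹.

1. **Parsing and preprocessing.** Standard fixed-column PDB `ATOM`/`HETATM`
   records are read; alternate locations other than `' '`/`'A'` are
   dropped. `preprocess_structure_file()` rewrites a file to a
   whitespace-separated nine-field form (record, serial, atom, residue,
   chain, residue number, x, y, z) and is idempotent.
2. **Charge assignment.** A table keyed by (residue, atom) assigns formal
   side-chain charges (Asp/Glu carboxylate oxygens −0.5 each, Lys NZ +1,
   Arg NH1/NH2 +0.5 each, C-terminal OXT −1, N-terminal N +1) and van der
   Waals radii by element. The table can be extended per run.
3. **Superposition.** Each structure is least-squares fitted to a common
   reference with the Kabsch SVD algorithm (reflection-corrected), pairing
   Cα atoms by (chain, residue number, atom name). **The fit is applied
   twice**; the second pass starts from the first pass's frame, so small
   pairing-order artifacts cannot accumulate, and both RMSDs are reported.
4. **Focus region.** A cylinder (default radius 40, length 33) is placed at
   the peptide centroid with its axis along the normal of the least-squares
   plane through the peptide Cα atoms. The peptide chain is detected as the
   shortest chain of 8–11 residues.
5. **Molecular skin.** For each complex, lattice points *g* with
   0 < min_i( |g − r_i| − (R_i + σ) ) ≤ δ are kept, with probe radius σ = 1
   and thickness δ = 25. The lower bound is strict (points on the
   solvent-accessible surface are excluded), the upper bound closed.
6. **Potential.** A screened-Coulomb (Debye–Hückel) sum on a uniform
   dielectric (default ε = 78.4, ionic strength 0.05 mol/L, 298.15 K) over a
   shared lattice (default spacing 1, padding 5 around the cylinder).
7. **Similarity.** The Hodgkin index
   SI = 2Σφ_aφ_b / (Σφ_a² + Σφ_b²), evaluated per pair on
   skin(a) ∩ skin(b) ∩ cylinder; distance D = √(2 − 2·SI).
8. **Clustering and support.** Complete linkage on the correlation distance
   between SI-matrix columns; multiscale bootstrap (scales 0.5–1.4 in steps
   of 0.1, 1000 replicates each) gives each internal node an approximately
   unbiased (AU) p-value. Nodes with AU **strictly greater than** 0.95
   (root excluded) are flagged.

## Why a screened-Coulomb potential

Production MEP comparisons often use a Poisson–Boltzmann (PB) solver with a
molecular dielectric boundary. `mepsim` instead evaluates an analytic
Debye–Hückel sum. Three reasons:

- The comparison statistic is evaluated on a skin that starts *outside* the
  solvent-accessible surface, where both models are dominated by the same
  charge geometry and decay; the ranking of pairwise similarities is driven
  by which charges sit where, not by boundary effects.
- The analytic form makes every value unit-testable against hand
  calculations (a single unit charge gives exactly 332.0637/(ε·d)) and
  removes solver-convergence nondeterminism.
- The grid interface (`mep_grid_spec`, `compute_potential_grid()`) is
  model-agnostic: a PB solver producing values on the same lattice can be
  substituted without touching the similarity or clustering code.

The trade-off is that absolute potential magnitudes near the surface are not
quantitative; conclusions should be read as *relative* similarity, which is
all the clustering consumes.

## Numerical conventions

These choices exist so that identical inputs and seeds give byte-identical
outputs on any platform:

- **Singularity floor.** Atom–point distances are clamped below at 0.5 Å.
  Affected points lie inside the solvent-accessible surface and are always
  masked out of the comparison; the clamp only keeps intermediate values
  finite.
- **Boundary conventions.** The skin is open at the surface, closed at the
  outer thickness; cylinder membership is closed on the surface (radius and
  caps included, with a 1e−9 absolute tolerance).
- **SI clamping.** Before D = √(2 − 2·SI), SI is clamped to [−1, 1] with a
  1e−9 tolerance to absorb round-off.
- **Linkage tie-breaking.** When two merge candidates have exactly equal
  complete-linkage heights (within 1e−15), the pair whose sorted leaf-label
  sets are lexicographically smallest is merged first. `hclust` leaves tie
  order implementation-defined; this rule makes the tree a pure function of
  the distance matrix and labels.
- **Collinear peptides.** If the peptide Cα atoms are (numerically)
  collinear, the cleft plane is undefined; the axis falls back to the
  least-squares plane normal of the whole structure. The axis sign is fixed
  by making its first nonzero component positive.
- **Bootstrap seeding.** Every (scale, replicate) pair seeds the RNG
  independently via a deterministic function of (seed, scale index,
  replicate), so increasing `nboot` extends rather than reshuffles the
  replicate stream, and results are independent of iteration order. The
  caller's `.Random.seed` is saved and restored.
- **Degenerate AU fits.** A node resampled in every replicate at every scale
  gets AU = 1; never resampled, AU = 0. Otherwise AU comes from a weighted
  least-squares fit of qnorm(1 − BP) against √r and 1/√r across scales; a
  node with fewer than two usable scales gets `NA` with a warning.
- **Flag-to-partition rule.** Flagged nodes can nest. Each complex is
  assigned to its **largest** flagged ancestor (smallest would split a
  supported group by its even-better-supported subgroups); complexes under
  no flagged node become singletons.

## What the synthetic fixtures emulate

Real pMHC structures are large and their "true" cross-reactivity groups are
unknown, so the package ships a generator with planted ground truth:

- a shared, electrically neutral 8 × 8 scaffold slab standing in for the
  MHC platform beneath the cleft;
- nine colinear charged pseudo-residues standing in for peptide side chains,
  with per-position charges encoded in residue names and resolved through a
  generated charge table — exercising the same assignment path as real data;
- groups defined by orthogonal, disjoint-support charge motifs of magnitude
  `motif_separation`, and within-group variation from seeded Gaussian
  coordinate jitter (coordinates rounded to 3 decimals, matching PDB
  precision, so regeneration is byte-identical).

These fixtures are *not* physically realistic; they are controlled inputs
whose correct answer is known, so every stage from parsing to AU flagging
can be verified end to end. The package's own validation uses a 3-group ×
3-member benchmark (separation 1 e, jitter 0.2 Å) at a reduced cylinder
(20 × 16) and 2 Å spacing — sized so the full 1000-replicate bootstrap runs
in well under a minute while remaining far from trivial (between-group SI
means around 0.6, not 0).

## Open choices and their defaults

- **Clustering input.** `cluster_input = "si"` (default) bootstraps the SI
  matrix columns; `"d"` uses the distance matrix instead. Correlation
  distance makes the two nearly equivalent; SI is the default because it is
  the directly computed quantity.
- **Multipole prescreen.** `prescreen_similarity()` compares monopole +
  dipole truncations on a spherical shell — useful for triaging large sets
  before the grid stage. Its matrix is reported in the run object but is
  advisory only; the clustering always uses grid-based indices.
- **Double fit.** The superposition is always run twice. With exact Cα
  pairing the second pass is a numerical no-op (tested to be a fixed point);
  it is kept because it is cheap and makes the pipeline robust to
  marginally inconsistent pairings in real files.

## Limitations

- The uniform-dielectric screened-Coulomb model omits the low-dielectric
  protein interior; near-surface magnitudes are qualitative.
- Charge assignment is formal-charge bookkeeping, not a protonation-state
  calculation; unusual residues default to zero charge (configurable to an
  error).
- The pipeline compares *structures you supply*; it does not model peptide
  loading, conformational ensembles, or TCR docking geometry.
- AU p-values test the reproducibility of tree edges under resampling of
  grid features, not a generative model of pMHC space; treat flagged
  clusters as candidates for experimental follow-up, not proof of
  cross-reactivity.
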