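---
title: "Aligning ligand-bound structure series with density fragments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning ligand-bound structure series with density fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligalign)
```

## The problem

Iterative structure-based drug design generates series of structures of
one macromolecular target bound to many different small molecules.
Analyzing such a series requires three recurring operations: bringing
all structures into one frame, isolating each binding site (including
contributions from crystal packing), and keeping the experimental
electron density attached to each ligand so that the reliability of
every modelled pose can be judged by eye. `ligalign` performs these
steps headlessly from a plain-text instruction card and writes standard
files plus a viewer script, so the result is portable and reproducible
rather than locked into one graphics session.

## Superposition model

Entries in a series are the *same protein* — different ligands,
sometimes different crystal forms. This assumption licenses a
sequence-guided correspondence instead of sequence-independent 3D
alignment: residues of the mobile and reference chains are paired by
global alignment of their three-letter residue codes (match +1,
mismatch −1, gap −2), and a representative atom per paired residue (CA
for amino acids, C1′ then P for nucleotides, otherwise the first atom)
enters a least-squares rigid fit.

The fit is the Kabsch solution: with paired, centered coordinate sets
$A$ and $B$ and SVD $A^{\mathsf T}B = U D V^{\mathsf T}$, the optimal
proper rotation is
$R = V\,\mathrm{diag}(1, 1, \det(VU^{\mathsf T}))\,U^{\mathsf T}$; the
determinant correction excludes reflections, so mirror-image inputs
still produce a physical rotation (with a large residual instead). The
fit is iterated with outlier rejection: after each cycle, pairs whose
post-fit deviation exceeds $\max(2\,\mathrm{rmsd},\ 2\,\text{Å})$ are
discarded and the fit repeated, for at most 5 cycles, never dropping
below 3 pairs. The 2× multiplier, the 2 Å floor and the cycle cap are
this package's choices: the floor stops the rejection from eating into
the well-fitted core once the RMSD is sub-Ångström, and five cycles are
ample for the rigid-plus-outliers geometry this emulates (flexible
loops, lattice-deformed termini). Refinement-based viewer commands
behave similarly but publish no exact parameters, so no equivalence
with any particular program is claimed.

Degenerate inputs fail loudly: fewer than 3 pairable residues or a
collinear representative-atom set is an error, not a silent identity.

## Crystallographic symmetry and truncation

Space-group operators come from a bundled table of the Sohncke groups
(the 65 chiral-compatible groups, with common alternative settings),
keyed by the Hermann–Mauguin symbol as printed on `CRYST1` records with
spacing and case normalized. Centrosymmetric groups are deliberately
absent — chiral macromolecules cannot crystallize in them — and an
unknown symbol is a loud error suggesting a direct map instead. Each
operator is stored as a coordinate triplet (e.g. `-x+1/2,-y,z+1/2`) and
parsed into a fractional rotation and translation.

Symmetry mates are enumerated as every operator image of every residue
combined with lattice translations of −2..2 cells per axis; an image is
kept when any of its atoms lies within the contact radius of any ligand
atom. The contact radius defaults to the truncation radius (4.5 Å): a
mate matters exactly when it would survive truncation. The −2..2 range
is generous for any cell larger than the cutoff; the test suite checks
it against a brute-force enumeration at the same range on randomized
toy crystals in five space groups. Mates receive fresh chain
identifiers (lowercase letters, then digits, skipping ids already in
use) in a deterministic order.

Truncation keeps the ligand plus every residue — protein, water, other
heteroatoms, symmetry mates — with at least one atom within 4.5 Å of at
least one ligand atom. Residues are kept or dropped whole. Waters are
treated as residues throughout: structured waters are part of the
binding-site picture. Truncation is idempotent by construction.

## Density handling

Weighted 2Fo–Fc coefficients are read from MTZ files, preferring the
`FWT`/`PHWT` column pair and falling back to `2FOFCWT`/`PH2FOFCWT`;
when both exist, the first pair wins. Synthesis expands the reflections
to P1 (applying $F(h R) = F(h)e^{-2\pi i\,h\cdot t}$ for each operator,
then Hermitian completion) and evaluates
$\rho(x) = V^{-1}\sum_h F(h)e^{-2\pi i\,h\cdot x}$ by FFT on a
full-cell grid. The grid satisfies two constraints: spacing at most
$d_{\min}/\text{sample\_rate}$ per axis (default sample rate 3), and at
least $2\max|h_i|+1$ divisions so no reflection aliases — under these
the FFT equals direct summation to machine precision, which the tests
assert pointwise and via the Parseval identity
$\mathrm{var}(\rho) = V^{-2}\sum_{h\neq 0}|F(h)|^2$. Sample rates below
2 are refused as sub-Nyquist.

The map mean and RMS ("sigma") are computed over the **full unit cell**
before any extraction, and travel with every fragment. Consequence: a
fragment contoured at 1.0 after sigma scaling shows the same surface a
full-map viewer would draw at its 1 σ level — scaling on the fragment's
own statistics would make contours incomparable across entries.

Fragments are the minimal axis-aligned subgrid (parent spacing and
orientation) containing all points within the extraction radius of the
selection — 3 Å around the ligand in the pipeline, 9 Å in the
standalone extractor — with periodic wrapping when the parent covers a
full cell. Rigid transformation into the reference frame resamples
trilinearly onto an axis-aligned Cartesian grid covering the
transformed bounding box, at a per-axis spacing equal to the dominant
transformed step; node-coincident cases (identity, integer-voxel
shifts, 90° axis rotations) therefore stay exact. Points falling
outside a non-periodic source are zero-filled and reported as a
coverage fraction rather than guessed.

Mesh generation itself (the 1 σ contour carved within 1.8 Å of the
ligand) is delegated to the emitted viewer script's `isomesh ... carve`
directive: triangulating in core would only duplicate what every viewer
does better, while the carve radius and level remain recorded,
adjustable scene metadata.

## Scene semantics

The reference is resolved with a strict precedence: an existing run's
reference, else the card's `#REF` (file plus optional chain, first
chain by default), else the first entry's structure. It is always
reduced to a single chain. Objects are grouped exactly as the card
orders them; an entry whose display name already exists is skipped, so
re-running a card is idempotent; the names `reference` and
`map_objects` are reserved. Colors are drawn without replacement from a
fixed 20-name palette by a seeded generator (recycling when exhausted),
and each mesh inherits its object's color. One failing entry is logged
in the JSON report and skipped; the run continues. The report carries
the full 4×4 transform, RMSD, pair counts, mate counts, residues kept
and map statistics per entry, and contains no timestamps, so identical
inputs give identical bytes.

Session persistence is a re-runnable script plus standard-format files
rather than a binary session: the pipeline stays testable headlessly
and the outputs remain readable by any viewer generation.

## The synthetic-fixture generator

`make_complex()` builds an ideal-geometry polyalanine helix (5 atoms
per residue) plus a single 5-atom heteroligand inside a stated cell —
by default 8 residues in a 30×34×38 Å orthorhombic P 2₁2₁2₁ cell, a
deliberately typical small protein crystal setting. Structure factors
come from a single-Gaussian-atom model,
$F(h)=\sum_j Z_j e^{-B|s|^2/4} e^{2\pi i\,h\cdot x_j}$ with B = 15 Å²
over the symmetry-expanded cell content, reduced to one representative
per symmetry orbit, to d_min = 4 Å (411 reflections for the default
crystal — small enough that tests re-sum them directly). The fixture
set used end-to-end comprises a reference, an identical entry with MTZ
coefficients, a rigidly moved copy, and the same complex in a
monoclinic P 1 2₁ 1 cell.

What the generator emulates: realistic cells and space groups, helical
protein geometry, maps that peak at atoms, crystal forms that differ by
a rigid motion. What it does not: scattering-factor tables, bulk
solvent, measurement noise, conformational change, partial occupancy,
alternate conformers beyond the altloc reader path. Passing tests
therefore demonstrate the geometric and crystallographic machinery —
alignment, symmetry, truncation, synthesis, resampling, scaling — not
robustness to experimental pathology (radiation damage,
twinning, poor phases), which no synthetic fixture can certify.

## Numerical choices and degeneracies

* Rotations are validated orthonormal with det +1 at 1e-8 on
  construction.
* Altlocs collapse to the highest-occupancy conformer (tie: first
  encountered) at load time, keeping distance logic single-valued.
* Trilinear interpolation snaps indices within 1e-9 of a node to the
  node, so exact cases are exact.
* A constant ("flat") map cannot be sigma-scaled and errors; an empty
  ligand selection, an unknown chain, and a selection outside a
  non-periodic map all raise labeled errors naming the offending input.
* Problem sizes: the shipped tests use 3–20-residue fixtures,
  ≤ 500-reflection coefficient sets and ≤ 64³ grids; the brute-force
  oracles (all-pairs distance scans, direct Fourier sums, exhaustive
  alignments at n ≤ 12) run in seconds at these sizes, which is what
  makes oracle-equality testing practical.

## Known limitations

* Ligand selections are a single chain plus an integer residue range:
  no insertion codes, no negative residue numbers, no multi-chain
  ligands.
* Sequence-guided pairing presumes the aligned chains are the same
  protein; remote homologs would need a 3D-alignment front end.
* MTZ support is limited to the two 2Fo-Fc label conventions by
  design; anything else (e.g. `FP/SIGFP`-only files) is rejected with
  the column list so the user knows what was found.
* Non-Sohncke space groups and BIOMT assembly generation are out of
  scope.
* Written mmCIF is a minimal canonical `atom_site` loop, not a full
  PDBx dictionary rendering.

## A worked run

```{r example, eval = FALSE}
dir <- tempfile()
card_path <- cmd_make_fixtures(file.path(dir, "fx"), seed = 1)
st <- cmd_run(card_path, file.path(dir, "run"), seed = 1)
scene <- attr(st, "scene")
glance(scene)              # 3 objects, 2 groups, 1 mapped
tidy(scene)                # per-entry rmsd, residues kept, colors
plot_alignment_quality(scene)   # needs ggplot2
```
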