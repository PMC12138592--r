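# ligalign

Structure-based drug design produces *series* of closely related
protein–ligand complexes — dozens to hundreds of crystal (or cryoEM)
structures of one target soaked or co-crystallized with different
fragments and lead compounds. Comparing them means answering the same
questions over and over: where exactly does each ligand sit once all
structures share one frame, which contacts come from crystal packing
rather than the biological site, and does the experimental density
actually support the modelled pose?

`ligalign` is a headless R pipeline that automates that bookkeeping for
structural biologists and medicinal chemists. From a plain-text input
card listing the series, it:

1. **superposes** every structure onto a common single-chain reference —
   residues are paired by global sequence alignment (match +1,
   mismatch −1, gap −2 on three-letter codes) and fitted by the Kabsch
   least-squares rotation
   `R = V diag(1,1,det(VUᵀ)) Uᵀ` (with `UDVᵀ` the SVD of the paired
   covariance matrix, the determinant correction excluding reflections),
   iterated with outlier rejection (pairs beyond `max(2·rmsd, 2 Å)`
   dropped, ≤ 5 cycles, never below 3 pairs);
2. **expands crystallographic symmetry**: space-group operators from a
   bundled Sohncke-group table generate every lattice image of the model
   within −2..2 cells, and images contacting the ligand are kept as
   explicit symmetry-mate chains — lattice contacts at a binding site
   are easy to mistake for biology, so they are made visible;
3. **truncates** each aligned entry to the binding site: the ligand plus
   every residue (protein, waters, mates) with an atom within 4.5 Å;
4. **carries the experimental density along**: weighted 2Fo–Fc map
   coefficients (MTZ columns `FWT/PHWT`, or `2FOFCWT/PH2FOFCWT`) are
   turned into a real-space map by inverse Fourier synthesis
   `ρ(x) = (1/V) Σ_h F(h) e^{iφ(h)} e^{−2πi h·x}` over the
   symmetry-expanded, Hermitian-completed reflection set; direct
   CCP4/MRC maps (cryoEM, Polder) are read as-is. A fragment within 3 Å
   of the ligand is cut out, moved into the reference frame with the
   superposition transform (trilinear resampling), and sigma-scaled so
   that a contour at 1.0 is the conventional "1 σ" level of the parent
   map;
5. **emits a reconstructable scene**: per-object PDB files and CCP4
   fragments, a molecular-viewer script that rebuilds the grouped,
   colored scene with one mesh per mapped object (1 σ, carved at 1.8 Å
   around the ligand), and a machine-readable JSON run report.

A synthetic-fixture module builds toy protein–ligand crystals, map
coefficients and maps from scratch, so the entire pipeline is testable
offline with no downloads.

## The input card

```
#REF ref.pdb A                 ← optional reference (file + chain)
#G siteA                       ← opens a display group
e1.pdb e1.mtz L 1 lig_mapped A ← coords [map] ligand-chain resno[-range] name [align-chain]
e2.pdb L 1 lig_moved A
#G siteB
e3.pdb L 1 lig_altform A
```

Residue ranges accept `100` or `100-102` (hyphen or en-dash); the second
token is a map only when its extension is `.mtz`, `.ccp4`, `.mrc` or
`.map`; any other `#` line is a comment; relative paths resolve against
the card's own directory.

## Worked example

```r
library(ligalign)
card_path <- cmd_make_fixtures("fixtures", seed = 1)   # synthetic series
st <- cmd_run(card_path, "run", seed = 1)
scene <- attr(st, "scene")
scene
#> <ligand_scene> 3 object(s) in 2 group(s)
#>   siteA: lig_mapped, lig_moved
#>   siteB: lig_altform
tidy(scene)[, c("object_name", "group", "status", "rmsd", "n_residues",
                "has_map", "color")]
#> # A tibble: 3 × 7
#>   object_name group status     rmsd n_residues has_map color
#>   <chr>       <chr> <chr>     <dbl>      <int> <lgl>   <chr>
#> 1 lig_mapped  siteA ok     1.15e-15          4 TRUE    yellow
#> 2 lig_moved   siteA ok     4.51e- 4          4 FALSE   slate
#> 3 lig_altform siteB ok     1.15e-15          4 FALSE   green
```

`lig_mapped` is byte-identical to the reference, so its superposition
RMSD is numerically zero; `lig_moved` was deposited in a rotated frame
and aligns back at 4.5×10⁻⁴ Å (PDB coordinate precision); `lig_altform`
comes from a different crystal form (monoclinic P 1 2₁ 1 instead of
P 2₁2₁2₁). Each trimmed object keeps 4 residues: the ligand and its
4.5 Å shell. The run directory then contains `reference.pdb`, one PDB
per object, `lig_mapped_map.ccp4`, `report.json` and `scene.pml`, whose
mesh directive reads

```
isomesh lig_mapped_mesh, lig_mapped_map, 1.0, (lig_mapped and chain L and resi 1), carve=1.8
```

Re-running the same card into the same directory adds nothing: objects
already present are skipped by display name, exactly like feeding a new
card into an existing viewer session.

A standalone extractor is also provided (default radius 9 Å):

```r
cmd_extract_map("e1.mtz", "e1.pdb", chain = "L", res_lo = 1,
                out_path = "site.ccp4")
```

A thin shell wrapper for all three commands is installed at
`inst/scripts/ligalign`.

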