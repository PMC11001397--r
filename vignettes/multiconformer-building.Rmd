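---
title: "Building multi-conformer models from dihedral density scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building multi-conformer models from dihedral density scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiconf)
```

## The model

A crystal structure refined as a single conformer is a population average.
When a side chain occupies two or three rotamers, the minor states leave
systematic density along the circle swept by each χ dihedral's moving
atom. `multiconf` turns that observation into an explicit procedure: scan
each χ through 360°, read the σ-scaled map at the moving atom, and treat
peaks in the resulting circular trace as evidence for rotamer wells.

The method rests on three assumptions worth stating explicitly:

* **The input model is near deposition quality.** Sampling is done with
  all other dihedrals held at their modeled values, so a badly placed
  side chain scans the wrong circle. Alternate conformations in the input
  are stripped first (highest occupancy wins, ties to the alphabetically
  earliest altloc) to give a defined single-conformer starting point.
* **Density peaks map onto ideal rotamers.** Peak angle tuples are only
  built when every χ is within a tolerance (default 30°) of a library
  rotamer's mean χ angles. Built conformers use the *ideal library
  means*, not the detected peak angles: peak positions carry
  interpolation and model error, and downstream refinement is expected to
  polish the geometry. The detected angles are kept in the decision
  report for transparency.
* **σ units are meaningful.** All thresholds are in units of the map's
  RMS deviation about its mean (the crystallographic σ; the population
  statistic, not the sample one — a grid holding the two values {0, 2}
  scales exactly to {−1, +1}).

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `threshold` | 0.3 | σ | minimum trace density for a peak |
| `minSeparation` | 30 | degrees | circular non-maximum suppression radius |
| `tolerance` | 30 | degrees | per-χ rotamer-matching tolerance |
| `maxAlts` | 3 | conformers | per-residue cap on built alternates |
| `mode` | `ALL` | — | duplicate whole residue vs CA-outward |
| `step` | 5 | degrees | trace sampling step (must divide 360) |

The suppression radius deliberately equals the matching tolerance: two
peaks closer than 30° would necessarily map into the same rotamer well,
so only the taller is kept. The signal of a candidate is the sum over χ
of the peak's relative intensity (height divided by the trace's tallest
peak), bounded by the χ count; altloc letters are assigned in decreasing
signal order, so altloc A is always the best-supported state. Occupancies
are initialized to the neutral 1/n split — refinement, not this package,
estimates populations — rounded to PDB precision with the first conformer
absorbing the remainder so each group sums to exactly 1.00.

Density can come from a CCP4/MRC map, from MTZ map coefficients
(synthesized by FFT with the crystallographic convention
ρ(x) = (1/V) Σ F exp(−2πi h·x), on a grid no coarser than resolution/4),
or from a pre-computed trace CSV. When both a map and an MTZ are given
the map file wins, since it needs no synthesis choices.

## Numerical choices

* **Interpolation** is trilinear over the 8 surrounding grid nodes after
  fractionalizing the point and wrapping modulo 1 (lattice translation).
  It is exact at grid nodes and cheap enough to evaluate 72 positions per
  χ. Tricubic schemes would smooth sub-grid detail but change no peak
  assignment at the working resolutions; maps must cover a full unit
  cell, and partial-cell maps are rejected rather than mis-wrapped.
* **Peak detection** operates natively on the circle (no padding), so a
  bump straddling the 0°/360° seam yields exactly one peak. Plateaus
  report their leftmost sample; suppression is greedy tallest-first with
  ties to the smaller angle. Every rule is deterministic, and the whole
  detector is tested sample-for-sample against a brute-force oracle.
* **Symmetric terminal groups** (Phe/Tyr χ2, Asp χ2, Glu χ3) are compared
  modulo 180°, the standard convention; otherwise genuine candidates near
  θ + 180° would be rejected. This is switchable (`symmetryAware`).
* **Chi kinematics** rotate the moving atom and every atom distal to the
  rotated bond as a rigid body (Rodrigues rotation about the bond axis),
  so bond lengths and angles are bit-preserved and only dihedrals change.
  Branched residues measure density at the IUPAC-priority branch atom
  (Val CG1, Thr OG1, Ile CG1), the Ringer convention. Hydrogens are
  ignored; residues missing χ-defining atoms are skipped with a warning
  rather than rebuilt, consistent with the near-deposition-quality
  assumption. Whether upstream samplers also scan the second branch atom
  is unknown to us; measuring one documented branch is a stated choice,
  not a claim of equivalence.

## The synthetic fixtures

`generateFixture()` builds an extended peptide (NeRF construction from
standard internal coordinates, φ = ψ = ω = 180°), plants chosen rotamers
at chosen occupancies as altloc conformers, and computes the ensemble
density as occupancy-weighted isotropic Gaussians (amplitude proportional
to the element's electron count) on a padded orthogonal P1 grid, with
optional seeded white noise added before σ-scaling. Identical spec and
seed give bit-identical fixtures.

Two calibration choices matter:

* **Gaussian width 0.5 Å.** This is the effective atomic width of a
  well-ordered atom at ~1.5 Å resolution, the regime the method targets.
  Substantially wider atoms are not just unrealistic — they smear
  backbone and CB density onto the moving atom's sampling circle until
  phantom local maxima appear in unoccupied rotamer wells, and a 100%
  single-state serine stops being recovered as a single state. At 0.5 Å
  the trace baseline away from planted states drops to ~0.04σ.
* **Box padding 4 Å** (≥ 2× the Gaussian width on every side) keeps the
  periodic images from leaking density back onto the peptide.

What the fixtures do **not** emulate: real scattering factors and B-factor
heterogeneity, solvent and neighbor-molecule density, phase error, and
series-termination ripple. Passing the fixture suite therefore shows the
*pipeline logic* is right — sampling geometry, peak bookkeeping, rotamer
assignment, altloc construction — not that any particular real map will
yield chemically correct alternates; threshold choice on real maps
remains the user's scientific judgement.

Under seeded noise (sd 0.2σ) the planted 60/40 serine ensemble is
recovered—both rotamers, major state as altloc A—in 20/20 seeds, but
noise bumps in the unoccupied `t` well occasionally clear the permissive
0.3σ default threshold and add a third, weak conformer (strict
two-alternates-only recovery: ~14/20). That is faithful behavior, not a
bug: the same trade-off exists on real maps, and the intended controls
are the threshold and the per-residue cap. `maxAlts = 2` or a threshold
just above the noise floor removes the phantom state.

## Design decisions that were genuinely open

* **"Occurs most often"** is read as the library's population frequency,
  not re-counting in the input structure.
* **Relative intensities are normalized per trace**, not per structure; a
  residue's signal then measures internal consistency of its own
  evidence, independent of how strong its absolute density is.
* **The input conformer is not specially preserved.** If its well has a
  peak it re-emerges as an ideal rotamer; if not, the density evidence
  wins and it is replaced.
* **`SIDECHAIN` mode labels CA and outward**; N, C, O stay shared with
  blank altlocs. Duplicating from CA lets refinement develop backbone
  heterogeneity while keeping the peptide bond single-state.
* **Single-candidate residues stay single-conformer** (no altloc with
  occupancy 1.0 is ever written for a lone state, and `maxAlts = 1`
  therefore never splits anything).
* **B factors are inherited** from the atoms being replaced.

## Problem sizes

The shipped tests and the acceptance script run on peptide fixtures of
3–5 residues with maps of ~40–60 thousand grid points, 1000 random
matching tuples per residue type and 1000 random traces for the oracle
comparisons, and 20 noise seeds for the Monte-Carlo recovery experiment —
sizes chosen so the full suite exercises every code path in about a
minute while keeping the Monte-Carlo rates stable.

## Known limitations

* Symmetry handling is lattice translation (P1 coverage of the full
  cell); maps with higher space-group symmetry must be supplied as
  full-cell grids, which standard map tools produce readily.
* PRO is excluded from sampling (ring-constrained χ), as are GLY/ALA
  (no χ); backbone φ/ψ sampling is out of scope.
* No occupancy refinement, clash resolution or water remodeling: outputs
  are starting points for crystallographic refinement, not end points.
* The fixture peptide builder covers 14 residue types; the sampling and
  building engine itself handles all 18 χ-bearing types.
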