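---
title: "Methods: predicting tyrosine-to-DOPA modification from solvent accessibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting tyrosine-to-DOPA modification from solvent accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dopasight)
```

## The problem

Mussel foot proteins (MFPs) owe their underwater adhesion to
L-3,4-dihydroxyphenylalanine (DOPA), a post-translationally modified
tyrosine carrying a second ring hydroxyl at the ortho (C3) position.
Engineered adhesives fuse DOPA-rich MFP domains to self-assembling
scaffolds — the canonical example being a chimera of the E. coli curli
subunit CsgA and the small, tyrosine-rich Mytilus protein MFP3.  The
modification is installed enzymatically by tyrosinase, which can only
act on tyrosines whose phenol ring is solvent-exposed.  `dopasight`
predicts, from a structure model, which tyrosines are plausible
tyrosinase substrates, edits them to DOPA in the coordinates, accounts
for the resulting mass shift, and classifies the pH-dependent
catechol/quinone adhesion state.

## Accessibility model

Solvent-accessible surface area (SASA) is computed with the
Shrake–Rupley method: every heavy atom's van der Waals sphere is
augmented by the probe radius (water, 1.4 Å), sampled at `n` test
points, and a point counts as accessible when it lies outside every
neighbouring augmented sphere.  Three numerical choices matter:

* **Test points** are a deterministic golden-section spiral
  (`sphere_points()`), not random samples, so results are
  bit-reproducible.  The default `n = 960` converges to within 2% of
  `n = 4000` on our fixtures; the residual grid noise is the reason the
  rigid-motion invariance test allows up to 1% total-area drift (and
  2% for a single residue).
* **Radii** are Bondi-style: C 1.70, N 1.55, O 1.52, S 1.80 Å,
  heavy atoms only by default (hydrogens are parsed and flagged but
  excluded, matching the usual heavy-atom convention for structure
  models without reliable protons).  All radii are config-overridable.
* **Neighbour search** uses a uniform spatial grid with cell size
  `2 × (max radius + probe)`, making the result independent of atom
  order and linear in atom count.  The inner point-occlusion loop is
  compiled (Rcpp) for speed; the algorithmic skeleton stays in R.

A seeded Monte-Carlo rejection-sampling estimator
(`mc_sasa_oracle()`) implements the same quantity by an independent
route; the test suite requires agreement within three standard errors
per atom.  Closed forms for an isolated sphere and for two equal
intersecting spheres (spherical-cap formula) anchor the absolute scale.

**Relative accessibility** divides a residue's area by a theoretical
maximum for its type (Tien et al. 2013 values, shipped as a plain-text
table).  The normalization is deliberately swappable because the
source workflow ("surface area percentage" in PyMOL) never states its
reference; whole-residue relative SASA is the default interpretation,
with side-chain-centric behaviour available through the ring-carbon
mode below.  DOPA has no published maximum, so its entry is the
tyrosine maximum plus a 30 Å² hydroxyl increment — only used when a
structure already containing DOPA is normalized, never in the
tyrosine classification itself.  Extended conformations can exceed
their reference (values are capped at 1.5 with a warning).

## Classifying tyrosines

Two schemes, mirroring the two manual strategies the workflow is built
around:

* `whole_residue` (default): modifiable iff relative SASA is
  **strictly greater** than the threshold, default 0.55 ("more than
  55%").
* `ring_carbon`: modifiable iff each of the named ring carbons
  (default CE1/CE2) has at least 5 Å² exposed.  The benzene "carbons
  three and four" of the source description are mapped to the
  PDB names CE1/CE2 — the positions ortho to the existing hydroxyl at
  CZ, which is where tyrosinase hydroxylates; CZ itself already bears
  the OH.  The 5 Å² cut-off is an operational stand-in for a visual
  judgement and is echoed in every report.

Both quantities are reported for every tyrosine regardless of mode, so
disagreements between the schemes on intermediate cases are visible.
Raising the threshold can only shrink the modifiable set
(a tested monotonicity property).

## Editing the structure

`apply_dopa()` renames each selected tyrosine to the DOPA component
code (`DAH`) and adds one oxygen (`OH3`) bonded to CE1 at 1.36 Å, in
the least-squares ring plane, along the bisector of the external angle
at CE1.  Pre-existing coordinates are untouched; exactly one atom is
added per conversion (heavy-atom model, no proton).  Re-application to
an already-converted residue is an error rather than a double edit.

## Mass bookkeeping

The mass model is the additive oxygen ledger `mw = uw + (ow × n)/1000`
(kDa).  Two conventions are first-class:

* **paper** (default): both catechol hydroxyls are booked per DOPA
  (`n = 2 × n_dopa`), reproducing the published arithmetic
  20.385 kDa + 14 × 16 Da = 20.609 kDa, i.e. a 224 Da shift for 7
  DOPA.
* **chemical**: hydroxylation adds a single oxygen per DOPA
  (`n = n_dopa`), the chemically standard accounting (112 Da for 7).

`ow` defaults to exactly 16.0 to reproduce the printed numbers;
15.9994 is available by configuration.  Sequence masses use average
residue masses plus one water.  The inverse map
`dopa_count_from_delta()` rounds and reports its residual, warning
when the difference is inconsistent with a whole number of DOPA.  The
unmodified mass of the real chimera cannot be re-derived from the
bundled sequences alone (linker and purification-tag composition are
unspecified), so it is treated as user input.

## pH and adhesion

The redox model is an explicit step function: DOPA is catechol
(reduced, two ring OH, hydrogen-bond donor, adhesive) at or below the
oxidation threshold and quinone (auto-oxidized, no donors,
non-adhesive) above it.  The default threshold 6.5 sits between the
adhesive (pH 3, 5) and non-adhesive (pH 7.4, 9) regimes; no titration
curve is fitted because none is available — this is a qualitative
classifier, not an energy model, and the published force values are
figure-only and deliberately not encoded.  Consequences asserted in
tests: adhesion is monotone non-increasing in pH, and an unmodified
protein is never adhesive at any pH.

## Synthetic fixtures: what they do and do not establish

All structures used in testing are generated (`build_fixture()`),
deterministically, from ideal internal coordinates (N–CA 1.458,
CA–C 1.525, C–N 1.329 Å; ω = 180): single atoms and pairs for
closed-form SASA checks, a 3×3×3 lattice for total burial, ideal
helices/strands for dihedral checks, and Gly-Tyr-Gly hosts for
tyrosine exposure.  The exposed host uses a fully extended backbone
(φ = −150, ψ = 150) with the common χ1 = −60 rotamer, which leaves the
central tyrosine at ~0.87 relative SASA — "near-maximal by
construction".  Burial is enforced by two concentric shells of carbon
blocker pseudo-atoms (HETATM records in their own chain, so
residue-level logic ignores them while occlusion sees them).  The toy
chimera concatenates a strand-like segment with an extended segment
carrying `k` exposed and `m` shell-buried tyrosines; classification
must recover exactly `k`.

These fixtures exercise the geometry and the decision logic under
controlled ground truth.  They do **not** emulate a folded protein's
packing, amyloid registers, or the real chimera's burial pattern: a
green classification suite establishes that the pipeline measures
exposure correctly, not that any particular published per-domain
modification split is reproduced.  The published 6-of-8 MFP3 split
would require the authors' undeposited structure model, and the
printed per-domain tyrosine counts disagree with the printed sequences
anyway (10 + 4 = 14 tyrosines in the sequences; the headline 7/14 = 50%
ratio is what the pipeline reproduces structurally).

## Degenerate inputs and tie-breaks

* FASTA: empty files, empty sequences, and non-amino-acid characters
  are errors naming the offender; `X` requires an explicit opt-in.
* PDB: first MODEL only (warning), highest-occupancy altLoc kept
  (ties: first), insertion codes form part of the residue key,
  unreadable coordinates report their line number.
* Classification threshold is a strict inequality: exactly 55% is not
  modifiable.
* Collinear backbone atoms make a dihedral undefined; the residue is
  marked `incomplete` with a warning rather than given an arbitrary
  angle.
* Ramachandran regions are coarse rectangles with a 20° "allowed"
  margin — a labelled simplification suitable for sanity checks, not a
  replacement for empirical density maps.

## Known limitations

* The CsgA precursor fixture carries the printed 150-residue sequence
  verbatim even though its annotated range implies 151; one residue is
  unrecoverable from the printed source, and the discrepancy is
  surfaced (not patched) in the acceptance suite.
* The ~20 Å² SASA difference reported between pH 3 and 7.4 has no
  stated computation (no protonation-dependent radii) and is not
  reproduced.
* SASA uses Shrake–Rupley only; no Lee–Richards slicing, meshes, or
  implicit-solvent energetics.
* The pH model is binary; partial oxidation between pH 5 and 7.4 is
  outside its vocabulary.
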