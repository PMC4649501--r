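---
title: "Quantifying calcium-driven activation of penta-EF-hand proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying calcium-driven activation of penta-EF-hand proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pefhand)
```

## The biological question

Penta-EF-hand (PEF) proteins — Sorcin, PDCD6/Alg-2, the calpain small
subunit dVI domain — are calcium sensors built from eight α-helices (A–H)
organised in five helix-loop-helix EF-hands (EF1–EF5). Two helices are
long and shared: helix D belongs to both EF2 and EF3, helix G to EF4 and
EF5. The EF4–EF5 region forms the dimer interface and is rigid; the
EF1–EF3 region binds calcium and moves. Activation is therefore naturally
described by angles: the opening angle θ of each EF-hand (between its two
helix axes) and the angle between helices D and G, which summarises the
swing of the EF1–EF3 sub-domain against the dimerisation sub-domain. This
package turns those descriptions, plus the accompanying surface, metal,
motif and binding measurements, into tested functions.

All structure-facing functions work on a tidy atom table (`pef_structure`):
one row per atom, author residue numbering preserved exactly as deposited,
hetero records flagged rather than dropped. PDB and mmCIF files are parsed
with bio3d behind `read_structure()`; alternate conformers collapse to the
highest-occupancy one (ties by altloc order) because single-conformer
geometry is what the measurements need.

## Helix axes and opening angles

The opening angle is only as good as the axis fit. We estimate an axis
from the trace curvature: for consecutive Cα positions the second
difference `s_i = p_{i+1} - 2 p_i + p_{i-1}` points from the trace toward
the axis, and the cross product of consecutive second differences lies
along the axis — exactly so for an ideal helix, which makes the estimator
exact (machine precision) on regular geometry and lets the test suite
demand recovery to 0.01°. The cross products are sign-aligned and
averaged over the whole segment, which damps local irregularity in real
helices; short or (near-)collinear traces fall back to the first principal
component of the point cloud, which is also the natural "ideal line"
answer for collinear input. We chose this over a plain principal-component
fit because the principal axis of a helical point cloud tilts measurably
(order 0.1°–2°) whenever the segment does not span an integral number of
turns; the curvature estimator has no such bias, and on real, regular
helices the two agree to within a degree or two, which is also the level
of agreement expected against molecular-graphics axis measures. The
reported `fit_rms` is the spread of point-to-axis distances about the
best-fit cylinder radius (0 for an ideal helix), a direct regularity
diagnostic.

Axes are *directed* (N→C terminus), so θ ∈ [0°, 180°] is well defined and
apo→holo differences carry a consistent sign: Δθ = θ(holo) − θ(apo), with
`delta_table()` antisymmetric by construction. For an apo/holo pair the
same residue ranges must be used on both forms — otherwise a Δθ conflates
boundary re-assignment with conformational change — which is what
`derive_registry()` (auto-assignment on one form, trimmed to residues
resolved in both) produces and what `run_full_analysis()` does by default.

Helix boundaries come from one of three routes. `auto` applies a
Cα-geometry secondary-structure assignment in the P-SEA spirit: residue
*i* is helical when the Cα(i)–Cα(i+3) distance falls in 4.5–5.6 Å and
Cα(i)–Cα(i+4) in 5.6–6.9 Å (the canonical α-helix values are ≈5.05 and
≈6.2 Å); overlapping 5-residue windows are merged, runs are broken at
author-numbering gaps, and segments of ≥5 residues survive. With
`label = "pef"` the eight longest segments are named A–H in sequence
order; fewer than eight is an error directing the user to the other
routes. `registry` ships approximate boundary tables for the three family
members, following the canonical architecture; these are synthetic
conveniences for getting started, explicitly documented as such, and any
real structure should use `auto`/`derive_registry()`. `file` reads a user
TSV. Every report can carry the annotation table used, so the provenance
of an angle is never ambiguous. On ideal helices, shifting boundaries by
±2 residues moves θ by well under a degree (tested); on real helices with
frayed termini the registry-trimming convention is what keeps apo and holo
comparable.

## Superposition and per-region RMSD

`kabsch_superpose()` is the standard SVD solution with a determinant
correction excluding reflections; degenerate (collinear) point sets are
an error rather than a silent garbage rotation. Sub-domain flexibility is
measured by `region_rmsd()`: pair Cα atoms by (chain, author number)
intersection, superpose *once* on a reference region (e.g. the EF4–EF5
half), and report each region's RMSD under that single transform. No
per-region re-fitting — the point is precisely how far other regions move
in the reference frame of the rigid part.

## Calcium coordination geometry

`find_metal_sites()` takes every hetero atom of the requested element as a
site and collects O/N ligands within a cutoff, default 2.9 Å: wide enough
to cover the canonical 2.3–2.6 Å Ca–O range plus the longer reach of
bidentate carboxylates, each oxygen of which counts as its own ligand
(that convention is what makes an EF-hand site hepta-coordinated).
Classification is template-based and exhaustive: for seven ligands, all
C(7,2) = 21 ligand pairs are tried as the axial pair of a pentagonal
bipyramid; the remaining five are ordered by azimuth about the axial
direction; and the deviation is the mean absolute residual against the
ideal angles (axial–axial 180°, axial–equatorial 90°, adjacent equatorial
72°). Six ligands are tested against the octahedral template the same way.
The class is assigned below a 20° deviation threshold — generous, because
real EF-hand sites are appreciably distorted, while the score itself
orders sites by regularity (it is 0 on ideal polyhedra and grows
monotonically with angular jitter, a tested property).

## Solvent accessibility and surfaces

`compute_sasa()` is a Shrake–Rupley implementation: each atom's sphere is
expanded by the probe radius (1.4 Å) and covered with a deterministic
golden-spiral point lattice (960 points/atom by default); the accessible
fraction is the share of points outside every neighbouring expanded
sphere. Radii are a Bondi-style heavy-atom table, recorded in the profile
for provenance. Waters and hetero atoms are excluded from surface and
occluders by default, the usual protein-surface convention. A
deterministic lattice (rather than random sampling) makes repeated runs
byte-identical; at 960 points a lone atom matches the analytic sphere to
0.5% and two-sphere systems match the spherical-cap closed form to 2%
(both tested), with per-residue convergence of better than 1% against a
4-fold denser lattice on multi-atom residues.

"Exposure change greater than 30%" needs a denominator convention; ours is
`100 * (holo − apo) / max(apo, 1 Å²)`, i.e. relative to the apo area with
a 1 Å² floor, plus an absolute guard of a ≥5 Å² increase. Rationale: the
biological claim is about residues that *gain* exposed surface on
activation, and without the floor and guard, near-buried residues with
sub-Å² areas dominate any percentage ranking. Both knobs are arguments.
Set comparisons against a reference residue list should use overlap
measures (Jaccard), not exact equality — the threshold sits on a
continuum and implementations legitimately differ at the margin.

`hydrophobic_patches()` is deliberately labelled Hotpatch-*like*: a
transparent approximation (exposed hydrophobics at ≥20% of their
Gly-X-Gly reference maximum, single-linkage clustering of side-chain
centroids at 6.5 Å, ranking by exposed area) of the kind of
hydrophobic-patch analysis done by dedicated servers whose statistical
models are not public. It finds the exposed clusters; it does not assign
their significance. `interface_burial()` measures per-residue burial as
isolated-minus-complex SASA — by definition, total complex SASA plus twice
the contact area equals the sum of isolated-partner SASAs, a tested
invariant.

## Consensus motifs

Phage-display output against Sorcin is summarised by degenerate
residue-class motifs; two ship built in. The Φ/Gly/Met-Φ/Gly/Met-x-P motif
has positions 1–2 drawn from {Trp, Tyr, Phe, Gly, Met}, a wildcard, then
proline — the class pattern matched by Sorcin's own N-terminal GYYP. The
acidic-Φ motif is {Asp, Glu} followed by an aromatic; since the aromatic
set for this second motif is not pinned down by the primary description,
we default Φ to {Trp, Tyr, Phe} and leave the set configurable. Scanning
is exact window matching (all overlapping hits, 1-based positions) and is
tested against a brute-force oracle. Library linkers (SSSG-/-GGGSGG) are
vector-derived, not selected, so `strip_linkers()` removes them before
analysis. Anchored position-frequency matrices align each sequence on its
first motif hit and count over the motif window — full-length alignment of
16-mers on a 4-position anchor would leave ragged, sparsely-populated
flanking columns that say nothing about the motif. Deduplication to unique
sequences is the default, matching the convention of counting unique
clones. Logos use the WebLogo information-content scaling; the PFM is the
tested object, the logo a thin rendering.

## SPR kinetics

The 1:1 Langmuir model: during association
R(t) = Req·(1 − e^(−(kon·C + koff)·t)) with Req = Rmax·C/(C + Kd),
during dissociation R(t) = R_end·e^(−koff·t), Kd = koff/kon. Parameters:
kon in 1/(M·s), koff in 1/s, Rmax in RU (surface capacity), C the molar
analyte concentration. `fit_kinetic()` fits one (kon, koff, Rmax) triple
globally across all concentrations by Levenberg–Marquardt on log-scale
parameters, started from a fixed 3×3 grid (kon ∈ {10³, 10⁵, 10⁷},
koff ∈ {10⁻⁴, 10⁻²·⁵, 10⁻¹}) so the answer cannot depend on a lucky
initial guess; curves are baseline-subtracted when a baseline phase is
present. Mass-transport limitation and drift are out of scope — the model
is the simple 1:1 scheme that single-Kd reporting implies.
`fit_steady_state()` fits the equilibrium isotherm and also returns the
Scatchard linearisation (Req/C vs Req, slope −1/Kd), which agrees exactly
on noiseless data; under noise the nonlinear fit is the better estimator,
and the tests treat the 5%-recovery claim at 2% noise as an ensemble
statement (mean error over seeded replicates), because single noisy
realisations of a 44-point design still fluctuate by up to ~9%.

## What the synthetic generators emulate — and what they do not

The generators produce: ideal α-helix Cα traces at exact axes (canonical
1.5 Å rise, 100° twist, 2.3 Å radius); eight-helix monomers whose directed
axes satisfy a full prescribed set of EF-hand and hD–hG angles (helix D is
the reference; C, E, G are placed at the EF2/EF3/hD–hG angles from it, F
and H at the EF4/EF5 angles from G, B at the EF1 angle from a free A —
azimuths drawn reproducibly under a seed); ideal or jittered coordination
polyhedra; motif-planted peptide sets over a background composition; and
noisy 1:1 sensorgrams. Fixtures are written as standard PDB text and read
back through the same parser as real data — no test-only code paths.

They do **not** emulate: side-chain packing, loop geometry connecting
helices, crystallographic disorder, real coordination-sphere distortion,
correlated SPR artefacts (drift, bulk shifts), or amino-acid composition
bias of real phage libraries. Passing tests therefore demonstrate that the
*measurement machinery* is correct and self-consistent at planted ground
truth; they do not certify boundary assignment on frayed real helices or
flagging behaviour under real crystallographic noise. On deposited
apo/holo pairs the angle pipeline is expected to agree with
molecular-graphics measurements to a few degrees (axis-method
differences), which is the tolerance the family comparison warrants.

Default study conditions used by the tests and the acceptance script
mirror the experimental setting: 16-mer peptides (the display library's
length), selections of order 200 sequences at planted prevalences of 47%
(calcium) and 15% (EDTA), sensorgram series of six concentrations
spanning 0.2–6 µM around micromolar Kd values (3.5, 5, 6 and 12 µM) with
noise at 1–2% of Rmax, and monomers of eight 12-residue helices (~96 Cα),
small enough that the whole suite runs in well under a minute.

## Numerical choices and degenerate inputs

- Angles are clamped into [−1, 1] before `acos`; antiparallel axes give
  exactly 180°.
- Kabsch requires ≥3 non-collinear pairs; collinear input errors.
- Axis fitting requires ≥4 points; 4-point traces use the PCA fallback
  (the curvature estimator needs 5).
- The SASA lattice is deterministic, so all surface outputs are exactly
  reproducible; report writers round floats to 4 decimals, making
  re-runs byte-identical (tested).
- `delta_sasa` errors on disjoint residue sets rather than returning an
  empty report; empty selections are values, not errors, where emptiness
  is meaningful (no hits, no patches, no interface).
- Metal sites with <4 ligands are "other" with a missing deviation;
  coordination numbers without a template (5, 8+) report a descriptive
  nearest-template deviation but never a class.
- All generators are deterministic under their `seed` argument
  (byte-identical outputs, tested).

## Known limitations

- The shipped registries are approximate, architecture-derived tables;
  exact boundaries should always be derived from the coordinates at hand.
- Hotpatch-like patches are a geometric approximation without a
  statistical significance model.
- The hydrogen-bond criterion is distance-only (≤3.5 Å heavy-atom), the
  right choice when hydrogens are absent from X-ray models, but it will
  report close polar contacts that a geometry-aware criterion would
  reject.
- The SPR model ignores mass transport; strongly transport-limited data
  will bias kon and koff (though Kd is more robust).
- `compare_family()` assumes the PEF topology (the EF↔helix map); it is
  not a general EF-hand discovery tool.
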