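# pefhand

Structural quantification of calcium-driven activation in penta-EF-hand
(PEF) proteins — Sorcin, PDCD6/Alg-2 and the calpain small-subunit dVI
domain — for structural biologists who want the family's standard
conformational-change measurements as tested, scriptable R functions
rather than one-off molecular-graphics sessions.

A PEF monomer carries a glycine-rich N-terminal domain and a calcium-binding
domain of eight α-helices (A–H) arranged in five EF-hands (EF1–EF5), with
two long helices shared between hands: helix D (EF2/EF3) and helix G
(EF4/EF5). Calcium binding opens individual EF-hands and tilts the EF1–EF3
sub-domain against the EF4–EF5 dimerisation sub-domain, exposing
hydrophobic surface that recruits partner proteins. The package measures
that mechanism end to end:

- **EF-hand opening angles.** Each helix axis is fitted from its Cα trace
  (a curvature-based estimator, exact on ideal helices); the opening angle
  of an EF-hand is the angle θ ∈ [0°, 180°] between the directed axes of
  its entering and exiting helices, and Δθ = θ(holo) − θ(apo). The angle
  between helices D and G tracks the global sub-domain movement.
- **Rigid superposition.** Kabsch least-squares rotation (SVD with
  determinant correction), whole-structure RMSD, and per-region RMSD under
  a single alignment to localise flexibility.
- **Calcium coordination.** Coordination spheres at a configurable cutoff
  (2.9 Å default for Ca–O), with exhaustive template classification of
  pentagonal-bipyramidal (2 axial + 5 equatorial at 72°) and octahedral
  geometry and a mean-angular-deviation score.
- **Solvent accessibility.** Shrake–Rupley point-sampled SASA (960
  points/atom default, 1.4 Å probe), apo→holo exposure-change flagging
  (relative change > 30% plus a 5 Å² absolute guard), hydrophobic
  surface-patch clustering, and peptide-interface burial by
  complex-versus-isolated SASA difference.
- **Consensus motifs.** Degenerate residue-class motif scanning (the
  Φ/Gly/Met-Φ/Gly/Met-x-P and acidic-Φ Sorcin-binding motifs ship
  built in), position frequency matrices, per-condition motif prevalence
  and information-content logos for phage-display peptide sets.
- **SPR kinetics.** 1:1 Langmuir sensorgram simulation, global
  Levenberg–Marquardt fitting of (kon, koff, Rmax) across concentration
  series (Kd = koff/kon), steady-state isotherm fitting and the Scatchard
  linearisation (slope −1/Kd).

Everything takes and returns tidy tables: structures are tibbles of atom
records (author residue numbering, never rewritten), reports are tibbles,
fits have `tidy()`/`glance()`/`autoplot()` methods, and a synthetic-data
module (`build_helix()`, `build_pef_monomer()`, `build_metal_site()`,
`generate_peptides()`, `simulate_sensorgram()`) generates every kind of
fixture at prescribed ground truth, so the whole pipeline is verifiable
without downloading coordinate files.

## Worked example

Build a synthetic apo/holo pair of eight-helix monomers at the opening
angles reported for apo and calcium-bound Sorcin, write them as PDB files,
and run the full pipeline (helix annotation is auto-derived from the apo
file):

```r
library(pefhand)

apo_angles  <- c(EF1 = 40.8, EF2 = 60.7, EF3 = 52,   EF4 = 47.3,
                 EF5 = 32.9, `hD-hG` = 57.5)
holo_angles <- c(EF1 = 59.2, EF2 = 57.9, EF3 = 66.5, EF4 = 45.9,
                 EF5 = 29.9, `hD-hG` = 78.1)
apo  <- build_pef_monomer(apo_angles,  seed = 1)
holo <- build_pef_monomer(holo_angles, seed = 2)
write_structure(apo$structure,  "apo_synthetic.pdb")
write_structure(holo$structure, "holo_synthetic.pdb")

bundle <- run_full_analysis("apo_synthetic.pdb", "holo_synthetic.pdb")
bundle$deltas
#> # A tibble: 6 × 6
#>   apo   holo  angle theta_apo theta_holo delta
#>   <chr> <chr> <chr>     <dbl>      <dbl> <dbl>
#> 1 apo   holo  EF1        40.8       59.2 18.4
#> 2 apo   holo  EF2        60.7       57.9 -2.80
#> 3 apo   holo  EF3        52.0       66.5 14.5
#> 4 apo   holo  EF4        47.3       45.9 -1.40
#> 5 apo   holo  EF5        32.9       29.9 -3.01
#> 6 apo   holo  hD-hG      57.5       78.1 20.6
```

The delta column is the calcium response: EF1 and EF3 open by ~18° and
~15°, EF2/EF4/EF5 barely move, and the hD–hG sub-domain angle tilts by
~21° — the signature of PEF-protein activation. On real files the same
call takes the deposited apo and holo PDB entries.

Kinetics round-trip at the Sorcin–PDCD6 affinity scale (Kd = 3.5 µM),
with 2% noise:

```r
sg  <- simulate_sensorgram(kon = 1e5, koff = 0.35, rmax = 100,
                           conc = c(2e-7, 4e-7, 8e-7, 1.5e-6, 3e-6, 6e-6),
                           noise_sd = 2, seed = 1)
fit <- fit_kinetic(sg)
fit
#> # 1:1 Langmuir kinetic fit
#>   kon  = 1.07e+05 1/(M s)
#>   koff = 0.373 1/s
#>   Kd   = 3.5e-06 M
#>   Rmax = 100 RU
autoplot(fit)   # observed curves with the fitted model overlaid
```

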