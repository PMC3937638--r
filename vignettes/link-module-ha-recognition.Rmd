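---
title: "Methods: modeling HA oligosaccharide recognition by the TSG-6 Link module"
author: "hagroove"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling HA oligosaccharide recognition by the TSG-6 Link module}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its models and numerical choices:
what each stage computes, which parameters matter, what the synthetic data
emulate, and where the design was genuinely open.

## The glycan geometry engine

Oligosaccharides are treated as chains of rigid pyranose rings. Each residue
type (GlcUA, GlcNAc, GalNAc) is an idealized ⁴C₁ chair: ring atoms on a
hexagon of radius 1.43 Å with alternating ±0.25 Å out-of-plane displacement
(ring bonds ≈ 1.52 Å), with substituents placed along tetrahedral axial or
equatorial directions at literature-standard bond lengths (C–O 1.41–1.43 Å,
C–N 1.45 Å, C–C 1.52 Å). GlcNAc and GalNAc differ only in the C4 hydroxyl
orientation (equatorial vs axial), which is exactly the chemical difference
between HA and chondroitin disaccharides. Only heavy atoms plus the N-acetyl
methyl carbon are represented: restraints, clash detection and contact
counting all operate on heavy atoms, so hydrogens would add cost without
information. Ring flexibility (non-⁴C₁ puckers) and exocyclic ω sampling are
out of scope.

The only degrees of freedom are the glycosidic torsions, defined per linkage
as Φ = O5(i)–C1(i)–O_g–C_x(i+1) and Ψ = C1(i)–O_g–C_x(i+1)–C_{x+1}(i+1),
heavy-atom convention, with x = 3 out of a uronic acid (β1,3) and x = 4 out
of a HexNAc (β1,4). No universal convention exists for carbohydrate
dihedrals, so this one is declared explicitly and carried as a tag on every
conformer and torsion map; mixing objects with different tags is a hard
error rather than a silent misinterpretation. Chains are assembled by
natural-extension placement of the three attachment atoms followed by an
exact three-point rigid superposition of the child template, which makes
`build_conformer()` and `measure_torsions()` exact inverses (round-trip
error below 10⁻⁶ degrees, tested over random torsion vectors) and keeps
every intra-ring distance bit-identical across torsion changes.

Specifier grammar: `HA{n}^{AN|NA|AA|NN}` (first letter = non-reducing
terminus, A = GlcUA, N = GlcNAc), `C{n}^..` for chondroitin, and the hybrids
`HA4C4` / `C4HA4`. The hybrid names are easy to invert, so the convention is
stated prominently: **`HA4C4` carries its chondroitin (GalNAc) disaccharides
at the non-reducing end** and its HA tetrasaccharide at the reducing end;
`C4HA4` is the mirror image. Impossible terminal combinations (an even-length
oligomer with identical termini, or odd with different) are rejected at
parse time.

## Φ/Ψ maps and the favored-region filter

Each linkage type has a periodic energy surface over [−180°, 180°)², stored
as a plain-text grid (10° spacing by default) and queried by bilinear
interpolation with wrap-around. A linkage is *favored* when its energy is at
most a cutoff above the map minimum; a model is accepted when every linkage
is favored. The default cutoff is 4 kcal/mol: the surfaces are contoured at
2 kcal/mol intervals, and "well outside the most favored region" is read as
beyond the second contour. The cutoff is exposed as a parameter, and
filtering is monotone in it by construction.

The molecular-dynamics-derived maps that motivated this machinery are not
publicly tabulated, so the package ships *surrogate* defaults: smooth
two-basin periodic surfaces per linkage type, with main basins placed (in
this package's own dihedral convention) where an HA chain built at the
minima adopts an extended, solution-like conformation (ring-1→ring-8
centroid separation ≈ 35 Å for the octasaccharide). These defaults are
documented approximations for exploratory use; quantitative work should
supply its own grids in the file format the package reads, and no test
depends on the defaults' absolute energies — fixtures always construct
their own basins.

## Complex modeling

The receptor is immutable; a checksum invariant verifies that no operation
touches its coordinates. Two restraints drive the models, both
flat-bottomed quadratics (zero inside the bound, k·excess² outside):

- **Ring stacking** between sugar ring 1 and the His45 imidazole: centroid
  distance target 3.5 Å plus an angular term keeping the ring planes within
  30° of parallel (angular force constant 0.01 kcal mol⁻¹ deg⁻²). The source
  experiments specify only the 3.5 Å stacking distance; the parallel-plane
  term and its 30° width are this package's functional form for "stacking",
  and both are parameters.
- **Methyl contact** between the ring-4 N-acetyl methyl carbon and the Ile61
  terminal side-chain carbon, upper bound 4.5 Å — a typical CH₃···CH₃
  hydrophobic contact distance, chosen here because no explicit bound was
  published; it is likewise configurable.

Steric exclusion counts receptor/ligand heavy-atom pairs closer than
0.7 × (r₁ + r₂) (van der Waals radii C 1.70, N 1.55, O 1.52, S 1.80 Å),
excluding pairs that a restraint deliberately brings together; the penalty
is a quadratic overlap sum. Salt bridges and hydrogen bonds are *not* energy
terms: they emerge (or not) as geometry and are reported through ring
contacts, matching the view that the restraints plus sterics carry the
modeling content.

Optimization is simulated annealing in the mixed torsion/rigid-body space:
moves perturb one torsion (σ 8°→1.5° over the schedule), rotate the ligand
about its ring-1 centroid (σ 3°→0.3°), or translate it (σ 0.25→0.03 Å), with
Metropolis acceptance under geometric cooling (T 3→0.02 over 600 steps by
default) followed by 200 descent-only polish steps from the best state. The
objective is restraint energy + 10× clash penalty + 0.5× summed map energy.
Everything is deterministic given the seed. Whether the original modeling
minimized a Cartesian force field is not recoverable; this torsion-space
objective is a declared reinterpretation, and the "distorted bonds" failure
mode of Cartesian refinement cannot arise in a rigid-ring build — the
equivalent sanity check is the glycosidic bond-length deviation (tolerance
0.05 Å) plus the residual clash count.

Ensemble generation runs one annealing per seed (default 20, mirroring the
size of an NMR ensemble), filters on sanity + zero clashes + satisfied
restraints (< 0.1) + favored torsions, and records a per-seed rejection
reason. Ring contacts use a 4.0 Å heavy-atom cutoff.

## Register inference from chemical shift perturbation classes

The binding groove has eight positions, numbered from the His45 end, with
uronic acids on odd positions and a feature table (stacking, salt bridges,
pockets, hydrogen bonds) giving each position an interaction weight
(positions 1–8 contribute 2, 1, 1, 2, 1, 3, 1, 0 features). A *register*
places ring r at position offset + r. Enumeration admits every offset with
parity-consistent in-groove rings, at most two rings overhanging each end,
and at least four rings in the groove — the loosest rules consistent with
all placements the reporter data support (the decasaccharide's two
registers need two-ring overhangs; the tetrasaccharides need the four-ring
floor). Both bounds are parameters of `groove_model()`.

Reporters map occupancy to peak classes: Val62 (class II iff position 1
occupied, else I), Lys63 (III iff position 1; IV iff position 2 only; V iff
neither), Ala49/Tyr78 (IX iff position 7 occupied; X iff the reducing
terminus sits at position 6; otherwise unclassified), with His45 available
as an optional mirror of Lys63 (VI/VII/VIII). An "unclassified" prediction
imposes no constraint during inference — this is how the distinct peaks of
the short oligomers are handled without guessing their cause. Inference
keeps candidates consistent with every observed reporter and then selects
the smallest subset whose predictions jointly cover all observed classes,
breaking ties by total interaction score; co-selected registers are
reported as coexisting (the underlying exchange is millisecond-timescale
and is not modeled). With no consistent candidate the result is empty plus
a per-candidate diagnostic naming the first violated reporter.

## ITC simulation and fitting

Per-injection heats follow the one-site isotherm with the standard
perfusion bookkeeping: after cumulative injected volume ΔV into cell volume
V₀, totals are scaled by (1 − ΔV/2V₀)/(1 + ΔV/2V₀) (macromolecule) and
(ΔV/V₀)/(1 + ΔV/2V₀) (ligand), the bound fraction solves the mass-action
quadratic in its numerically stable root form, and the measured heat of
injection i is Q(i) − Q(i−1) + (dVᵢ/V₀)(Q(i)+Q(i−1))/2. The cell volume is
not part of the published protocol; the default is the VP-ITC nominal
1.4 ml, configurable. First-injection discard is available but off by
default. In the saturating limit the cumulative heat approaches
N·ΔH·(cell protein moles), with a residual of order dV/2V₀ from the volume
displaced during the pre-saturation injections — which is why the
saturation check uses small (1 μl) injections.

Fitting is Levenberg–Marquardt least squares over (N, log K_b, ΔH), with ΔH
started from the early-injection heats per mole injected, N at 1, and K_b
from a coarse grid of Wiseman c-values; the best of the four starts wins.
Standard errors come from the fit covariance and are labelled as such — the
published uncertainties mix fit errors and between-experiment scatter, so
no attempt is made to match them. Degenerate (near-zero-heat) series are
flagged rather than silently returned. ΔG = −RT ln K_b is evaluated at
298.15 K with R = 1.9872 × 10⁻³ kcal mol⁻¹ K⁻¹; TΔS = ΔH − ΔG is an
arithmetic identity; the percent-of-reference column is formatted at the
published precision (one decimal below 100, integer above). Published ΔG
values that derive from per-experiment averaging can differ from
−RT ln(mean K_b) by a few hundredths of a kcal/mol; the reproduction report
flags those rows as failing rather than loosening the comparison.

## What the synthetic data do and do not show

The receptor fixture is explicitly non-physical: anchor side chains only
(His45 imidazole, Lys63/Lys11/Arg81 amines, the Cys47–Cys68 pair, Tyr59 and
Tyr78 rings, Ile61), arranged around an HA₈ conformer built at the
default-map minima so that the reference pose satisfies both restraints
exactly, has zero clashes, and touches the receptor with rings 1–7 but not
ring 8. It exercises every code path — restraint evaluation, annealing
convergence, filtering, contact counting — under a known ground truth, but
it cannot test force-field realism, receptor flexibility, or the geometry
of a real Link module; conclusions about real complexes require real
coordinates, which the loaders accept as multi-model PDB.

The CSP panel generator places each reporter's bound peak at an arbitrary
but fixed canonical position per class, spaced at least five significance
thresholds apart (1.2 ppm ¹⁵N, 0.30 ppm ¹H against thresholds of 0.20 and
0.05), so class identity is unambiguous at zero noise and the round trip
(synthesize from known registers → classify → infer) is exact for the full
ten-oligomer panel. Jitter above the class spacing degrades assignment
loudly: unassignable peaks are reported, never dropped. The titration
generator uses the published panel parameters and protocol (0.015–0.029 mM
protein, 0.21–0.32 mM ligand, 26 × 5 μl) with a constant dilution heat and
seeded Gaussian noise.

Problem sizes used in the shipped checks — 20-model ensembles at 400
annealing + 200 polish steps, 100-replicate fit-recovery runs, 200-draw
property loops — were chosen as the smallest sizes at which the verified
properties are stable, and all generators are deterministic in their seeds.

## Known limitations

- The surrogate Φ/Ψ maps are placeholders for simulation-derived surfaces;
  absolute energies from them mean nothing.
- The annealing objective has no electrostatics, hydrogen-bond or solvation
  terms; it finds restraint-consistent, sterically clean, torsionally
  favored poses, not free-energy minima.
- Register inference is purely combinatorial on reporter classes; it cannot
  distinguish registers that predict identical class vectors, and it treats
  exchange-broadened or shifted peaks only through the loud-failure path.
- The one-site model assumes a single independent site; multi-site or
  cooperative binding, baseline integration from raw power traces, and
  ΔCp analysis are out of scope.
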