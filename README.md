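# hagroove

Hyaluronan (HA) is the extracellular matrix polysaccharide of repeating
GlcUA–GlcNAc disaccharides; TSG-6 is an inflammation-associated protein whose
isolated Link module (Link_TSG6) binds HA through a shallow eight-position
groove. `hagroove` is an R package for the computational side of studying
that recognition event with defined oligosaccharides (HA 4- to 8-mers in all
terminal variants, chondroitin, and chondroitin/HA hybrids):

- **Glycan building.** Oligosaccharide conformers are assembled from rigid
  ⁴C₁ pyranose templates (GlcUA, GlcNAc, GalNAc) joined by glycosidic
  linkages parameterized by the torsions Φ = O5–C1–O<sub>g</sub>–C<sub>x</sub>
  and Ψ = C1–O<sub>g</sub>–C<sub>x</sub>–C<sub>x+1</sub> (heavy-atom
  convention; x = 3 for β1,3, x = 4 for β1,4). Building and measuring are
  exact inverses to below 10⁻⁶ degrees.
- **Φ/Ψ energy maps.** Periodic energy grids per linkage type score every
  glycosidic angle; a conformer is *favored* when each linkage lies within a
  cutoff (default 4 kcal/mol, two 2-kcal/mol contour intervals) of the map
  minimum.
- **Complex modeling.** With the receptor held fixed, simulated annealing
  over the ligand's torsions and rigid-body placement minimizes restraint
  energy (a 3.5 Å ring-stacking restraint between sugar ring 1 and the His45
  imidazole, and an upper-bound contact between the ring-4 N-acetyl methyl
  and Ile61) plus a clash penalty and the map energy. Ensembles are filtered
  on geometry sanity, residual clashes and favored torsions, and per-ring
  receptor contacts are reported.
- **Register inference.** NMR chemical shift perturbation classes of
  reporter residues (Val62, Lys63, Ala49/Tyr78) constrain where an oligomer
  sits in the groove; the package enumerates all parity-consistent
  placements (registers), predicts each one's reporter classes, and selects
  the minimal set of registers covering the observed classes.
- **ITC analysis.** One-site titrations are simulated with
  volume-displacement bookkeeping and fitted by nonlinear least squares for
  (N, K_b, ΔH); ΔG = −RT ln K_b, TΔS = ΔH − ΔG and percent-of-reference
  affinity are derived at the printed table precision.
- **Synthetic data.** Seed-deterministic generators produce a pseudo-receptor
  fixture arranged around a known-good HA₈ pose, peak-list panels whose
  class structure encodes known registers, titration series and torsion-map
  grids, so the entire pipeline runs with no external inputs.

## Worked example

```r
library(hagroove)

## a defined octasaccharide: GlcUA at the non-reducing end
seq <- parse_glycan("HA8^AN")
seq
#> <glycan_sequence> HA8^AN: 8 residues
#>   GlcUA-GlcNAc-GlcUA-GlcNAc-GlcUA-GlcNAc-GlcUA-GlcNAc

## build at alternating basin torsions and classify on the default maps
maps <- default_torsion_maps()
tor  <- matrix(rep(c(-120, 60, -60, -120), length.out = 14), ncol = 2, byrow = TRUE)
classify_linkages(build_conformer(seq, tor), maps)
#> <favored_verdict> cutoff 4 kcal/mol: 7/7 linkages favored; model ACCEPTED

## infer binding registers of the 7-mer with GlcNAc termini from its
## observed reporter classes: two coexisting registers
infer_registers("HA7^NN", list(Val62 = c("I", "II"),
                               Lys63 = c("III", "IV"),
                               Ala49 = c("IX", "X")))
#> <register_inference> 2 register(s) selected
#>   offset -1, positions 0-6, score 10: Val62=II Lys63=III Ala49=X
#>   offset +1, positions 2-8, score 9: Val62=I Lys63=IV Ala49=IX

## simulate a noisy one-site titration and refit it
fit <- fit_one_site(simulate_titration(binding_params(0.97, 102.3e5, -6.90),
                                       itc_protocol(), noise_sd = 0.08, seed = 7))
fit
#> <binding_params> N = 0.969, Kb = 9.779e+06 1/M, dH = -6.877 kcal/mol
#>   se: N=0.00239  Kb=520000  dH=0.0267
derive_thermo(fit, reference_Kb = 54.3e5)
#> <thermo_row> dG -9.54  dH -6.88  TdS 2.66 kcal/mol;  Kd 1.02e-07 M;  180% of reference
```

The register output reads: the heptasaccharide is consistent with two
placements, one starting just off the His45 end (rings at positions 0–6,
reducing terminus at position 6, hence Ala49 class X) and one shifted two
positions toward the Arg81 end (positions 2–8, GlcUA at position 7, class
IX). The fitted association constant (K_b ≈ 98 × 10⁵ M⁻¹) recovers the
generating value within the noise, and the derived ΔG/TΔS follow from the
thermodynamic identities.

A full modeling run — ensemble generation, filtering and on-disk reports —
goes through `run_refine_model()`; `run_reproduce_tables()` recomputes the
derived thermodynamic columns and the register counts for the ten-oligomer
panel next to their reference values.

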