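Package: hagroove
Title: Modeling Hyaluronan Oligosaccharide Recognition by the TSG-6 Link Module
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how short hyaluronan (HA) and chondroitin
    oligosaccharides are recognized by the Link module of TSG-6. Builds
    three-dimensional oligosaccharide conformers from rigid 4C1 pyranose
    templates joined by glycosidic linkages parameterized by phi/psi torsions,
    scores conformers on periodic phi/psi energy maps, generates
    restraint-driven models of protein/oligosaccharide complexes by simulated
    annealing with clash and torsion-map filtering, infers oligosaccharide
    binding registers in the eight-position groove from NMR chemical shift
    perturbation classes, and fits one-site isothermal titration calorimetry
    data with full thermodynamic decomposition. Includes seed-deterministic
    synthetic data generators (receptor fixture, peak-list panels, titration
    series, torsion-map grids) so every stage can be exercised without
    external inputs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
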