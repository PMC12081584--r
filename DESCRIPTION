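Package: cholkatp
Title: Membrane-Cholesterol Effects on ATP-Kir6.2 Binding Energetics and
    Beta-Cell Electrical Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking implicit-solvent binding free energy
    decomposition of ATP binding to the Kir6.2 subunit of the ATP-sensitive
    potassium (K_ATP) channel, under varying membrane cholesterol, to the
    electrical activity of the pancreatic beta-cell. Provides structure and
    trajectory input/output (PDB, PQR, multi-frame XYZ), trajectory geometry
    (Kabsch superposition RMSD, cluster-referenced RMSF, GROMOS-style
    conformational clustering, tetramer gate-perimeter series), Shrake-Rupley
    solvent-accessible surface area and binding-energy assembly
    (solvation + Coulomb + nonpolar terms), conversion of binding energies to
    affinity constants and dissociation-constant rescaling, and an Integrated
    Oscillator Model of the beta cell with K(ATP) open-probability, burst and
    spike event detection and activity classification. A synthetic-data module
    generates every input at desk scale with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
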