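# Regenerates the packaged plain-text fixtures under inst/extdata/.
# Run from the repository root with the package installed.
library(cholkatp)

# Per-cluster binding-energy component table (with the documented Coulomb
# sign correction at 0%/Cluster1).
write_results_table(table1_components(), "inst/extdata/table1_components.csv")

# Synthetic stand-in for a Kir6.2-like tetramer: NOT deposited coordinates.
# Four chains, one CA per residue, gate glutamine at residue 173 whose four
# alpha-carbons form a square of side 15.51 A (perimeter 62.04 A ~ 60 A).
spec <- tetramer_spec(residues_per_chain = 20, gate_residue_index = 10,
                      gate_side_length = 15.51, seed = 42)
tet <- gen_toy_tetramer(spec)
tet$residue_id <- tet$residue_id + 163L   # place the gate at residue 173
write_pdb(tet, "inst/extdata/synthetic_kir_tetramer.pdb")
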