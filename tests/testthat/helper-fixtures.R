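# Shared fixtures: parsed graphs are cached per session because SMILES
# parsing shells out to OpenBabel.

.fx <- new.env(parent = emptyenv())

fx_graph <- function(smiles) {
  if (is.null(.fx[[smiles]])) .fx[[smiles]] <- smiles_to_graph(smiles)
  .fx[[smiles]]
}

fx_graphs <- function(smiles) lapply(smiles, fx_graph)

# a small mixed bag covering rings, heteroatoms, charges, stereo
MIXED_BAG <- c("CCO", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O", "C#N", "C/C=C/C",
               "N[C@@H](C)C(=O)O", "CS(=O)(=O)C", "c1ccoc1", "[NH4+]",
               "C1CCCCC1", "CC[O-]", "c1ccc2ccccc2c1", "C", "CC(=O)NC")

tiny_cfg <- function(hidden_width = 8, ...) {
  fragsol_config(hidden_width = hidden_width, ...)
}

# generator molecules used by several property tests
synth_bag <- function(n = 40, seed = 2026, ring_prob = 0.3) {
  sc <- synth_config(n_molecules = n, seed = seed, ring_prob = ring_prob)
  synth_smiles(sc)
}
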