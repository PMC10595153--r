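Package: fragsol
Title: Fragment-Pair Graph Attention Networks for Aqueous Solubility Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts aqueous solubility (logS) of drug-like molecules from SMILES
    with a fragment-pair graph attention network. Each molecule is split at every
    acyclic single bond into pairs of fragments; every fragment is embedded by
    atom-level attention layers with gated recurrent unit (GRU) state updates and a
    supernode readout, fragment embeddings are fused by summation, pair embeddings
    are averaged, and a dense head regresses logS. Includes SMILES table loading and
    cleaning, one-hot atom/bond featurization backed by OpenBabel (ChemmineOB),
    deterministic fragment enumeration, random and Bemis-Murcko scaffold dataset
    splitting, minibatch Adam training with early stopping, MAE/RMSE evaluation, a
    synthetic SMILES+logS generator with a known structure-to-label law, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
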