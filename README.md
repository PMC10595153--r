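# fragsol

Fragment-pair graph attention networks for predicting aqueous solubility
(logS) of drug-like molecules from SMILES, in pure R.

## The problem

Aqueous solubility is a gatekeeper property in drug discovery: a candidate
that cannot dissolve in water cannot reach its target, so medicinal chemists
routinely triage compound libraries by predicted logS (the base-10 logarithm
of molar solubility). `fragsol` is for computational chemists and method
developers who want a solubility regressor — and a fully inspectable
implementation of its architecture — without leaving R.

## The model

A molecule's graph `G = (V, E, X_atom, X_bond)` is cut at every acyclic
single bond. Each cut yields a fragment pair `(G_1, G_2)`; a molecule with
`m` breakable bonds yields `m` pairs. One shared (siamese) network embeds
every fragment:

* atoms start from 40-dimensional feature vectors (element, degree, charge,
  radicals, hybridization, aromaticity, hydrogens, chirality), bonds from
  10-dimensional vectors (type, conjugation, ring, stereo);
* three graph-attention layers score each neighbour
  `ε_ti = leakyrelu(s1·W a_t + s2·W a_i)`, softmax-normalize over the
  neighbourhood, aggregate messages `C_t = elu(Σ_i α_ti W a_i)`, and update
  states with a GRU, `a_t ← GRU(a_t, C_t)` (bond features enter through the
  first layer's neighbour messages);
* a supernode connected to all atoms, initialized to the mean atom state, is
  refined by two more attention+GRU rounds; its final state `y` is the
  fragment embedding;
* pair fusion is a sum, `ŷ_i = y_i1 + y_i2`; the molecule embedding is the
  mean `ŷ = (1/m) Σ_i ŷ_i`; a single affine head maps `ŷ` to logS.

Training minimizes MSE with Adam (initial learning rate 0.0025, weight decay
0.005, batch size 256, at most 300 epochs) and early-stops when validation
RMSE fails to improve for 40 epochs. Evaluation reports MAE and RMSE.
Datasets can be split randomly or by Bemis–Murcko scaffold. A whole-molecule
("null fragment") ablation runs the identical network without fragmentation.

Because no real benchmark can be bundled, the package ships a synthetic
SMILES+logS generator whose labels follow a known linear law in structural
counts (`logS = 0.5 − 0.45·#C + 0.8·#heteroatoms − 1.2·#aromatic rings +
noise`), so learning, splitting, and metrics are testable offline.

## Worked example

```r
library(fragsol)

ds  <- synth_dataset(synth_config(n_molecules = 200, seed = 7))
fit <- fragsol(logS ~ smiles, ds,
               model    = fragsol_config(hidden_width = 32),
               training = train_config(epochs = 60, patience = 20, seed = 7))
fit
#> Fragment-pair attention solubility model
#>   169 molecules (137 train / 16 val / 16 test, random split)
#>   hidden width 32, 3 atom + 2 supernode layers, 39,553 parameters
#>   trained 60 epochs (best validation epoch 50)
#>   test MAE 0.3869, RMSE 0.5994 (n = 16)

predict(fit, newdata = c("CCO", "OCC", "c1ccccc1"))
#>        CCO        OCC   c1ccccc1
#>  0.6145087  0.6145087 -4.6399003
```

The fit report reads: after cleaning (here deduplication shrank 200 noisy
records to 169 unique molecules), the model trained on 137 molecules and
reached a held-out mean absolute error of ~0.39 log units on this short
60-epoch run — against a predict-the-mean baseline of ~1.67. The two SMILES
writings of ethanol get the exact same prediction; benzene, with no acyclic
single bond, is routed through the whole-molecule path. `plot(fit)` draws the
training curve and the held-out predicted-vs-observed scatter;
`summary(fit)`, `coef(fit)`, `residuals(fit)` behave as for any R model fit.

A command-line interface wraps the same functions:

```sh
Rscript inst/scripts/fragsol synth --n 100 --seed 1 --out data.csv
Rscript inst/scripts/fragsol train --data data.csv --out run/
Rscript inst/scripts/fragsol fragment "CC(=O)Oc1ccccc1C(=O)O"   # m = 5 pairs
Rscript inst/scripts/fragsol predict --ckpt run/model.json --in smiles.txt
```

## Method vignette

`vignettes/fragsol-methods.Rmd` documents the model and its assumptions, the
featurization conventions (including the deliberately narrow stereo
handling), every tunable parameter with its default, the synthetic
generator's design, and known limitations.
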