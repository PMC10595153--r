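# Atom/bond feature encoding layout and invariants.

cfg <- feature_config()

test_that("feature widths follow the block layout", {
  expect_equal(cfg$atom_width, 15 + 8 + 1 + 1 + 6 + 1 + 5 + 1 + 2)
  expect_equal(cfg$bond_width, 4 + 1 + 1 + 4)
  expect_identical(cfg$elements,
                   c("B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "As",
                     "Se", "Br", "Te", "I", "At"))
})

test_that("the methane carbon encodes as expected", {
  g <- fx_graph("C")
  v <- g$atom_features[1, ]
  expect_equal(unname(which(v[1:15] == 1)), 2)            # element C
  expect_equal(unname(which(v[16:23] == 1)) - 1, 0)       # heavy degree 0
  expect_equal(unname(v[24]), 0)                          # charge
  expect_equal(unname(v[25]), 0)                          # radicals
  expect_equal(unname(which(v[33:37] == 1)) - 1, 4)       # four hydrogens
  expect_equal(unname(v[38]), 0)                          # achiral
  expect_equal(unname(v[39:40]), c(0, 0))                 # no parity block
})

test_that("charge and radical scalars occupy their single slots", {
  anion <- fx_graph("CC[O-]")
  expect_equal(anion$atom_features[3, "charge"], c(charge = -1))
  radical <- fx_graph("[CH3]")
  expect_equal(radical$atom_features[1, "radicals"], c(radicals = 1))
})

test_that("out-of-vocabulary elements are rejected", {
  expect_error(smiles_to_graph("[Na+]"), "unsupported element")
  expect_error(featurize_atom(list(element = "Na", degree = 0, charge = 1,
                                   radicals = 0, hybridization = "other",
                                   aromatic = FALSE, n_h = 0, chiral = FALSE,
                                   chirality = NA)),
               "unsupported element")
})

test_that("encoding overflow raises errors", {
  base <- list(element = "C", degree = 0, charge = 0, radicals = 0,
               hybridization = "sp3", aromatic = FALSE, n_h = 0,
               chiral = FALSE, chirality = NA)
  too_many_bonds <- modifyList(base, list(degree = 8))
  expect_error(featurize_atom(too_many_bonds), "degree")
  too_many_h <- modifyList(base, list(n_h = 5))
  expect_error(featurize_atom(too_many_h), "hydrogen")
})

test_that("bond vectors encode type, conjugation, ring and stereo", {
  ethane <- fx_graph("CC")
  v <- ethane$bond_features[1, ]
  expect_equal(unname(v), c(1, 0, 0, 0, 0, 0, 0, 1, 0, 0))  # single, StereoNone
  benz <- fx_graph("c1ccccc1")
  expect_true(all(benz$bond_features[, "type_aromatic"] == 1))
  expect_true(all(benz$bond_features[, "ring"] == 1))
  carbonyl <- fx_graph("C=O")
  expect_equal(unname(carbonyl$bond_features[1, 1:4]), c(0, 1, 0, 0))
})

test_that("one-hot blocks are exactly hot across a molecule corpus", {
  for (s in c(MIXED_BAG, synth_bag(25, seed = 31))) {
    g <- fx_graph(s)
    X <- g$atom_features
    expect_true(all(rowSums(X[, 1:15, drop = FALSE]) == 1), label = s)
    expect_true(all(rowSums(X[, 16:23, drop = FALSE]) == 1), label = s)
    expect_true(all(rowSums(X[, 26:31, drop = FALSE]) == 1), label = s)
    expect_true(all(rowSums(X[, 33:37, drop = FALSE]) == 1), label = s)
    expect_true(all(rowSums(X[, 39:40, drop = FALSE]) <= 1), label = s)
    E <- g$bond_features
    if (nrow(E) > 0) {
      expect_true(all(rowSums(E[, 1:4, drop = FALSE]) == 1), label = s)
      expect_true(all(rowSums(E[, 7:10, drop = FALSE]) == 1), label = s)
    }
  }
})

test_that("equivalent SMILES writings give isomorphic graphs", {
  multiset <- function(g) sort(apply(g$atom_features, 1, paste, collapse = ","))
  bondset <- function(g) sort(apply(g$bond_features, 1, paste, collapse = ","))
  a <- fx_graph("CCO"); b <- fx_graph("OCC")
  expect_identical(multiset(a), multiset(b))
  expect_identical(bondset(a), bondset(b))
})
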