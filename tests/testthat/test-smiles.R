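# SMILES parsing, validity checking, stereo annotations, canonicalization.

test_that("simple molecules produce the expected graphs", {
  g <- fx_graph("CCO")
  expect_equal(g$n_atoms, 3)
  expect_equal(nrow(g$bonds), 2)
  b <- fx_graph("c1ccccc1")
  expect_equal(b$n_atoms, 6)
  expect_equal(nrow(b$bonds), 6)
  expect_true(all(b$bond_order == "aromatic"))
  expect_true(all(b$bond_ring))
  expect_true(all(b$atom_info$aromatic))
})

test_that("malformed SMILES raise validity errors naming the input", {
  expect_error(smiles_to_graph("C("), "invalid SMILES 'C\\('")
  expect_error(smiles_to_graph("C1CC"), "ring-closure")
  expect_error(smiles_to_graph("xyz"), "invalid SMILES")
  expect_error(smiles_to_graph("C)C"), "unmatched")
  expect_error(smiles_to_graph("C=#C"), "consecutive bond symbols")
})

test_that("non-strict parsing flags bad entries without failing the batch", {
  expect_warning(out <- parse_smiles(c("CCO", "C(", "CC"), strict = FALSE),
                 "invalid SMILES")
  expect_false(is.null(out[[1]]))
  expect_null(out[[2]])
  expect_false(is.null(out[[3]]))
})

test_that("tetrahedral parity tags map to the chirality-type slots", {
  ccw <- smiles_to_graph("N[C@H](C)C(=O)O")
  cw <- smiles_to_graph("N[C@@H](C)C(=O)O")
  expect_true(ccw$atom_info$chiral[2])
  expect_equal(ccw$atom_info$chirality[2], "anticlockwise")
  expect_equal(cw$atom_info$chirality[2], "clockwise")
  expect_equal(unname(ccw$atom_features[2, 39:40]), c(1, 0))
  expect_equal(unname(cw$atom_features[2, 39:40]), c(0, 1))
  # achiral atoms keep an all-zero parity block but a zero chiral flag
  expect_true(all(ccw$atom_features[-2, 38:40] == 0))
})

test_that("double-bond geometry resolves to E/Z only when specified", {
  trans <- fx_graph("C/C=C/C")
  expect_equal(trans$bond_info$stereo, c("none", "E", "none"))
  cis <- fx_graph("C/C=C\\C")
  expect_equal(cis$bond_info$stereo, c("none", "Z", "none"))
  plain <- fx_graph("CC=CC")
  expect_true(all(plain$bond_info$stereo == "none"))
})

test_that("canonical SMILES identifies equivalent writings", {
  can <- canonical_smiles(c("CCO", "OCC", "C(C)O", "c1ccccc1", "C1=CC=CC=C1"))
  expect_equal(can[1], can[2])
  expect_equal(can[1], can[3])
  expect_equal(can[4], can[5])
  expect_true(is.na(canonical_smiles("C1CC")))
})

test_that("rewrite_smiles produces equivalent alternative writings", {
  for (s in c("CCO", "CC(=O)Oc1ccccc1C(=O)O", "c1ccc2ccccc2c1", "CC(C)CO")) {
    g <- fx_graph(s)
    for (sd in 1:3) {
      alt <- rewrite_smiles(g, seed = sd)
      expect_equal(canonical_smiles(alt), g$canonical, label = alt)
    }
  }
})

test_that("hydrogen counts come from the added-hydrogen conversion", {
  g <- fx_graph("CC(=O)NC")  # N-methylacetamide
  expect_equal(g$atom_info$n_h, c(3, 0, 0, 1, 3))
  pyrrole <- fx_graph("c1cc[nH]c1")
  expect_equal(g$atom_info$n_h[4], 1)
  expect_equal(sum(pyrrole$atom_info$n_h), 5)
})
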