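# Fragment-pair enumeration at acyclic single bonds.

test_that("known molecules have the expected breakable-bond counts", {
  expect_equal(nrow(breakable_bonds(fx_graph("CC"))), 1)
  expect_equal(nrow(breakable_bonds(fx_graph("c1ccccc1"))), 0)
  expect_equal(nrow(breakable_bonds(fx_graph("CCO"))), 2)
  expect_equal(nrow(breakable_bonds(fx_graph("CC(=O)Oc1ccccc1C(=O)O"))), 5)
  expect_equal(length(fragment_pairs(fx_graph("CC(=O)Oc1ccccc1C(=O)O"))), 5)
  expect_equal(length(fragment_pairs(fx_graph("C"))), 0)
})

test_that("splitting conserves atoms and copies features verbatim", {
  e <- fx_graph("CC")
  p <- split_on_bond(e, 1)
  expect_equal(p$frag1$n_atoms, 1)
  expect_equal(p$frag2$n_atoms, 1)
  expect_equal(nrow(p$frag1$bonds), 0)
  pr <- fx_graph("CCC")
  q <- split_on_bond(pr, 1)
  expect_equal(sort(c(q$frag1$n_atoms, q$frag2$n_atoms)), c(1, 2))
  for (s in c("CC(=O)Oc1ccccc1C(=O)O", synth_bag(20, seed = 77))) {
    g <- fx_graph(s)
    for (p in fragment_pairs(g)) {
      expect_length(intersect(p$map1, p$map2), 0)
      expect_setequal(c(p$map1, p$map2), seq_len(g$n_atoms))
      expect_true(p$endpoints["u"] %in% p$map1)
      expect_true(p$endpoints["v"] %in% p$map2)
      expect_identical(p$frag1$atom_features,
                       g$atom_features[p$map1, , drop = FALSE])
      expect_identical(p$frag2$atom_features,
                       g$atom_features[p$map2, , drop = FALSE])
      # bonds partition the parent's bonds minus the broken one
      expect_equal(nrow(p$frag1$bonds) + nrow(p$frag2$bonds),
                   nrow(g$bonds) - 1)
    }
  }
})

test_that("pair counts match an independent ring-membership oracle", {
  # oracle: a bond is in a ring iff its endpoints stay connected without it
  oracle_count <- function(g) {
    nb <- nrow(g$bonds)
    if (nb == 0) return(0L)
    n <- 0L
    for (b in seq_len(nb)) {
      if (g$bond_order[b] != "single") next
      rest <- g$bonds[-b, , drop = FALSE]
      ig <- igraph::make_empty_graph(g$n_atoms, directed = FALSE)
      if (nrow(rest) > 0) ig <- igraph::add_edges(ig, t(rest))
      d <- igraph::distances(ig, v = g$bonds[b, "u"], to = g$bonds[b, "v"])
      if (is.infinite(d[1, 1])) n <- n + 1L
    }
    n
  }
  for (s in c("CCO", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O",
              synth_bag(40, seed = 123))) {
    g <- fx_graph(s)
    expect_equal(length(fragment_pairs(g)), oracle_count(g), label = s)
  }
})

test_that("enumeration is deterministic", {
  g <- fx_graph("CC(=O)Oc1ccccc1C(=O)O")
  expect_identical(fragment_pairs(g), fragment_pairs(g))
})

test_that("disconnected molecules take the whole-molecule path", {
  g <- smiles_to_graph("CC.CC")
  expect_length(fragment_pairs(g), 0)
  cfg <- tiny_cfg()
  params <- fragsol_params(cfg, seed = 1)
  expect_identical(fragsol_forward(g, params, cfg),
                   fragsol_forward(g, params, cfg, null_fragment = TRUE))
})

test_that("non-breakable bonds are refused", {
  benz <- fx_graph("c1ccccc1")
  expect_error(split_on_bond(benz, 1), "not a breakable")
  ethene <- fx_graph("C=C")
  expect_error(split_on_bond(ethene, 1), "not a breakable")
})
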