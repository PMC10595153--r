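# Network forward/backward mechanics.

cfg8 <- fragsol_config(hidden_width = 8, dropout = 0)

test_that("forward returns one finite prediction per molecule", {
  params <- fragsol_params(cfg8, seed = 2)
  gs <- fx_graphs(c("CCO", "c1ccccc1", "C"))
  pred <- fragsol_forward(gs, params, cfg8)
  expect_length(pred, 3)
  expect_true(all(is.finite(pred)))
})

test_that("parameter count depends only on the configuration", {
  p <- fragsol_params(cfg8, seed = 1)
  expected <- 40 * 8 + 50 * 8 +                       # input projections
    (3 + 2) * (8 * 8 + 8 + 8 + 6 * 8 * 8 + 3 * 8) +  # attention + GRU blocks
    8 + 1                                             # head
  expect_equal(fragsol:::fs_param_count(p), expected)
})

test_that("attention weights sum to one over every neighbourhood", {
  params <- fragsol_params(cfg8, seed = 4)
  gs <- fx_graphs(c("CC(=O)Oc1ccccc1C(=O)O", "CCO"))
  pred <- fragsol_forward(gs, params, cfg8, collect_attention = TRUE)
  att <- attr(pred, "attention")
  expect_gt(length(att), 0)
  for (layer in att) {
    sums <- tapply(layer$weights, layer$group, sum)
    expect_true(all(abs(sums - 1) < 1e-6))
  }
  # a target with a single neighbour gets weight exactly 1
  ethane_att <- attr(fragsol_forward(fx_graph("CC"), params, cfg8,
                                     null_fragment = TRUE,
                                     collect_attention = TRUE), "attention")
  expect_true(all(abs(ethane_att$atom1$weights - 1) < 1e-12))
})

test_that("zero attention parameters give uniform weights and zero context", {
  params <- fragsol_params(cfg8, seed = 4)
  params$A1.W[] <- 0
  params$A1.s1[] <- 0
  params$A1.s2[] <- 0
  g <- fx_graph("CC(C)C")  # central atom with three neighbours
  batch <- fragsol:::fs_make_batch(list(
    fragsol:::fs_compile_molecule(g, null_fragment = TRUE)))
  out <- fragsol:::fs_forward(batch, params, cfg8, keep_cache = TRUE,
                              collect_attention = TRUE)
  w <- out$attention$atom1$weights
  grp <- out$attention$atom1$group
  expect_true(all(abs(w - 1 / table(grp)[as.character(grp)]) < 1e-12))
  expect_true(all(out$cache$A[[1]]$msg == 0))  # C = elu(0) = 0
})

test_that("isolated atoms receive a zero context vector", {
  params <- fragsol_params(cfg8, seed = 4)
  batch <- fragsol:::fs_make_batch(list(
    fragsol:::fs_compile_molecule(fx_graph("C"))))
  out <- fragsol:::fs_forward(batch, params, cfg8, keep_cache = TRUE)
  for (l in seq_len(cfg8$atom_layers))
    expect_true(all(out$cache$A[[l]]$msg == 0))
})

test_that("the GRU cell matches its closed form at zero inputs", {
  params <- fragsol_params(cfg8, seed = 9)
  params$A1.bz <- stats::rnorm(8)
  params$A1.br <- stats::rnorm(8)
  params$A1.bh <- stats::rnorm(8)
  x <- matrix(0, 3, 8)
  h <- matrix(0, 3, 8)
  out <- fragsol:::gru_forward(params, "A1.", x, h)$out
  zg <- 1 / (1 + exp(-params$A1.bz))
  expected <- zg * tanh(params$A1.bh)   # (1-z)*0 + z*tanh(bh)
  for (r in 1:3) expect_equal(unname(out[r, ]), unname(expected),
                              tolerance = 1e-12)
})

test_that("supernode state initializes to the mean of atom states", {
  params <- fragsol_params(cfg8, seed = 5)
  batch <- fragsol:::fs_make_batch(list(
    fragsol:::fs_compile_molecule(fx_graph("CC"), null_fragment = TRUE)))
  out <- fragsol:::fs_forward(batch, params, cfg8, keep_cache = TRUE)
  expect_equal(out$cache$g0[1, ], colMeans(out$cache$A_L), tolerance = 1e-12)
  single <- fragsol:::fs_make_batch(list(
    fragsol:::fs_compile_molecule(fx_graph("C"))))
  outs <- fragsol:::fs_forward(single, params, cfg8, keep_cache = TRUE)
  expect_equal(outs$cache$g0[1, ], outs$cache$A_L[1, ], tolerance = 1e-12)
})

test_that("pair fusion is a sum, pair pooling a mean, the head affine", {
  params <- fragsol_params(cfg8, seed = 6)
  g <- fx_graph("CCO")   # two pairs, four fragments
  batch <- fragsol:::fs_make_batch(list(fragsol:::fs_compile_molecule(g)))
  out <- fragsol:::fs_forward(batch, params, cfg8, keep_cache = TRUE)
  y <- out$cache$y
  expect_equal(out$cache$ypair[1, ], y[1, ] + y[2, ], tolerance = 1e-12)
  expect_equal(out$cache$ypair[2, ], y[3, ] + y[4, ], tolerance = 1e-12)
  expect_equal(out$cache$ymol[1, ],
               (out$cache$ypair[1, ] + out$cache$ypair[2, ]) / 2,
               tolerance = 1e-12)
  expect_equal(out$pred,
               drop(out$cache$ymol %*% params$w) + params$b,
               tolerance = 1e-12)
})

test_that("predictions are invariant to how the molecule is written", {
  params <- fragsol_params(cfg8, seed = 7)
  expect_equal(fragsol_forward(fx_graph("CCO"), params, cfg8),
               fragsol_forward(fx_graph("OCC"), params, cfg8),
               tolerance = 1e-10)
  for (s in synth_bag(10, seed = 55)) {
    g <- fx_graph(s)
    alt <- smiles_to_graph(rewrite_smiles(g, seed = 11))
    expect_equal(fragsol_forward(g, params, cfg8),
                 fragsol_forward(alt, params, cfg8),
                 tolerance = 1e-8, label = s)
  }
})

test_that("molecules without breakable bonds fall back to the whole-molecule path", {
  params <- fragsol_params(cfg8, seed = 8)
  benz <- fx_graph("c1ccccc1")
  expect_identical(fragsol_forward(benz, params, cfg8),
                   fragsol_forward(benz, params, cfg8, null_fragment = TRUE))
  single <- fx_graph("C")
  expect_identical(fragsol_forward(single, params, cfg8),
                   fragsol_forward(single, params, cfg8,
                                   null_fragment = TRUE))
})

test_that("evaluation-mode forward is deterministic", {
  cfgd <- fragsol_config(hidden_width = 8, dropout = 0.2)
  params <- fragsol_params(cfgd, seed = 10)
  gs <- fx_graphs(c("CCO", "CC(=O)O"))
  expect_identical(fragsol_forward(gs, params, cfgd),
                   fragsol_forward(gs, params, cfgd))
})

test_that("analytic gradients match central finite differences", {
  cfg4 <- fragsol_config(hidden_width = 4, atom_layers = 2, mol_layers = 2,
                         dropout = 0)
  params <- fragsol_params(cfg4, seed = 3)
  gs <- fx_graphs(c("CCO", "c1ccccc1C", "C"))
  labels <- c(0.4, -2.0, 0.05)
  compiled <- lapply(gs, fragsol:::fs_compile_molecule)
  batch <- fragsol:::fs_make_batch(compiled)
  lossfun <- function(p)
    mean((fragsol:::fs_forward(batch, p, cfg4)$pred - labels)^2)
  fwd <- fragsol:::fs_forward(batch, params, cfg4, keep_cache = TRUE)
  grads <- fragsol:::fs_backward(batch, params, cfg4, fwd,
                                 dpred = 2 * (fwd$pred - labels) / 3)
  h <- 1e-5
  set.seed(14)
  for (nm in names(params)) {
    for (i in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + h
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - h
      num <- (lossfun(p1) - lossfun(p2)) / (2 * h)
      ana <- grads[[nm]][i]
      expect_lt(abs(num - ana), 1e-6 + 1e-3 * (abs(num) + abs(ana)),
                label = sprintf("%s[%d]", nm, i))
    }
  }
})

test_that("checkpoints round-trip and refuse mismatched featurization", {
  params <- fragsol_params(cfg8, seed = 12)
  f <- withr::local_tempfile(fileext = ".json")
  write_fragsol(params, f, cfg = cfg8)
  back <- read_fragsol(f)
  expect_equal(back$params$Q, params$Q, tolerance = 1e-12)
  expect_equal(back$config$hidden_width, 8)
  gs <- fx_graph("CCO")
  expect_equal(fragsol_forward(gs, back$params, back$config),
               fragsol_forward(gs, params, cfg8), tolerance = 1e-12)
  txt <- readLines(f)
  writeLines(gsub("\"feature_descriptor\":\"v1", "\"feature_descriptor\":\"v0",
                  txt), f)
  expect_error(read_fragsol(f), "featurization does not match")
})
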