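# Metrics, splits, and the training loop contract.

test_that("metrics match hand computations", {
  expect_equal(unclass(eval_metrics(c(1, 2), c(1, 2)))[c("mae", "rmse")],
               list(mae = 0, rmse = 0))
  m <- eval_metrics(c(0, 2), c(1, 1))
  expect_equal(m$mae, 1); expect_equal(m$rmse, 1)
  m2 <- eval_metrics(c(1, 3), c(0, 0))
  expect_equal(m2$mae, 2)
  expect_equal(m2$rmse, sqrt(5))
  expect_equal(m2$n, 2)
})

test_that("metrics reject malformed input", {
  expect_error(eval_metrics(1:3, 1:2), "length mismatch")
  expect_error(eval_metrics(numeric(0), numeric(0)), "empty")
})

test_that("RMSE dominates MAE, with equality only for equal errors", {
  set.seed(60)
  for (i in 1:20) {
    p <- rnorm(50); o <- rnorm(50)
    m <- eval_metrics(p, o)
    expect_gte(m$rmse, m$mae - 1e-12)
  }
  eq <- eval_metrics(c(1, -1, 1), c(0, 0, 0))
  expect_equal(eq$rmse, eq$mae)
})

test_that("random splits have floor/remainder sizes and reproduce", {
  sp <- split_spec("random", c(0.8, 0.1, 0.1), seed = 42)
  s1 <- random_split(10, sp)
  expect_equal(lengths(s1), c(train = 8L, val = 1L, test = 1L))
  expect_identical(s1, random_split(10, sp))
  expect_setequal(unlist(s1), 1:10)
  s2 <- random_split(10, split_spec("random", c(0.8, 0.1, 0.1), seed = 43))
  expect_false(identical(s1, s2))
  expect_error(random_split(2, sp), "at least 3")
  expect_error(split_spec("random", c(0.5, 0.5, 0.5)), "summing to 1")
})

test_that("scaffold groups never straddle partitions", {
  smiles <- c("Cc1ccccc1", "CCc1ccccc1", "OCc1ccccc1",   # benzene scaffold
              "Cc1ccncc1", "CCc1ccncc1",                 # pyridine scaffold
              "CC1CCCCC1", "CCC1CCCCC1",                 # cyclohexane
              "CCO", "CCC", "CCN")                       # acyclic
  idx <- scaffold_split(smiles, split_spec("scaffold"))
  keys <- vapply(fx_graphs(smiles), murcko_scaffold, "")
  part <- integer(10)
  part[idx$train] <- 1; part[idx$val] <- 2; part[idx$test] <- 3
  for (k in unique(keys))
    expect_length(unique(part[keys == k]), 1)
  expect_true(all(part[keys == ""] == 1))  # acyclic molecules train first
  expect_identical(idx, scaffold_split(smiles, split_spec("scaffold")))
})

test_that("ten distinct scaffolds split 8/1/1 under the greedy assignment", {
  smiles <- c("Cc1ccccc1", "Cc1ccncc1", "CC1CCCCC1", "CC1CCCC1",
              "Cc1ccc2ccccc2c1", "CC1CCNCC1", "Cc1cccnc1C", "CC1CCOC1",
              "Cc1ccco1", "Cc1cccs1")
  idx <- scaffold_split(smiles, split_spec("scaffold"))
  expect_equal(lengths(idx), c(train = 8L, val = 1L, test = 1L))
})

test_that("a flat validation metric halts exactly patience epochs after best", {
  ds <- synth_dataset(synth_config(n_molecules = 8, seed = 3, noise_sigma = 0,
                                   max_chain = 4))
  gs <- fx_graphs(ds$smiles)
  cfg <- tiny_cfg()
  params <- fragsol_params(cfg, seed = 1)
  tc <- train_config(epochs = 50, lr = 0, patience = 3, seed = 2)
  fit <- fragsol_train(gs, ds$logS, gs, ds$logS, params, cfg, tc,
                       init_bias = FALSE)
  expect_equal(fit$best_epoch, 1)         # lr 0: nothing ever improves
  expect_equal(fit$epochs_run, 1 + 3)     # best epoch + patience
  expect_true(all(!fit$history$best[-1]))
})

test_that("zero learning rate is a no-op on the parameters", {
  ds <- synth_dataset(synth_config(n_molecules = 6, seed = 4, max_chain = 4))
  gs <- fx_graphs(ds$smiles)
  cfg <- tiny_cfg()
  params <- fragsol_params(cfg, seed = 5)
  tc <- train_config(epochs = 3, lr = 0, weight_decay = 0, patience = 3,
                     seed = 2)
  fit <- fragsol_train(gs, ds$logS, gs, ds$logS, params, cfg, tc,
                       init_bias = FALSE)
  for (nm in names(params))
    expect_equal(fit$params[[nm]], params[[nm]], tolerance = 0)
})

test_that("returned parameters are the best-validation ones, not the last", {
  ds <- synth_dataset(synth_config(n_molecules = 12, seed = 6, max_chain = 5))
  gs <- fx_graphs(ds$smiles)
  cfg <- tiny_cfg()
  params <- fragsol_params(cfg, seed = 7)
  tc <- train_config(epochs = 12, lr = 0.01, weight_decay = 0, patience = 12,
                     seed = 3)
  fit <- fragsol_train(gs[1:8], ds$logS[1:8], gs[9:12], ds$logS[9:12],
                       params, cfg, tc)
  pred <- fragsol_forward(gs[9:12], fit$params, cfg)
  rmse <- eval_metrics(pred, ds$logS[9:12])$rmse
  expect_equal(rmse, fit$best_val_rmse, tolerance = 1e-10)
  expect_equal(rmse, min(fit$history$val_rmse), tolerance = 1e-10)
})

test_that("a non-finite loss aborts with the epoch named", {
  ds <- synth_dataset(synth_config(n_molecules = 6, seed = 8, max_chain = 4))
  gs <- fx_graphs(ds$smiles)
  cfg <- tiny_cfg()
  params <- fragsol_params(cfg, seed = 9)
  labels <- ds$logS
  labels[1] <- NaN
  tc <- train_config(epochs = 3, patience = 3, seed = 2)
  expect_error(
    fragsol_train(gs, labels, gs, ds$logS, params, cfg, tc,
                  init_bias = FALSE),
    "diverged.*epoch 1")
})

test_that("seeded training is exactly reproducible", {
  ds <- synth_dataset(synth_config(n_molecules = 10, seed = 10, max_chain = 4))
  gs <- fx_graphs(ds$smiles)
  cfg <- tiny_cfg()
  params <- fragsol_params(cfg, seed = 11)
  tc <- train_config(epochs = 4, patience = 4, seed = 12)
  f1 <- fragsol_train(gs[1:7], ds$logS[1:7], gs[8:10], ds$logS[8:10],
                      params, cfg, tc)
  f2 <- fragsol_train(gs[1:7], ds$logS[1:7], gs[8:10], ds$logS[8:10],
                      params, cfg, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})
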