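# User-facing model fit: formula + data in, classed fit object out.

#' Fit a fragment-pair solubility model
#'
#' End-to-end pipeline: clean the table, parse SMILES into featurized graphs,
#' split into train/validation/test, train the fragment-pair attention network
#' with Adam and early stopping, and evaluate MAE/RMSE on the held-out test
#' set.
#'
#' @param formula A formula naming the label and SMILES columns of `data`,
#'   e.g. `logS ~ smiles`.
#' @param data Data frame holding those columns.
#' @param split A [split_spec()] (random 8:1:1 by default).
#' @param model A [fragsol_config()].
#' @param training A [train_config()].
#' @param null_fragment If `TRUE`, fit the whole-molecule ablation variant
#'   (no fragmentation).
#' @param clean Clean the table first (drop missing labels, unparseable
#'   SMILES, canonical-structure duplicates); see [clean_records()].
#' @param seed Seed for parameter initialization.
#' @param verbose Per-epoch progress to stderr.
#' @return An object of class `fragsol`; see [predict.fragsol()],
#'   [summary.fragsol()], [plot.fragsol()].
#' @examples
#' \donttest{
#' ds <- synth_dataset(synth_config(n_molecules = 60, seed = 1))
#' fit <- fragsol(logS ~ smiles, ds,
#'                model = fragsol_config(hidden_width = 16),
#'                training = train_config(epochs = 3))
#' predict(fit, newdata = c("CCO", "c1ccccc1"))
#' }
#' @export
fragsol <- function(formula = logS ~ smiles, data,
                    split = split_spec("random"),
                    model = fragsol_config(),
                    training = train_config(),
                    null_fragment = FALSE, clean = TRUE, seed = 1,
                    verbose = FALSE) {
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  vars <- all.vars(formula)
  if (length(vars) != 2)
    stop("formula must have the form <label> ~ <smiles>", call. = FALSE)
  label_col <- vars[1]
  smiles_col <- vars[2]
  missing <- setdiff(vars, names(data))
  if (length(missing) > 0)
    stop(sprintf("column%s %s not found in data",
                 if (length(missing) > 1) "s" else "",
                 paste(sprintf("'%s'", missing), collapse = ", ")),
         call. = FALSE)
  records <- data.frame(smiles = as.character(data[[smiles_col]]),
                        logS = as.numeric(data[[label_col]]),
                        stringsAsFactors = FALSE)
  if (clean) records <- clean_records(records)
  if (nrow(records) < 3) stop("fewer than 3 usable records", call. = FALSE)
  graphs <- parse_smiles(records$smiles)
  idx <- if (split$mode == "random") random_split(nrow(records), split)
         else scaffold_split(graphs, split)
  if (length(idx$val) == 0 || length(idx$test) == 0)
    stop("split produced an empty validation or test partition", call. = FALSE)
  cfgf <- feature_config()
  params0 <- fragsol_params(model, seed = seed,
                            n_atom_feat = cfgf$atom_width,
                            n_bond_feat = cfgf$bond_width)
  tr <- fragsol_train(graphs[idx$train], records$logS[idx$train],
                      graphs[idx$val], records$logS[idx$val],
                      params0, model, training,
                      null_fragment = null_fragment, verbose = verbose)
  test_pred <- fragsol_forward(graphs[idx$test], tr$params, model,
                               null_fragment = null_fragment)
  metrics <- eval_metrics(test_pred, records$logS[idx$test])
  structure(list(
    call = match.call(), formula = formula,
    config = model, train_config = training, split = split,
    split_index = idx, records = records,
    params = tr$params, history = tr$history, best_epoch = tr$best_epoch,
    epochs_run = tr$epochs_run,
    metrics = metrics, test_pred = test_pred,
    null_fragment = null_fragment, seed = seed,
    feature_descriptor = cfgf$descriptor,
    version = as.character(utils::packageVersion("fragsol"))),
    class = "fragsol")
}

#' @export
print.fragsol <- function(x, ...) {
  cat("Fragment-pair attention solubility model",
      if (x$null_fragment) "(whole-molecule ablation)" else "", "\n")
  cat(sprintf("  %d molecules (%d train / %d val / %d test, %s split)\n",
              nrow(x$records), length(x$split_index$train),
              length(x$split_index$val), length(x$split_index$test),
              x$split$mode))
  cat(sprintf("  hidden width %d, %d atom + %d supernode layers, %s parameters\n",
              x$config$hidden_width, x$config$atom_layers,
              x$config$mol_layers,
              format(fs_param_count(x$params), big.mark = ",")))
  cat(sprintf("  trained %d epochs (best validation epoch %d)\n",
              x$epochs_run, x$best_epoch))
  cat(sprintf("  test MAE %.4f, RMSE %.4f (n = %d)\n", x$metrics$mae,
              x$metrics$rmse, x$metrics$n))
  invisible(x)
}

#' @export
summary.fragsol <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object,
                 residual_summary = summary(res),
                 val_curve = object$history[, c("epoch", "val_rmse")]),
            class = "summary.fragsol")
}

#' @export
print.summary.fragsol <- function(x, ...) {
  print(x$fit)
  cat("\nTest-set residuals (observed - predicted):\n")
  print(x$residual_summary)
  invisible(x)
}

#' Predict logS for new molecules
#'
#' @param object A fitted [fragsol()] model.
#' @param newdata Character vector of SMILES, or a data frame with the SMILES
#'   column named in the fitting formula. Defaults to the test partition.
#' @param ... Unused.
#' @return Numeric vector of predicted logS values named by the input SMILES.
#'   Unparseable inputs yield `NA` with a warning.
#' @export
predict.fragsol <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    return(stats::setNames(object$test_pred,
                           object$records$smiles[object$split_index$test]))
  smiles <- if (is.character(newdata)) newdata
            else as.character(newdata[[all.vars(object$formula)[2]]])
  graphs <- parse_smiles(smiles, strict = FALSE)
  ok <- !vapply(graphs, is.null, TRUE)
  pred <- rep(NA_real_, length(smiles))
  if (any(ok))
    pred[ok] <- fragsol_forward(graphs[ok], object$params, object$config,
                                null_fragment = object$null_fragment)
  stats::setNames(pred, smiles)
}

#' @export
fitted.fragsol <- function(object, ...) {
  idx <- object$split_index$train
  stats::setNames(
    fragsol_forward(parse_smiles(object$records$smiles[idx]), object$params,
                    object$config, null_fragment = object$null_fragment),
    object$records$smiles[idx])
}

#' @export
residuals.fragsol <- function(object, ...) {
  idx <- object$split_index$test
  stats::setNames(object$records$logS[idx] - object$test_pred,
                  object$records$smiles[idx])
}

#' Output-layer coefficients
#'
#' The affine head mapping the molecule embedding to logS: `F` weights plus
#' the intercept. The full parameter set lives in `object$params`.
#'
#' @param object A fitted [fragsol()] model.
#' @param ... Unused.
#' @return Named numeric vector of length `hidden_width + 1`.
#' @export
coef.fragsol <- function(object, ...) {
  w <- drop(object$params$w)
  stats::setNames(c(w, object$params$b),
                  c(paste0("y", seq_along(w)), "(Intercept)"))
}

#' Diagnostic plots for a fitted model
#'
#' Two panels: the training curve (train MSE and validation RMSE per epoch,
#' best epoch marked) and held-out predictions against observed labels.
#'
#' @param x A fitted [fragsol()] model.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.fragsol <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  h <- x$history
  graphics::plot(h$epoch, sqrt(h$train_mse), type = "l", col = "grey40",
                 xlab = "epoch", ylab = "error (log units)",
                 main = "training curve",
                 ylim = range(c(sqrt(h$train_mse), h$val_rmse)), ...)
  graphics::lines(h$epoch, h$val_rmse, col = "firebrick")
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", legend = c("train RMSE", "val RMSE"),
                   col = c("grey40", "firebrick"), lty = 1, bty = "n")
  obs <- x$records$logS[x$split_index$test]
  graphics::plot(obs, x$test_pred, xlab = "observed logS",
                 ylab = "predicted logS", main = "held-out test set",
                 pch = 19, col = grDevices::adjustcolor("steelblue", 0.7), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
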