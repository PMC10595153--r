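# Regression metrics: mean absolute error and root-mean-square error over a
# prediction/label set.

#' MAE and RMSE of predictions
#'
#' `MAE = (1/n) * sum(|pred - obs|)` and
#' `RMSE = sqrt((1/n) * sum((pred - obs)^2))`. RMSE >= MAE always, with
#' equality exactly when all absolute errors are equal.
#'
#' @param pred,obs Equal-length numeric vectors.
#' @return An object of class `fragsol_metrics`: list with `mae`, `rmse`, `n`.
#' @examples
#' eval_metrics(c(0, 2), c(1, 1))  # MAE 1, RMSE 1
#' eval_metrics(c(1, 3), c(0, 0))  # MAE 2, RMSE sqrt(5)
#' @export
eval_metrics <- function(pred, obs) {
  if (length(pred) != length(obs))
    stop(sprintf("length mismatch: %d predictions vs %d labels",
                 length(pred), length(obs)), call. = FALSE)
  if (length(pred) == 0) stop("empty prediction set", call. = FALSE)
  err <- pred - obs
  structure(list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)),
                 n = length(err)),
            class = "fragsol_metrics")
}

#' @export
print.fragsol_metrics <- function(x, ...) {
  cat(sprintf("MAE %.4f  RMSE %.4f  (n = %d)\n", x$mae, x$rmse, x$n))
  invisible(x)
}
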