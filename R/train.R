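# Minibatch MSE training with Adam, decoupled-from-nothing classic L2 weight
# decay folded into the gradient, and early stopping on validation RMSE.

#' Training configuration
#'
#' Defaults are the package's standard training recipe: 300 epochs, batch 256,
#' Adam with initial learning rate 0.0025 and weight decay 0.005, early-stop
#' patience 40 epochs.
#'
#' @param epochs Maximum epochs.
#' @param batch_size Minibatch size (the last short batch is kept).
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty added to weight-matrix gradients (biases and
#'   the head intercept are exempt).
#' @param patience Early stopping: halt when validation RMSE has not improved
#'   for this many consecutive epochs.
#' @param seed Seed driving minibatch shuffles and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 300, batch_size = 256, lr = 0.0025,
                         weight_decay = 0.005, patience = 40, seed = 1) {
  stopifnot(epochs >= 1, batch_size >= 1, lr >= 0, weight_decay >= 0,
            patience >= 1, patience <= epochs)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay, patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  decay_exempt <- grepl("(^b$|\\.b[zrh]$)", names(params))
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (weight_decay > 0 && !decay_exempt[match(nm, names(params))])
      g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- 0.9 * state$m[[nm]] + (1 - 0.9) * g
    state$v[[nm]] <- 0.999 * state$v[[nm]] + (1 - 0.999) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    upd <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    if (is.matrix(upd)) dimnames(upd) <- NULL
    params[[nm]] <- upd
  }
  list(params = params, state = state)
}

#' Train the network
#'
#' Minibatch mean-squared-error minimization with Adam. After every epoch the
#' validation RMSE is computed in evaluation mode; the parameters of the best
#' validation epoch are kept, and training halts once the validation RMSE has
#' not (strictly) improved for `tc$patience` consecutive epochs, or at
#' `tc$epochs`. The whole run is reproducible from `tc$seed`.
#'
#' @param train_graphs,train_labels Training molecules (list of `mol_graph`)
#'   and their logS labels.
#' @param val_graphs,val_labels Validation set, monitored for early stopping.
#' @param params Initial [fragsol_params()].
#' @param cfg The [fragsol_config()].
#' @param tc A [train_config()].
#' @param null_fragment Train the whole-molecule (no fragmentation) variant.
#' @param init_bias If `TRUE` (default), initialize the head intercept to the
#'   training-label mean before optimization, so the network starts from the
#'   mean predictor instead of zero.
#' @param verbose Print one line per epoch to stderr.
#' @return List with `params` (best-validation parameters), `history` (data
#'   frame: epoch, train MSE, validation MAE/RMSE, best-so-far flag),
#'   `best_epoch`, `best_val_rmse`, and `epochs_run`.
#' @export
fragsol_train <- function(train_graphs, train_labels, val_graphs, val_labels,
                          params, cfg, tc = train_config(),
                          null_fragment = FALSE, init_bias = TRUE,
                          verbose = FALSE) {
  stopifnot(length(train_graphs) >= 1, length(val_graphs) >= 1,
            length(train_graphs) == length(train_labels),
            length(val_graphs) == length(val_labels))
  if (init_bias) params$b <- mean(train_labels)
  compiled <- lapply(train_graphs, fs_compile_molecule,
                     null_fragment = null_fragment)
  val_compiled <- lapply(val_graphs, fs_compile_molecule,
                         null_fragment = null_fragment)
  val_batch <- fs_make_batch(val_compiled)
  n <- length(compiled)
  state <- adam_init(params)
  best <- list(params = params, rmse = Inf, epoch = 0L)
  stall <- 0L
  hist <- vector("list", tc$epochs)
  epochs_run <- 0L
  with_local_seed(tc$seed, {
    for (ep in seq_len(tc$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = tc$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + tc$batch_size - 1L, n)]
        batch <- fs_make_batch(compiled[idx])
        fwd <- fs_forward(batch, params, cfg, training = TRUE,
                          keep_cache = TRUE)
        err <- fwd$pred - train_labels[idx]
        loss <- mean(err^2)
        if (!is.finite(loss))
          stop(sprintf("training diverged (non-finite loss) at epoch %d", ep),
               call. = FALSE)
        ep_loss <- ep_loss + loss * length(idx)
        grads <- fs_backward(batch, params, cfg, fwd,
                             dpred = 2 * err / length(idx))
        upd <- adam_step(params, grads, state, tc$lr, tc$weight_decay)
        params <- upd$params
        state <- upd$state
      }
      ep_loss <- ep_loss / n
      val_pred <- fs_forward(val_batch, params, cfg)$pred
      vm <- eval_metrics(val_pred, val_labels)
      improved <- vm$rmse < best$rmse
      if (improved) {
        best <- list(params = params, rmse = vm$rmse, epoch = ep)
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      hist[[ep]] <- data.frame(epoch = ep, train_mse = ep_loss,
                               val_mae = vm$mae, val_rmse = vm$rmse,
                               best = improved)
      if (verbose)
        message(sprintf("epoch %3d  train MSE %.4f  val MAE %.4f  val RMSE %.4f%s",
                        ep, ep_loss, vm$mae, vm$rmse,
                        if (improved) "  *" else ""))
      epochs_run <- ep
      if (stall >= tc$patience) break
    }
  })
  list(params = best$params, history = do.call(rbind, hist[seq_len(epochs_run)]),
       best_epoch = best$epoch, best_val_rmse = best$rmse,
       epochs_run = epochs_run)
}
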