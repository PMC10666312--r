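#' Model architecture configuration
#'
#' The convolutional backbone is configurable because only the training
#' protocol (SGD, MSE, ReLU, batch 32, lr 5e-4, 100 epochs, patience 20)
#' and the concatenation points are fixed by the method; filter counts,
#' kernel widths, pooling and dense width follow the published Xpresso
#' backbone by default and a small toy preset is provided for desk-scale
#' work.
#'
#' @param window Window length W in bases.
#' @param conv_blocks List of numeric vectors
#'   `c(filters, width, dilation, pool)`, applied in order to the one-hot
#'   sequence.
#' @param dense_units Width of the hidden dense layer.
#' @param dropout Dropout fraction on the hidden dense layer, in `[0, 1)`.
#' @param k_mirnas Number of miRNA features K (0 = baseline model).
#' @param standardize Z-score the half-life/miRNA features using
#'   training-partition statistics? Default `FALSE` (features enter raw).
#' @return A `model_config` object.
#' @export
model_config <- function(window = 10500,
                         conv_blocks = list(c(128, 6, 1, 30), c(32, 9, 1, 10)),
                         dense_units = 64, dropout = 0.05, k_mirnas = 0,
                         standardize = FALSE) {
  stopifnot(window >= 1, dense_units >= 1, dropout >= 0, dropout < 1,
            k_mirnas >= 0)
  L <- window
  C <- 4L
  for (b in conv_blocks) {
    stopifnot(length(b) == 4, all(b[c(1, 2, 4)] >= 1), b[3] >= 1)
    L <- L - (b[2] - 1) * b[3]
    if (L < 1) stop("model_config: conv receptive field exceeds input length")
    L <- L %/% b[4]
    if (L < 1) stop("model_config: pooled sequence length < 1")
    C <- b[1]
  }
  structure(list(window = as.integer(window), conv_blocks = conv_blocks,
                 dense_units = as.integer(dense_units), dropout = dropout,
                 k_mirnas = as.integer(k_mirnas),
                 standardize = isTRUE(standardize),
                 pooled_length = as.integer(L), n_flat = as.integer(L * C)),
            class = "model_config")
}

#' Toy architecture preset
#'
#' One conv block (8 filters of width 8) with aggressive width-100 max
#' pooling over a 1000-base window, a 32-unit dense layer and no dropout:
#' small enough that a full multi-run comparison trains on a single CPU in
#' minutes. The wide pooling keeps the flattened sequence block compact
#' (72 values), so the half-life and miRNA features are not crowded out of
#' the shared dense layer; the preset also standardizes those features
#' (training-partition z-scores) because at the fixed learning-rate/epoch
#' budget the sparse miRNA features train far too slowly on their raw
#' scale.
#'
#' @inheritParams model_config
#' @return A [model_config()].
#' @export
model_config_toy <- function(window = 1000, k_mirnas = 0, standardize = TRUE) {
  model_config(window = window, conv_blocks = list(c(8, 8, 1, 100)),
               dense_units = 32, dropout = 0, k_mirnas = k_mirnas,
               standardize = standardize)
}

#' Training configuration
#'
#' Defaults are the published training protocol: batch size 32, learning
#' rate 0.0005, at most 100 epochs, early stopping with patience 20 on the
#' validation loss.
#'
#' @param batch_size Minibatch size.
#' @param learning_rate SGD learning rate (plain SGD, no momentum).
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience in epochs.
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout; fixes the run bit-for-bit on a given platform.
#' @return A `train_config` object.
#' @export
train_config <- function(batch_size = 32, learning_rate = 0.0005,
                         max_epochs = 100, patience = 20, seed = 1) {
  stopifnot(batch_size >= 1, learning_rate >= 0, max_epochs >= 1,
            patience >= 1, patience <= max_epochs)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

conv_field <- function(cfg, i) vapply(cfg$conv_blocks, function(b) as.integer(b[i]), integer(1))

#' Build an untrained model handle
#'
#' @param cfg A [model_config()].
#' @return A `mirex_model` object; weights are attached by [train()].
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  structure(list(config = cfg, weights = NULL, feature_stats = NULL),
            class = "mirex_model")
}

#' Analytic parameter count
#'
#' @param model A `mirex_model` (or [model_config()]).
#' @return Total number of trainable scalars.
#' @export
n_params <- function(model) {
  cfg <- if (inherits(model, "mirex_model")) model$config else model
  C <- 4L
  total <- 0L
  for (b in cfg$conv_blocks) {
    total <- total + b[2] * C * b[1] + b[1]
    C <- b[1]
  }
  n_in <- cfg$n_flat + 8L + cfg$k_mirnas
  total + n_in * cfg$dense_units + cfg$dense_units + cfg$dense_units + 1L
}

# extra feature block = half-life then miRNA columns, optionally z-scored
# with training-partition statistics
extra_block <- function(batch, stats = NULL) {
  x <- cbind(batch$halflife, batch$mirna)
  if (!is.null(stats)) x <- sweep(sweep(x, 2, stats$mean), 2, stats$sd, "/")
  x
}

check_batch <- function(batch, cfg, name) {
  if (ncol(batch$seq_codes) != cfg$window)
    stop(sprintf("%s batch: window is %d bases but the model expects %d",
                 name, ncol(batch$seq_codes), cfg$window))
  if (ncol(batch$mirna) != cfg$k_mirnas)
    stop(sprintf("%s batch: %d miRNA columns but the model expects k_mirnas = %d",
                 name, ncol(batch$mirna), cfg$k_mirnas))
  if (nrow(batch$seq_codes) == 0) stop(sprintf("%s batch is empty", name))
}

#' Train the model with SGD, MSE loss and early stopping
#'
#' Minimises mean squared error with plain SGD at the configured learning
#' rate; training stops when the validation loss has not strictly improved
#' for `patience` epochs (or at `max_epochs`), and the weights of the best
#' validation epoch are restored. Fully reproducible given
#' `train_cfg$seed`.
#'
#' @param model A `mirex_model` from [build_model()].
#' @param train_batch,val_batch Batches from [assemble_dataset()].
#' @param train_cfg A [train_config()].
#' @param test_batch Optional test batch; if given, test predictions and
#'   test R-squared are attached to the result.
#' @param residual_on Partitions whose residuals
#'   (`y - yhat`) populate the result's residual map; default train and
#'   validation genes, keeping the test set out of downstream feature
#'   selection.
#' @return A `mirex_run` object: fitted `model`, `val_loss_curve`,
#'   `train_loss_curve`, `best_epoch`, `epochs_run`, `predictions`,
#'   `residuals`, `r2_val`, `r2_test`, `seed`.
#' @export
train <- function(model, train_batch, val_batch, train_cfg = train_config(),
                  test_batch = NULL, residual_on = c("train", "val")) {
  stopifnot(inherits(model, "mirex_model"), inherits(train_cfg, "train_config"))
  cfg <- model$config
  check_batch(train_batch, cfg, "train")
  check_batch(val_batch, cfg, "validation")
  stats <- NULL
  if (cfg$standardize) {
    x <- extra_block(train_batch)
    stats <- list(mean = colMeans(x), sd = pmax(apply(x, 2, sd), 1e-8))
  }
  fit <- cnn_fit(train_batch$seq_codes, extra_block(train_batch, stats),
                 unname(train_batch$y),
                 val_batch$seq_codes, extra_block(val_batch, stats),
                 unname(val_batch$y),
                 conv_field(cfg, 1), conv_field(cfg, 2), conv_field(cfg, 3),
                 conv_field(cfg, 4), cfg$dense_units, cfg$dropout,
                 train_cfg$batch_size, train_cfg$learning_rate,
                 train_cfg$max_epochs, train_cfg$patience, train_cfg$seed)
  model$weights <- fit$weights
  model$feature_stats <- stats

  batches <- list(train = train_batch, val = val_batch)
  if (!is.null(test_batch)) {
    check_batch(test_batch, cfg, "test")
    batches$test <- test_batch
  }
  preds <- lapply(batches, function(b) setNames(predict(model, b), b$gene_ids))
  predictions <- unlist(unname(preds))
  residual_parts <- intersect(residual_on, names(batches))
  residuals <- unlist(unname(lapply(residual_parts, function(p)
    batches[[p]]$y - preds[[p]])))
  structure(list(
    model = model,
    seed = train_cfg$seed,
    best_epoch = fit$best_epoch,
    epochs_run = fit$epochs_run,
    val_loss_curve = fit$val_loss,
    train_loss_curve = fit$train_loss,
    best_val_loss = fit$best_val_loss,
    predictions = predictions,
    residuals = residuals,
    r2_val = r_squared(val_batch$y, preds$val),
    r2_test = if (is.null(test_batch)) NA_real_ else
      r_squared(test_batch$y, preds$test)),
    class = "mirex_run")
}

#' Predict expression for a batch
#'
#' Deterministic forward pass (dropout disabled).
#'
#' @param object A trained `mirex_model`.
#' @param batch A batch from [assemble_dataset()].
#' @param ... Unused.
#' @return Numeric vector of predictions, named by gene.
#' @export
predict.mirex_model <- function(object, batch, ...) {
  if (is.null(object$weights)) stop("predict: model has not been trained")
  cfg <- object$config
  check_batch(batch, cfg, "predict")
  out <- cnn_forward(object$weights, batch$seq_codes,
                     extra_block(batch, object$feature_stats),
                     conv_field(cfg, 1), conv_field(cfg, 2),
                     conv_field(cfg, 3), conv_field(cfg, 4), cfg$dense_units)
  setNames(out, batch$gene_ids)
}

#' @export
print.mirex_run <- function(x, ...) {
  cat(sprintf("mirex run (seed %d): %d epochs, best epoch %d, val MSE %.4f, val R2 %.3f, test R2 %s\n",
              x$seed, x$epochs_run, x$best_epoch, x$best_val_loss, x$r2_val,
              ifelse(is.na(x$r2_test), "NA", sprintf("%.3f", x$r2_test))))
  invisible(x)
}
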