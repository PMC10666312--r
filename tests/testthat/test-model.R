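test_that("forward pass honors the shape contract", {
  cfg <- tiny_model_cfg(W = 60, K = 10)
  b <- make_batch(2, 60, K = 10, seed = 2)
  run <- train(build_model(cfg), b, b,
               train_config(batch_size = 2, max_epochs = 2, patience = 2, seed = 1))
  p <- predict(run$model, b)
  expect_length(p, 2)
  expect_true(all(is.finite(p)))
  expect_named(p, b$gene_ids)
})

test_that("parameter count is the analytic formula; adding K miRNAs widens the first dense layer by K x dense_units", {
  cfg0 <- model_config(window = 300, conv_blocks = list(c(6, 5, 1, 10), c(4, 3, 2, 2)),
                       dense_units = 16, k_mirnas = 0)
  cfg10 <- model_config(window = 300, conv_blocks = list(c(6, 5, 1, 10), c(4, 3, 2, 2)),
                        dense_units = 16, k_mirnas = 10)
  expect_equal(n_params(cfg10) - n_params(cfg0), 10 * 16)
  # analytic count equals the number of scalars actually allocated
  w <- mirex:::cnn_init_weights(300L, 8L, c(6L, 4L), c(5L, 3L), c(1L, 2L),
                                c(10L, 2L), 16L, 1L)
  n_alloc <- sum(vapply(w$Wc, length, numeric(1))) +
    sum(vapply(w$bc, length, numeric(1))) +
    length(w$W1) + length(w$b1) + length(w$w2) + 1
  expect_equal(n_params(cfg0), n_alloc)
})

test_that("a validation loss that never improves stops training exactly patience epochs past the best", {
  b <- make_batch(8, 40, seed = 3)
  cfg <- tiny_model_cfg(W = 40)
  # zero learning rate freezes the weights, so the validation loss is flat
  # and the first epoch stays the best
  run <- train(build_model(cfg), b, b,
               train_config(batch_size = 4, learning_rate = 0,
                            max_epochs = 50, patience = 7, seed = 1))
  expect_equal(run$best_epoch, 1)
  expect_equal(run$epochs_run, 1 + 7)
  expect_length(run$val_loss_curve, run$epochs_run)
})

test_that("training never exceeds patience epochs past the best, and runs to max_epochs when stopping cannot trigger", {
  b <- make_batch(30, 40, seed = 4)
  cfg <- tiny_model_cfg(W = 40)
  run <- train(build_model(cfg), b, b,
               train_config(batch_size = 8, max_epochs = 25, patience = 5, seed = 2))
  expect_lte(run$epochs_run - run$best_epoch, 5)
  run2 <- train(build_model(cfg), b, b,
                train_config(batch_size = 8, max_epochs = 10, patience = 10, seed = 2))
  expect_equal(run2$epochs_run, 10)
})

test_that("training is bit-reproducible for a fixed seed and differs across seeds", {
  tr <- make_batch(20, 50, K = 2, seed = 5)
  va <- make_batch(8, 50, K = 2, seed = 6)
  cfg <- tiny_model_cfg(W = 50, K = 2)
  tc <- function(s) train_config(batch_size = 8, max_epochs = 6, patience = 6, seed = s)
  r1 <- train(build_model(cfg), tr, va, tc(7))
  r2 <- train(build_model(cfg), tr, va, tc(7))
  expect_identical(r1$val_loss_curve, r2$val_loss_curve)
  expect_identical(r1$predictions, r2$predictions)
  r3 <- train(build_model(cfg), tr, va, tc(8))
  expect_false(identical(r1$val_loss_curve, r3$val_loss_curve))
})

test_that("residuals satisfy y - yhat exactly over train and validation genes", {
  tr <- make_batch(15, 40, seed = 9)
  va <- make_batch(5, 40, seed = 10)
  run <- train(build_model(tiny_model_cfg(W = 40)), tr, va,
               train_config(batch_size = 8, max_epochs = 4, patience = 4, seed = 1))
  y_all <- c(tr$y, va$y)
  expect_setequal(names(run$residuals), names(y_all))
  g <- names(run$residuals)
  expect_equal(run$residuals[g], y_all[g] - run$predictions[g])
})

test_that("analytic gradients match central finite differences on a two-block dilated network", {
  set.seed(13)
  n <- 5; W <- 40L; nex <- 4L
  seqs <- matrix(sample(0:4, n * W, replace = TRUE,
                        prob = c(0.05, rep(0.2375, 4))), n, W)
  storage.mode(seqs) <- "integer"
  extra <- matrix(rnorm(n * nex), n, nex)
  y <- rnorm(n)
  fl <- c(4L, 3L); wd <- c(5L, 3L); dl <- c(1L, 2L); pl <- c(2L, 3L); du <- 6L
  w <- mirex:::cnn_init_weights(W, nex, fl, wd, dl, pl, du, 42L)
  g <- mirex:::cnn_grad_dbl(w, seqs, extra, y, fl, wd, dl, pl, du)
  eps <- 1e-6
  perturb <- function(w, slot, l, i, d) {
    if (is.na(l)) w[[slot]][i] <- w[[slot]][i] + d
    else w[[slot]][[l]][i] <- w[[slot]][[l]][i] + d
    w
  }
  check_slot <- function(slot, l = NA) {
    arr <- if (is.na(l)) w[[slot]] else w[[slot]][[l]]
    ga <- if (is.na(l)) g[[slot]] else g[[slot]][[l]]
    idx <- if (length(arr) > 12) sample(length(arr), 12) else seq_along(arr)
    for (i in idx) {
      fp <- mirex:::cnn_mse_dbl(perturb(w, slot, l, i, eps), seqs, extra, y,
                                fl, wd, dl, pl, du)
      fm <- mirex:::cnn_mse_dbl(perturb(w, slot, l, i, -eps), seqs, extra, y,
                                fl, wd, dl, pl, du)
      expect_equal(ga[i], (fp - fm) / (2 * eps), tolerance = 1e-6)
    }
  }
  check_slot("Wc", 1); check_slot("Wc", 2)
  check_slot("bc", 1); check_slot("bc", 2)
  check_slot("W1"); check_slot("b1"); check_slot("w2"); check_slot("b2")
})

test_that("prediction is batching-invariant and sensitive to miRNA inputs only when K > 0", {
  tr <- make_batch(24, 50, K = 2, seed = 20)
  # make the miRNA features matter: y depends on them strongly
  tr$y <- setNames(2 * tr$mirna[, 1] - tr$mirna[, 2] + 0.1 * rnorm(24),
                   tr$gene_ids)
  run <- train(build_model(tiny_model_cfg(W = 50, K = 2)), tr, tr,
               train_config(batch_size = 8, max_epochs = 30, patience = 30, seed = 3))
  p_all <- predict(run$model, tr)
  sub <- function(b, i) lapply(
    list(seq_codes = b$seq_codes[i, , drop = FALSE],
         halflife = b$halflife[i, , drop = FALSE],
         mirna = b$mirna[i, , drop = FALSE],
         y = b$y[i], gene_ids = b$gene_ids[i]), identity)
  p_split <- c(predict(run$model, sub(tr, 1:10)), predict(run$model, sub(tr, 11:24)))
  # single-precision forward: batching equivalence holds to float tolerance
  expect_equal(p_all, p_split, tolerance = 1e-5)
  expect_length(predict(run$model, sub(tr, 3)), 1)

  pert <- tr
  pert$mirna <- pert$mirna + 1
  expect_false(isTRUE(all.equal(predict(run$model, pert), p_all)))

  # baseline model has no miRNA inputs at all: its prediction cannot react
  run0 <- train(build_model(tiny_model_cfg(W = 50, K = 0)),
                { b <- tr; b$mirna <- b$mirna[, 0, drop = FALSE]; b },
                { b <- tr; b$mirna <- b$mirna[, 0, drop = FALSE]; b },
                train_config(batch_size = 8, max_epochs = 5, patience = 5, seed = 3))
  b0 <- tr; b0$mirna <- b0$mirna[, 0, drop = FALSE]
  expect_equal(n_params(run0$model), n_params(tiny_model_cfg(W = 50, K = 0)))
  expect_identical(predict(run0$model, b0), predict(run0$model, b0))
})

test_that("invalid configurations and shape mismatches are rejected", {
  expect_error(model_config(window = 10, conv_blocks = list(c(4, 20, 1, 2))),
               "receptive field")
  expect_error(model_config(window = 30, conv_blocks = list(c(4, 5, 1, 40))),
               "pooled")
  cfg <- tiny_model_cfg(W = 40, K = 2)
  b0 <- make_batch(4, 40, K = 0)
  expect_error(train(build_model(cfg), b0, b0, train_config(max_epochs = 1, patience = 1)),
               "k_mirnas")
  expect_error(predict(build_model(cfg), b0), "trained")
})

test_that("divergent training aborts with a diagnostic", {
  b <- make_batch(10, 40, seed = 30)
  b$y <- b$y * 1e4
  expect_error(
    train(build_model(tiny_model_cfg(W = 40)), b, b,
          train_config(batch_size = 2, learning_rate = 50,
                       max_epochs = 20, patience = 20, seed = 1)),
    "diverged")
})
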