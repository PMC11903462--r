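test_that("parameter count matches a manual shape walk", {
  spec <- model_spec(n_channels = 32, window_length = 100, seed = 1)
  m <- build_model(spec)
  # conv stack: time 100 -> 98 -> 49 -> 45 -> 22 -> 16 -> 8
  conv <- (32 * 3 * 32 + 32) + (64 * 5 * 32 + 64) + (128 * 7 * 64 + 128)
  bn <- 2 * (32 + 64 + 128)
  flat <- 8 * 128
  dense <- (128 * flat + 128) + (64 * 128 + 64) + (6 * 64 + 6)
  expect_equal(n_parameters(m), conv + bn + dense)
  expect_equal(m$spec$conv_filters, c(32L, 64L, 128L))
  expect_equal(m$spec$conv_kernels, c(3L, 5L, 7L))
})

test_that("initialization is seed-deterministic and window-length checked", {
  s1 <- build_model(model_spec(n_channels = 4, window_length = 64, seed = 5))
  s2 <- build_model(model_spec(n_channels = 4, window_length = 64, seed = 5))
  expect_identical(s1$params, s2$params)
  s3 <- build_model(model_spec(n_channels = 4, window_length = 64, seed = 6))
  expect_false(identical(s1$params, s3$params))
  expect_error(build_model(model_spec(n_channels = 4, window_length = 10)),
               "too short")
})

test_that("outputs are six probabilities and inference is deterministic", {
  b <- separable_batch(count = 10)
  m <- build_model(model_spec(n_channels = 6, window_length = 48, seed = 2))
  tr <- train_model(m, b, b, train_config(epochs = 1, batch_size = 5, seed = 3))
  p1 <- predict(tr, b)
  expect_equal(dim(p1), c(10L, 6L))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_identical(p1, predict(tr, b))
  short <- separable_batch(count = 4, n_window = 32)
  expect_error(predict(tr, short), "window length")
})

test_that("zero learning rate leaves the initial weights untouched", {
  b <- separable_batch(count = 12)
  m <- build_model(model_spec(n_channels = 6, window_length = 48, seed = 4))
  tr <- train_model(m, b, b, train_config(epochs = 1, batch_size = 4,
                                          learning_rate = 0, seed = 1))
  expect_equal(tr$final$params, m$params, tolerance = 1e-15)
})

test_that("training separates a separable toy problem to per-class AUC 1", {
  train_b <- separable_batch(count = 60, seed = 10)
  test_b <- separable_batch(count = 40, seed = 11)
  m <- build_model(model_spec(n_channels = 6, window_length = 48, seed = 2,
                              dropout = 0))
  tr <- train_model(m, train_b, train_b,
                    train_config(epochs = 10, batch_size = 10, seed = 3))
  # loss decreased over training
  h <- tr$history
  expect_lt(h$val_loss[nrow(h)], h$val_loss[1])
  # the fitted fixture is ranked perfectly, held-out windows near-perfectly
  fit_scores <- predict(tr, train_b)
  for (cl in 1:6) {
    expect_equal(roc_auc(train_b$labels[, cl], fit_scores[, cl]), 1.0)
  }
  scores <- predict(tr, test_b)
  macro <- micro_macro_auc(test_b$labels, scores)$macro
  expect_gt(macro, 0.95)
})

test_that("checkpoints attain the recorded best validation loss and accuracy", {
  train_b <- separable_batch(count = 40, seed = 20)
  val_b <- separable_batch(count = 20, seed = 21)
  m <- build_model(model_spec(n_channels = 6, window_length = 48, seed = 7))
  tr <- train_model(m, train_b, val_b,
                    train_config(epochs = 3, batch_size = 8,
                                 checkpoint_every = 2, seed = 8))
  ev_loss <- eegnda:::evaluate_model(tr$best_loss, val_b)
  ev_acc <- eegnda:::evaluate_model(tr$best_acc, val_b)
  expect_equal(ev_loss$loss, min(tr$history$val_loss), tolerance = 1e-12)
  expect_equal(ev_acc$accuracy, max(tr$history$val_accuracy), tolerance = 1e-12)
  expect_equal(tr$cfg$epochs, 3L)
  expect_equal(train_config()$epochs, 1L)  # single-epoch default
})

test_that("trained models round-trip through their native serialized form", {
  b <- separable_batch(count = 10)
  m <- build_model(model_spec(n_channels = 6, window_length = 48, seed = 2))
  tr <- train_model(m, b, b, train_config(epochs = 1, batch_size = 5, seed = 3))
  td <- withr::local_tempdir()
  path <- file.path(td, "model.rds")
  save_trained_model(tr, path)
  tr2 <- load_trained_model(path)
  expect_identical(predict(tr, b), predict(tr2, b))
})

test_that("backpropagated gradients match finite differences", {
  # tiny network, dropout off so the loss is deterministic given the batch
  b <- separable_batch(count = 6, n_channels = 3, n_window = 48, seed = 30)
  m <- build_model(model_spec(n_channels = 3, window_length = 48,
                              dense_widths = c(8), dropout = 0, seed = 9))
  x <- eegnda:::batch_to_input(b)
  y <- t(b$labels)
  loss_at <- function(model) {
    fwd <- eegnda:::model_forward(model, x, training = TRUE)
    eegnda:::bce_loss(fwd$probs, y)$loss
  }
  fwd <- eegnda:::model_forward(m, x, training = TRUE)
  grads <- eegnda:::model_backward(m, fwd, eegnda:::bce_loss(fwd$probs, y)$dlogits)
  eps <- 1e-5
  set.seed(17)
  for (nm in c("conv1_w", "conv2_w", "conv3_b", "bn1_gamma", "bn2_beta",
               "dense1_w", "dense2_b")) {
    for (r in seq_len(3)) {
      i <- sample.int(length(m$params[[nm]]), 1)
      mp <- m
      mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm <- m
      mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
      num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      expect_equal(unname(grads[[nm]][i]), num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})
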