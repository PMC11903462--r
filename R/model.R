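#' Specification of the compact convolutional classifier
#'
#' The "vanilla" architecture: three 1D convolutional stages along time
#' (kernels of length 3, 5 and 7 with 32, 64 and 128 filters; the 32 EEG
#' channels enter the first convolution as input feature maps), each followed
#' by batch normalization, ReLU, (2,1) max pooling and dropout 0.1, then
#' fully connected layers ending in six independent sigmoid outputs (the
#' classes co-occur, so the head is multi-label).
#'
#' @param n_channels Input channel count (default 32).
#' @param window_length Window length N in samples.
#' @param conv_filters Filters per conv stage (default `c(32, 64, 128)`).
#' @param conv_kernels Kernel lengths along time (default `c(3, 5, 7)`).
#' @param dropout Dropout probability in `[0, 1)` (default 0.1).
#' @param dense_widths Hidden dense-layer widths (default `c(128, 64)`).
#' @param n_classes Output classes (default 6).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(n_channels = 32, window_length, conv_filters = c(32, 64, 128),
                       conv_kernels = c(3, 5, 7), dropout = 0.1,
                       dense_widths = c(128, 64), n_classes = 6, seed = 1L) {
  if (length(conv_filters) != 3 || any(diff(conv_filters) <= 0)) {
    stopf("conv_filters must be three strictly increasing counts")
  }
  if (length(conv_kernels) != 3) stopf("conv_kernels must have three entries")
  if (dropout < 0 || dropout >= 1) stopf("dropout must lie in [0, 1)")
  structure(
    list(n_channels = as.integer(n_channels),
         window_length = as.integer(window_length),
         conv_filters = as.integer(conv_filters),
         conv_kernels = as.integer(conv_kernels),
         pool_kernel = 2L, dropout = dropout,
         dense_widths = as.integer(dense_widths),
         n_classes = as.integer(n_classes), seed = as.integer(seed)),
    class = "model_spec"
  )
}

# walk the conv/pool stack and return the time length after each stage;
# errors name the offending stage
shape_walk <- function(spec) {
  t_len <- spec$window_length
  out <- list()
  for (i in 1:3) {
    t_conv <- t_len - spec$conv_kernels[i] + 1L
    if (t_conv < 1L) {
      stopf("window length %d too short at conv stage %d (kernel %d needs >= %d samples)",
            spec$window_length, i, spec$conv_kernels[i], spec$conv_kernels[i])
    }
    t_pool <- t_conv %/% 2L
    if (t_pool < 1L) {
      stopf("window length %d too short at pool stage %d", spec$window_length, i)
    }
    out[[i]] <- c(conv = t_conv, pool = t_pool)
    t_len <- t_pool
  }
  out
}

#' Build the classifier with deterministic weight initialization
#'
#' He-normal initialization for conv and dense weights, zero biases, unit
#' batch-norm scale; identical `model_spec` (including seed) gives identical
#' initial weights.
#'
#' @param spec A [model_spec()].
#' @return An object of class `cnn_model` holding parameters, batch-norm
#'   running statistics and the layer shape walk.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  shapes <- shape_walk(spec)
  flat_dim <- shapes[[3]]["pool"] * spec$conv_filters[3]

  params <- list()
  bn_state <- list()
  with_seed(spec$seed, {
    cin <- spec$n_channels
    for (i in 1:3) {
      f <- spec$conv_filters[i]
      k <- spec$conv_kernels[i]
      fan_in <- cin * k
      params[[paste0("conv", i, "_w")]] <-
        matrix(stats::rnorm(f * fan_in, 0, sqrt(2 / fan_in)), f, fan_in)
      params[[paste0("conv", i, "_b")]] <- numeric(f)
      params[[paste0("bn", i, "_gamma")]] <- rep(1, f)
      params[[paste0("bn", i, "_beta")]] <- numeric(f)
      bn_state[[i]] <- list(mean = numeric(f), var = rep(1, f))
      cin <- f
    }
    din <- flat_dim
    widths <- c(spec$dense_widths, spec$n_classes)
    for (j in seq_along(widths)) {
      dout <- widths[j]
      params[[paste0("dense", j, "_w")]] <-
        matrix(stats::rnorm(dout * din, 0, sqrt(2 / din)), dout, din)
      params[[paste0("dense", j, "_b")]] <- numeric(dout)
      din <- dout
    }
    invisible(NULL)
  })

  structure(list(spec = spec, params = params, bn_state = bn_state,
                 shapes = shapes, flat_dim = flat_dim),
            class = "cnn_model")
}

#' Count trainable parameters of the classifier
#'
#' @param model A `cnn_model`.
#' @return Integer parameter count (conv/dense weights and biases plus
#'   batch-norm scale and shift).
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "cnn_model"))
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.cnn_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<cnn_model> N = %d, conv %s (kernels %s), dense %s -> %d sigmoid; %d parameters\n",
              s$window_length, paste(s$conv_filters, collapse = "/"),
              paste(s$conv_kernels, collapse = "/"),
              paste(s$dense_widths, collapse = "/"), s$n_classes,
              n_parameters(x)))
  invisible(x)
}

# full forward pass; training = TRUE uses batch statistics, updates running
# stats and applies dropout (caller controls the RNG stream)
model_forward <- function(model, x, training) {
  p <- model$params
  caches <- list()
  h <- x
  for (i in 1:3) {
    cv <- conv1d_forward(h, p[[paste0("conv", i, "_w")]],
                         p[[paste0("conv", i, "_b")]], model$spec$conv_kernels[i])
    bn <- bnrelu_forward(cv$out, p[[paste0("bn", i, "_gamma")]],
                         p[[paste0("bn", i, "_beta")]], model$bn_state[[i]],
                         training)
    if (training) model$bn_state[[i]] <- bn$state
    pl <- pool2_forward(bn$out)
    dr <- dropout_forward(pl$out, model$spec$dropout, training)
    caches[[i]] <- list(conv = cv, bn = bn, pool = pl, drop = dr)
    h <- dr$out
  }
  d <- dim(h)
  hmat <- matrix(h, d[1] * d[2], d[3])
  flat_dims <- d
  n_dense <- length(model$spec$dense_widths) + 1L
  dense_caches <- list()
  for (j in seq_len(n_dense)) {
    dn <- dense_forward(hmat, p[[paste0("dense", j, "_w")]],
                        p[[paste0("dense", j, "_b")]])
    if (j < n_dense) {
      rl <- relu_forward(dn$out)
      dense_caches[[j]] <- list(dense = dn, relu = rl)
      hmat <- rl$out
    } else {
      dense_caches[[j]] <- list(dense = dn)
      hmat <- dn$out
    }
  }
  probs <- sigmoid(hmat)  # [n_classes, B]
  list(probs = probs, caches = caches, dense_caches = dense_caches,
       flat_dims = flat_dims, model = model)
}

model_backward <- function(model, fwd, dlogits) {
  p <- model$params
  grads <- list()
  n_dense <- length(model$spec$dense_widths) + 1L
  dy <- dlogits
  for (j in rev(seq_len(n_dense))) {
    if (j < n_dense) dy <- relu_backward(dy, fwd$dense_caches[[j]]$relu)
    bk <- dense_backward(dy, p[[paste0("dense", j, "_w")]],
                         fwd$dense_caches[[j]]$dense)
    grads[[paste0("dense", j, "_w")]] <- bk$dw
    grads[[paste0("dense", j, "_b")]] <- bk$db
    dy <- bk$dx
  }
  dh <- array(dy, dim = fwd$flat_dims)
  for (i in 3:1) {
    cc <- fwd$caches[[i]]
    dh <- dropout_backward(dh, cc$drop)
    dh <- pool2_backward(dh, cc$pool)
    bb <- bnrelu_backward(dh, p[[paste0("bn", i, "_gamma")]], cc$bn)
    grads[[paste0("bn", i, "_gamma")]] <- bb$dgamma
    grads[[paste0("bn", i, "_beta")]] <- bb$dbeta
    cb <- conv1d_backward(bb$dx, p[[paste0("conv", i, "_w")]], cc$conv)
    grads[[paste0("conv", i, "_w")]] <- cb$dw
    grads[[paste0("conv", i, "_b")]] <- cb$db
    dh <- cb$dx
  }
  grads
}

# batch data [B, C, N] -> activation layout [C, N, B]
batch_to_input <- function(batch) aperm(batch$data, c(2, 3, 1))

# evaluate loss and per-label binary accuracy in inference mode
evaluate_model <- function(model, batch) {
  x <- batch_to_input(batch)
  fwd <- model_forward(model, x, training = FALSE)
  probs <- t(fwd$probs)
  y <- batch$labels
  loss <- bce_loss(t(probs), t(y))$loss
  if (!is.finite(loss)) stopf("non-finite validation loss")
  acc <- mean((probs > 0.5) == (y > 0.5))
  list(loss = loss, accuracy = acc)
}

#' Training configuration
#'
#' @param epochs Training epochs (default 1: the study trains for a single
#'   epoch and relies on checkpointing).
#' @param batch_size Mini-batch size (default 64).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param checkpoint_every Validation cadence in batches (default 50);
#'   validation is always also run at each epoch end.
#' @param seed Integer seed controlling shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 1L, batch_size = 64L, learning_rate = 1e-3,
                         checkpoint_every = 50L, seed = 1L) {
  if (epochs < 1) stopf("epochs must be >= 1")
  if (batch_size < 1) stopf("batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 checkpoint_every = as.integer(checkpoint_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train the classifier with best-loss/best-accuracy checkpointing
#'
#' Optimizes mean binary cross-entropy over the six sigmoid outputs with
#' Adam. Validation loss and thresholded (0.5) per-label accuracy are
#' evaluated every `checkpoint_every` batches and at each epoch end; the
#' weight snapshots attaining the minimum validation loss and the maximum
#' validation accuracy are retained alongside the final state.
#'
#' @param model A `cnn_model` from [build_model()].
#' @param train_batch,val_batch `window_batch` objects.
#' @param cfg A [train_config()].
#' @return An object of class `trained_model` with elements `final`,
#'   `best_loss`, `best_acc` (model snapshots) and `history` (data.frame of
#'   checkpoint evaluations).
#' @export
train_model <- function(model, train_batch, val_batch, cfg = train_config()) {
  stopifnot(inherits(model, "cnn_model"), inherits(cfg, "train_config"))
  n <- dim(train_batch$data)[1]
  if (n < 1) stopf("training batch is empty")
  if (dim(val_batch$data)[1] < 1) stopf("validation batch is empty")

  opt <- adam_init(model$params)
  history <- list()
  best <- list(loss = Inf, acc = -Inf, loss_state = NULL, acc_state = NULL)
  snapshot <- function(m) list(params = m$params, bn_state = m$bn_state)

  checkpoint <- function(m, step) {
    ev <- evaluate_model(m, val_batch)
    history[[length(history) + 1L]] <<-
      data.frame(step = step, val_loss = ev$loss, val_accuracy = ev$accuracy)
    if (ev$loss < best$loss) {
      best$loss <<- ev$loss
      best$loss_state <<- snapshot(m)
    }
    if (ev$accuracy > best$acc) {
      best$acc <<- ev$accuracy
      best$acc_state <<- snapshot(m)
    }
  }

  step <- 0L
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      batch_starts <- seq(1L, n, by = cfg$batch_size)
      for (bs in batch_starts) {
        idx <- ord[bs:min(bs + cfg$batch_size - 1L, n)]
        xb <- batch_to_input(subset_batch(train_batch, idx))
        yb <- t(train_batch$labels[idx, , drop = FALSE])
        fwd <- model_forward(model, xb, training = TRUE)
        model$bn_state <- fwd$model$bn_state
        loss <- bce_loss(fwd$probs, yb)
        if (!is.finite(loss$loss)) {
          stopf("divergent (non-finite) training loss at batch %d", step + 1L)
        }
        grads <- model_backward(model, fwd, loss$dlogits)
        upd <- adam_step(model$params, grads, opt, cfg$learning_rate)
        model$params <- upd$params
        opt <- upd$state
        step <- step + 1L
        if (step %% cfg$checkpoint_every == 0L) checkpoint(model, step)
      }
      checkpoint(model, step)
    }
  })

  structure(list(final = model,
                 best_loss = replace_state(model, best$loss_state),
                 best_acc = replace_state(model, best$acc_state),
                 history = do.call(rbind, history), cfg = cfg),
            class = "trained_model")
}

replace_state <- function(model, state) {
  model$params <- state$params
  model$bn_state <- state$bn_state
  model
}

#' @export
print.trained_model <- function(x, ...) {
  h <- x$history
  cat(sprintf("<trained_model> %d checkpoints; best val loss %.4f, best val accuracy %.4f\n",
              nrow(h), min(h$val_loss), max(h$val_accuracy)))
  invisible(x)
}

#' Predict per-class probabilities for a window batch
#'
#' Inference is deterministic: dropout is disabled and batch normalization
#' uses the stored running statistics.
#'
#' @param object A `trained_model`.
#' @param batch A `window_batch` whose window length matches the model's.
#' @param which Checkpoint to apply: `"best_loss"` (default), `"best_acc"`
#'   or `"final"`.
#' @param ... Unused.
#' @return Numeric matrix `[count x 6]` of probabilities in `[0, 1]`.
#' @export
predict.trained_model <- function(object, batch, which = c("best_loss", "best_acc", "final"),
                                  ...) {
  which <- match.arg(which)
  model <- object[[which]]
  if (dim(batch$data)[3] != model$spec$window_length) {
    stopf("batch window length %d does not match model window length %d",
          dim(batch$data)[3], model$spec$window_length)
  }
  fwd <- model_forward(model, batch_to_input(batch), training = FALSE)
  scores <- t(fwd$probs)
  colnames(scores) <- gal_class_names()[seq_len(ncol(scores))]
  scores
}

#' Save or load a trained model's weight snapshots
#'
#' Snapshots are written in R's native serialization (RDS). The returned
#' path can be referenced from a run manifest.
#'
#' @param trained A `trained_model`.
#' @param path Output `.rds` path.
#' @return `save_trained_model` invisibly returns `path`;
#'   `load_trained_model` returns the restored `trained_model`.
#' @export
save_trained_model <- function(trained, path) {
  stopifnot(inherits(trained, "trained_model"))
  saveRDS(trained, path)
  invisible(path)
}

#' @rdname save_trained_model
#' @export
load_trained_model <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "trained_model")) stopf("not a trained_model snapshot")
  obj
}
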