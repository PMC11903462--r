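# Minimal neural-network engine used by the classifier module.
#
# Activations are stored as arrays [channels, time, batch]; convolutions are
# valid 1D convolutions along time implemented as im2col + one BLAS matmul,
# which is where essentially all the arithmetic happens. Everything is plain
# double-precision base R.

# ---- conv1d ----------------------------------------------------------------

# X: [Cin, Tin, B]; W: [F, Cin*k]; b: [F]
conv1d_forward <- function(x, w, b, k) {
  d <- dim(x)
  tout <- d[2] - k + 1L
  if (tout < 1L) stopf("conv kernel %d larger than input length %d", k, d[2])
  xmat <- .im2col_time(x, k)
  y <- w %*% xmat + b
  list(out = array(y, dim = c(nrow(w), tout, d[3])), xmat = xmat,
       dims = c(cin = d[1], tin = d[2], tout = tout, bsz = d[3], k = k))
}

conv1d_backward <- function(dy, w, cache) {
  d <- cache$dims
  dy_mat <- dy
  dim(dy_mat) <- c(nrow(w), d[["tout"]] * d[["bsz"]])
  dw <- tcrossprod(dy_mat, cache$xmat)
  db <- rowSums(dy_mat)
  dxmat <- crossprod(w, dy_mat)
  dx <- .col2im_time(dxmat, d[["cin"]], d[["tin"]], d[["bsz"]], d[["k"]])
  list(dx = dx, dw = dw, db = db)
}

# ---- batch normalization + ReLU (fused, per feature channel) ----------------

bnrelu_forward <- function(x, gamma, beta, state, training, momentum = 0.1,
                           eps = 1e-5) {
  fz <- .bnrelu_fwd(x, gamma, beta, state$mean, state$var, training, eps)
  if (training) {
    state$mean <- (1 - momentum) * state$mean + momentum * fz$batch_mean
    state$var <- (1 - momentum) * state$var + momentum * fz$batch_var
  }
  list(out = fz$out, xhat = fz$xhat, inv_sd = fz$inv_sd, mask = fz$mask,
       state = state)
}

# dy is the gradient at the post-ReLU activation; the fused kernel applies
# the ReLU mask before the batch-norm backward pass
bnrelu_backward <- function(dy, gamma, cache) {
  .bnrelu_bwd(dy, cache$mask, cache$xhat, cache$inv_sd, gamma)
}

# ---- relu / max-pool / dropout ---------------------------------------------

relu_forward <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_backward <- function(dy, cache) dy * cache$mask

# pool kernel 2, stride 2, along time (dim 2); trailing odd sample dropped
pool2_forward <- function(x) {
  d <- dim(x)
  p <- d[2] %/% 2L
  if (p < 1L) stopf("time length %d too short for (2,1) max pooling", d[2])
  fw <- .pool2_fwd(x)
  list(out = fw$out, take_first = fw$take_first, tin = d[2], p = p)
}

pool2_backward <- function(dy, cache) {
  .pool2_bwd(dy, cache$take_first, cache$tin)
}

dropout_forward <- function(x, p, training) {
  if (!training || p == 0) return(list(out = x, mask = NULL, p = p))
  mask <- array(stats::runif(length(x)) >= p, dim = dim(x)) / (1 - p)
  list(out = x * mask, mask = mask, p = p)
}

dropout_backward <- function(dy, cache) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}

# ---- dense -----------------------------------------------------------------

dense_forward <- function(x, w, b) list(out = w %*% x + b, x = x)
dense_backward <- function(dy, w, cache) {
  list(dx = crossprod(w, dy), dw = tcrossprod(dy, cache$x), db = rowSums(dy))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# mean binary cross-entropy over all outputs; returns loss and gradient wrt
# the pre-sigmoid logits
bce_loss <- function(probs, y) {
  p <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
  grad <- (probs - y) / length(y)
  list(loss = loss, dlogits = grad)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    upd <- .adam_update(params[[nm]], grads[[nm]], state$m[[nm]],
                        state$v[[nm]], lr, beta1, beta2, eps, bc1, bc2)
    params[[nm]] <- upd$p
    state$m[[nm]] <- upd$m
    state$v[[nm]] <- upd$v
  }
  list(params = params, state = state)
}
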