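# shared fixtures, all generated in code

# small, fast synthetic recording (8 channels keeps the model tiny)
tiny_synth <- function(seed = 1L, snr = 1, duration = 30, trials = 4,
                       channels = 8L, ...) {
  synth_config(n_channels = channels, duration = duration,
               n_trials_per_class = trials, lead_time = 0.2, lag_time = 0.2,
               snr = snr, min_gap = 0.5, seed = seed, ...)
}

# hand-built recording/timeline pair with a single trigger run per class
manual_pair <- function(n_samples = 1000, n_channels = 3, run_start = 401,
                        run_len = 100, seed = 1) {
  data <- with_seed(seed, matrix(stats::rnorm(n_channels * n_samples),
                                 n_channels, n_samples))
  trig <- matrix(0, 6, n_samples)
  for (cl in 1:6) trig[cl, run_start:(run_start + run_len - 1)] <- 1
  list(recording = eeg_recording(data, sampling_rate = 500),
       timeline = event_timeline(trig))
}

# linearly separable multi-label toy batch: class c is signalled by a strong
# constant offset on channel c
separable_batch <- function(count = 40, n_channels = 6, n_window = 48,
                            seed = 1) {
  with_seed(seed, {
    labels <- matrix(stats::rbinom(count * 6, 1, 0.5), count, 6)
    data <- array(stats::rnorm(count * n_channels * n_window, 0, 0.1),
                  dim = c(count, n_channels, n_window))
    half <- n_window %/% 2L
    for (i in seq_len(count)) {
      for (cl in 1:6) {
        if (labels[i, cl] == 0) next
        ch <- (cl - 1L) %% n_channels + 1L
        # odd classes mark the first half-window, even classes the second,
        # so classes sharing a channel stay separable
        span <- if (cl <= n_channels) seq_len(n_window) else (half + 1L):n_window
        data[i, ch, span] <- data[i, ch, span] + 3
      }
    }
    colnames(labels) <- gal_class_names()
    structure(list(data = data, labels = labels, starts = seq_len(count),
                   offset = 0.5, sigma = 0, n_window = n_window),
              class = "window_batch")
  })
}

# brute-force AUC over all positive-negative pairs (independent oracle)
pairwise_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# naive per-window DFA fluctuation oracle (forward + reverse passes, lm fits)
naive_fluctuation <- function(prof, n, order = 1) {
  len <- length(prof)
  m <- len %/% n
  resids <- c()
  for (pass in 1:2) {
    p <- if (pass == 1) prof else rev(prof)
    for (w in seq_len(m)) {
      seg <- p[((w - 1) * n + 1):(w * n)]
      tt <- seq_len(n)
      fit <- stats::lm(seg ~ stats::poly(tt, order, raw = TRUE))
      resids <- c(resids, stats::residuals(fit))
    }
  }
  sqrt(mean(resids^2))
}
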