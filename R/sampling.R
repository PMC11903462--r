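#' Per-channel z-score normalization
#'
#' Normalizes each channel using mean and standard deviation computed over a
#' designated set of samples only (so statistics from training data can be
#' reused on held-out data). Channels with zero standard deviation map to
#' all-zeros.
#'
#' @param recording An [eeg_recording].
#' @param stats_from Sample indices over which to compute the statistics
#'   (default: all samples).
#' @return A list with `recording` (normalized) and `stats` (data.frame with
#'   columns `channel`, `mean`, `sd`).
#' @export
normalize_recording <- function(recording, stats_from = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (is.null(stats_from)) stats_from <- seq_len(ncol(recording$data))
  if (length(stats_from) == 0) stopf("stats_from must be non-empty")
  sub <- recording$data[, stats_from, drop = FALSE]
  mu <- rowMeans(sub)
  sd_ <- apply(sub, 1L, stats::sd)
  stats <- data.frame(channel = recording$channel_names, mean = mu, sd = sd_)
  list(recording = apply_channel_stats(recording, stats), stats = stats)
}

#' Apply stored per-channel normalization statistics
#'
#' Computes `(x - mean) / sd` per channel with the supplied statistics;
#' channels whose stored `sd` is zero map to all-zeros.
#'
#' @param recording An [eeg_recording].
#' @param stats The `stats` data.frame returned by [normalize_recording()].
#' @return A normalized [eeg_recording].
#' @export
apply_channel_stats <- function(recording, stats) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (nrow(stats) != nrow(recording$data)) {
    stopf("stats has %d rows but recording has %d channels",
          nrow(stats), nrow(recording$data))
  }
  sd_safe <- ifelse(stats$sd > 0, stats$sd, 1)
  x <- (recording$data - stats$mean) / sd_safe
  x[stats$sd == 0, ] <- 0
  eeg_recording(x, sampling_rate = recording$sampling_rate,
                channel_names = recording$channel_names)
}

#' Label position inside a window for a given offset
#'
#' Returns the sample index at which ground-truth trigger values define a
#' window's label: `start + floor(offset * (N - 1))`. Offset 0 labels at the
#' window's first sample, 0.5 at its middle, 1 at its last sample. `floor`
#' (rather than rounding) makes the rule deterministic for even-length
#' windows.
#'
#' @param start Window start index (any base; the same base is returned).
#' @param n_window Window length N in samples.
#' @param offset Label offset in `[0, 1]`.
#' @return The labeling sample index.
#' @export
#' @examples
#' label_index(1, 100, 0)    # first sample
#' label_index(1, 100, 1)    # last sample (start + 99)
#' label_index(8, 100, 0.5)  # 8 + floor(0.5 * 99) = 57
label_index <- function(start, n_window, offset) {
  if (any(offset < 0) || any(offset > 1)) stopf("offset must lie in [0, 1]")
  if (any(n_window < 1)) stopf("window length must be >= 1")
  start + floor(offset * (n_window - 1))
}

#' Draw labeled windows at random from a recording
#'
#' Draws `count` window start indices uniformly over the whole timeline (the
#' valid range `[1, n_samples - N + 1]`); each window's 6-bit label vector is
#' the trigger values at [label_index()] for the chosen offset. An optional
#' positive-enrichment fraction redraws part of the windows so their label
#' index falls inside a trigger run of a uniformly chosen class (off by
#' default; uniform sampling leaves negatives dominant).
#'
#' @param recording An [eeg_recording].
#' @param timeline The aligned [event_timeline].
#' @param n_window Window length N in samples.
#' @param count Number of windows to draw.
#' @param offset Label offset in `[0, 1]` (default 0.5).
#' @param seed Integer seed; the batch is deterministic given the seed.
#' @param enrich_positive Fraction in `[0, 1)` of windows forced to carry a
#'   positive label (default 0).
#' @return A `window_batch`: list with `data` (array `[count x channels x N]`),
#'   `labels` (matrix `[count x 6]`), `starts`, `offset`, `sigma` (0 until
#'   noise is injected) and `n_window`.
#' @export
sample_windows <- function(recording, timeline, n_window, count,
                           offset = 0.5, seed = 1L, enrich_positive = 0) {
  check_aligned(recording, timeline)
  n_samples <- ncol(recording$data)
  n_window <- as.integer(n_window)
  if (n_window < 1 || n_window > n_samples) {
    stopf("window length %d outside [1, %d]", n_window, n_samples)
  }
  if (offset < 0 || offset > 1) stopf("offset must lie in [0, 1]")
  if (enrich_positive < 0 || enrich_positive >= 1) {
    stopf("enrich_positive must lie in [0, 1)")
  }
  count <- as.integer(count)
  max_start <- n_samples - n_window + 1L
  lab_shift <- floor(offset * (n_window - 1))

  starts <- with_seed(seed, {
    s <- sample.int(max_start, count, replace = TRUE)
    n_forced <- as.integer(round(enrich_positive * count))
    if (n_forced > 0) {
      runs_by_class <- lapply(1:6, function(cl) indicator_runs(timeline$triggers[cl, ]))
      for (i in seq_len(n_forced)) {
        cl <- sample.int(6L, 1L)
        runs <- runs_by_class[[cl]]
        if (nrow(runs) == 0) next
        r <- runs[sample.int(nrow(runs), 1L), ]
        lab <- r$start + sample.int(r$length, 1L) - 1L
        st <- lab - lab_shift
        if (st >= 1L && st <= max_start) s[i] <- st
      }
    }
    s
  })

  n_ch <- nrow(recording$data)
  data <- array(0, dim = c(count, n_ch, n_window))
  labels <- matrix(0, count, 6L)
  for (i in seq_len(count)) {
    st <- starts[i]
    data[i, , ] <- recording$data[, st:(st + n_window - 1L)]
    labels[i, ] <- timeline$triggers[, st + lab_shift]
  }
  colnames(labels) <- gal_class_names()
  structure(list(data = data, labels = labels, starts = starts,
                 offset = offset, sigma = 0, n_window = n_window),
            class = "window_batch")
}

#' @export
print.window_batch <- function(x, ...) {
  cat(sprintf("<window_batch> %d windows x %d channels x %d samples (offset %g, sigma %g)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$offset, x$sigma))
  cat("positives per class:\n")
  print(colSums(x$labels))
  invisible(x)
}

#' Inject i.i.d. Gaussian noise into a window batch
#'
#' Adds an independent N(0, sigma^2) perturbation to every channel-time entry
#' (the synthetic noise-augmentation scheme, applied to normalized data).
#' Labels and start indices are never altered.
#'
#' @param batch A `window_batch`.
#' @param sigma Noise standard deviation (>= 0); 0 returns the input unchanged.
#' @param seed Integer seed.
#' @return The augmented `window_batch` with `sigma` recorded in its metadata.
#' @export
add_gaussian_noise <- function(batch, sigma, seed = 1L) {
  stopifnot(inherits(batch, "window_batch"))
  if (sigma < 0) stopf("sigma must be >= 0")
  if (sigma == 0) return(batch)
  noise <- with_seed(seed, stats::rnorm(length(batch$data), 0, sigma))
  batch$data <- batch$data + array(noise, dim = dim(batch$data))
  batch$sigma <- batch$sigma + sigma
  batch
}

# internal: subset a window batch by window indices
subset_batch <- function(batch, idx) {
  structure(list(data = batch$data[idx, , , drop = FALSE],
                 labels = batch$labels[idx, , drop = FALSE],
                 starts = batch$starts[idx], offset = batch$offset,
                 sigma = batch$sigma, n_window = batch$n_window),
            class = "window_batch")
}

#' Split a window batch into train/validation/test sets
#'
#' Random mode permutes windows before cutting (the design default);
#' time-blocked mode sorts windows by recording position and assigns
#' contiguous segments to the folds, which prevents train/test windows from
#' overlapping in the underlying recording. Fold sizes follow the rounded
#' cumulative fractions, so 1000 windows at (0.82, 0.09, 0.09) give
#' 820/90/90.
#'
#' @param batch A `window_batch`.
#' @param fractions Length-3 positive fractions summing to 1
#'   (default `c(0.82, 0.09, 0.09)`).
#' @param mode `"random"` (default) or `"blocked"`.
#' @param seed Integer seed for the random permutation.
#' @return A list with `window_batch` elements `train`, `val`, `test`.
#' @export
split_windows <- function(batch, fractions = c(0.82, 0.09, 0.09),
                          mode = c("random", "blocked"), seed = 1L) {
  stopifnot(inherits(batch, "window_batch"))
  mode <- match.arg(mode)
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stopf("fractions must be three positive values summing to 1")
  }
  n <- dim(batch$data)[1]
  if (n < 3) stopf("need at least 3 windows to split")
  ord <- if (mode == "random") {
    with_seed(seed, sample.int(n))
  } else {
    order(batch$starts)
  }
  cuts <- diff(round(cumsum(c(0, fractions)) * n))
  if (any(cuts < 1)) stopf("a fold would be empty with %d windows", n)
  idx <- split(ord, rep(1:3, times = cuts))
  list(train = subset_batch(batch, idx[[1]]),
       val = subset_batch(batch, idx[[2]]),
       test = subset_batch(batch, idx[[3]]))
}
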