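test_that("normalization z-scores per channel and guards zero variance", {
  x <- rbind(rnorm(500, 5, 2), rep(3, 500))
  rec <- eeg_recording(x, sampling_rate = 100)
  nm <- normalize_recording(rec)
  expect_equal(mean(nm$recording$data[1, ]), 0, tolerance = 1e-12)
  expect_equal(stats::sd(nm$recording$data[1, ]), 1, tolerance = 1e-12)
  expect_true(all(nm$recording$data[2, ] == 0))  # constant channel
  # stored statistics applied to new data follow the elementwise formula
  y <- rbind(rnorm(50), rnorm(50))
  rec2 <- eeg_recording(y, sampling_rate = 100)
  out <- apply_channel_stats(rec2, nm$stats)
  expect_equal(out$data[1, ], (y[1, ] - nm$stats$mean[1]) / nm$stats$sd[1])
  expect_true(all(out$data[2, ] == 0))
  expect_error(normalize_recording(rec, integer(0)), "non-empty")
})

test_that("label_index follows the floor(offset * (N - 1)) rule", {
  expect_equal(label_index(1, 100, 0), 1)
  expect_equal(label_index(1, 100, 1), 100)
  expect_equal(label_index(1, 101, 0.5), 51)   # exact middle, odd length
  expect_equal(label_index(8, 100, 0.5), 8 + floor(0.5 * 99))
  expect_error(label_index(1, 100, 1.2), "offset")
})

test_that("sample_windows respects bounds, labels and determinism", {
  p <- manual_pair()
  b1 <- sample_windows(p$recording, p$timeline, 50, count = 200, offset = 0.5,
                       seed = 3)
  expect_true(all(b1$starts >= 1 & b1$starts <= 1000 - 50 + 1))
  # labels equal the trigger values at the labelled index (direct oracle)
  shift <- floor(0.5 * 49)
  for (i in seq_len(20)) {
    expect_equal(b1$labels[i, ],
                 p$timeline$triggers[, b1$starts[i] + shift],
                 ignore_attr = TRUE)
  }
  expect_identical(sample_windows(p$recording, p$timeline, 50, 200, 0.5, seed = 3),
                   b1)
  b2 <- sample_windows(p$recording, p$timeline, 50, 200, 0.5, seed = 4)
  expect_false(identical(b1$starts, b2$starts))
  expect_error(sample_windows(p$recording, p$timeline, 2000, 10), "window length")
})

test_that("start indices are uniform over the valid range", {
  p <- manual_pair(n_samples = 500)
  b <- sample_windows(p$recording, p$timeline, 101, count = 10000, seed = 11)
  # chi-squared goodness of fit against the discrete uniform on 400 starts
  tab <- tabulate(b$starts, nbins = 400)
  pval <- stats::chisq.test(tab)$p.value
  expect_gt(pval, 1e-4)
})

test_that("offset semantics on a constructed timeline", {
  p <- manual_pair(run_start = 401, run_len = 100)
  n <- 40
  # window fully inside the run: all offsets agree
  for (off in c(0, 0.5, 1)) {
    idx <- label_index(431, n, off)
    expect_equal(unname(p$timeline$triggers[1, idx]), 1)
  }
  # window start before onset: offset 1 is positive only when the end sample
  # is inside the run
  st <- 401 - 20
  expect_equal(unname(p$timeline$triggers[1, label_index(st, n, 0)]), 0)
  expect_equal(unname(p$timeline$triggers[1, label_index(st, n, 1)]), 1)
  st2 <- 401 - 60  # end sample 401 - 60 + 39 = 380 < run start
  expect_equal(unname(p$timeline$triggers[1, label_index(st2, n, 1)]), 0)
})

test_that("the labelled action's in-window share shrinks as N grows", {
  g <- generate_eeg(tiny_synth(seed = 21, duration = 60, trials = 8))
  share <- sapply(c(100, 300, 600), function(n) {
    b <- sample_windows(g$recording, g$timeline, n, count = 400, offset = 0.5,
                        seed = 5, enrich_positive = 0.5)
    shift <- floor(0.5 * (n - 1))
    vals <- c()
    for (i in seq_len(400)) {
      pos <- which(b$labels[i, ] == 1)
      if (length(pos) == 0) next
      span <- b$starts[i]:(b$starts[i] + n - 1)
      vals <- c(vals, mean(g$timeline$triggers[pos[1], span]))
    }
    mean(vals)
  })
  expect_true(all(diff(share) < 0))
})

test_that("Gaussian noise injection has the stated moments and never touches labels", {
  p <- manual_pair()
  b <- sample_windows(p$recording, p$timeline, 320, count = 100, seed = 2)
  expect_identical(add_gaussian_noise(b, 0, seed = 9), b)
  bn <- add_gaussian_noise(b, 0.2, seed = 9)
  d <- bn$data - b$data  # ~1e6 entries
  expect_equal(mean(d), 0, tolerance = 3 * 0.2 / sqrt(length(d)))
  expect_equal(stats::sd(d), 0.2, tolerance = 0.001)
  expect_identical(bn$labels, b$labels)
  expect_identical(bn$starts, b$starts)
  for (s in c(0.001, 0.01, 0.1, 0.2)) {
    expect_s3_class(add_gaussian_noise(b, s, seed = 1), "window_batch")
  }
  expect_error(add_gaussian_noise(b, -0.1), "sigma")
})

test_that("splitting partitions windows with the rounded 82/9/9 sizes", {
  p <- manual_pair(n_samples = 3000)
  b <- sample_windows(p$recording, p$timeline, 20, count = 1000, seed = 6)
  sp <- split_windows(b, seed = 8)
  sizes <- vapply(sp, function(x) dim(x$data)[1], integer(1))
  expect_equal(unname(sizes), c(820L, 90L, 90L))
  # disjoint partition covering the input (windows identified by position)
  all_starts <- sort(c(sp$train$starts, sp$val$starts, sp$test$starts))
  expect_equal(all_starts, sort(b$starts))
  expect_identical(split_windows(b, seed = 8)$train$starts, sp$train$starts)
  # blocked mode assigns contiguous recording segments
  bl <- split_windows(b, mode = "blocked")
  expect_lt(max(bl$train$starts), min(bl$val$starts))
  expect_lt(max(bl$val$starts), min(bl$test$starts))
  expect_error(split_windows(b, fractions = c(0.5, 0.3, 0.1)), "summing to 1")
})
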