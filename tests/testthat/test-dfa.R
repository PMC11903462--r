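test_that("profile construction centers, integrates and telescopes", {
  expect_equal(dfa_profile(rep(3, 10)), rep(0, 10))
  set.seed(2)
  x <- rnorm(10)
  prof <- dfa_profile(x)
  expect_equal(prof, cumsum(x - mean(x)))  # partial-sum oracle
  expect_equal(prof[10], 0)
  # adding a constant to the raw series changes nothing downstream
  expect_equal(dfa_profile(x + 100), prof)
  expect_error(dfa_profile(1), "length")
})

test_that("a linear profile is annihilated by first-order detrending", {
  prof <- 0.3 * seq_len(256) - 7
  ff <- fluctuation_function(prof, dfa_config(min_scale = 4, max_scale = 64))
  expect_true(all(ff$fluctuations < 1e-10))
  expect_true(all(diff(ff$scales) > 0))
})

test_that("fluctuation function matches the naive per-window polyfit oracle", {
  set.seed(5)
  for (len in c(64, 128, 256, 512)) {
    prof <- dfa_profile(rnorm(len))
    cfg <- dfa_config(min_scale = 4, max_scale = 16, scales_per_decade = 4)
    ff <- fluctuation_function(prof, cfg)
    for (j in seq_along(ff$scales)) {
      expect_equal(ff$fluctuations[j], naive_fluctuation(prof, ff$scales[j]),
                   tolerance = 1e-10,
                   label = sprintf("len %d scale %d", len, ff$scales[j]))
    }
  }
})

test_that("scales with fewer than two windows are dropped with a warning", {
  prof <- dfa_profile(rnorm(40))
  expect_warning(
    ff <- fluctuation_function(prof, dfa_config(min_scale = 4, max_scale = 30)),
    "dropped")
  expect_true(all(ff$scales <= 20))
})

test_that("hurst_fit recovers an exact power law and white-noise scaling", {
  n <- c(8, 16, 32, 64, 128)
  fit <- hurst_fit(n, 3 * n^0.7)
  expect_equal(fit$hurst, 0.7, tolerance = 1e-12)
  expect_equal(fit$intercept, log(3), tolerance = 1e-12)
  # i.i.d. Gaussian series scales with H ~ 0.5
  h <- hurst_bands(with_seed(8, rnorm(2^13)))$hurst_full
  expect_lt(abs(h - 0.5), 0.05)
  expect_error(hurst_fit(c(8, 16), c(1, 2), range = c(100, 200)), "usable")
})

test_that("banded fits agree on a uniform power law and default to the 1000-sample split", {
  cfg <- dfa_config()
  expect_equal(cfg$band_split, 1000L)
  scales <- round(exp(seq(log(8), log(4000), length.out = 40)))
  f <- 0.2 * scales^0.6
  full <- hurst_fit(scales, f)$hurst
  low <- hurst_fit(scales, f, c(min(scales), 999))$hurst
  high <- hurst_fit(scales, f, c(1001, max(scales)))$hurst
  expect_equal(low, full, tolerance = 1e-10)
  expect_equal(high, full, tolerance = 1e-10)
  # piecewise power law: the union-range slope lies between the band slopes
  f2 <- ifelse(scales < 1000, scales^0.9, 1000^(0.9 - 0.3) * scales^0.3)
  h_lo <- hurst_fit(scales, f2, c(8, 999))$hurst
  h_hi <- hurst_fit(scales, f2, c(1001, 4000))$hurst
  h_all <- hurst_fit(scales, f2)$hurst
  expect_true(h_all < h_lo && h_all > h_hi)
})

test_that("a constructed crossover series yields hurst_low > hurst_high", {
  ok <- sapply(1:10, function(s) {
    x <- generate_fgn(0.9, 2^13, seed = s)
    # shuffle 256-sample blocks: short-lag persistence survives inside
    # blocks, long-range order is destroyed
    blocks <- split(x, rep(seq_len(2^13 / 256), each = 256))
    x2 <- unlist(blocks[with_seed(s, sample(length(blocks)))], use.names = FALSE)
    r <- hurst_bands(x2, dfa_config(min_scale = 8, band_split = 300))
    r$hurst_low > r$hurst_high
  })
  expect_gte(sum(ok), 9)
})

test_that("action series concatenates per-event extracts and seeds its noise", {
  p <- manual_pair(n_samples = 4000, run_start = 500, run_len = 100)
  # add two more runs for class 1
  p$timeline$triggers[1, 2000:2099] <- 1
  p$timeline$triggers[1, 3000:3099] <- 1
  s <- action_series(p$recording, p$timeline, 1, pre = 0, post = 100)
  expect_length(s, 3 * 100)
  agg <- colMeans(p$recording$data)
  expect_equal(s[1:100], agg[500:599])
  # sigma = 0 reproduces the clean series; the F(n) difference curve is zero
  s0 <- action_series(p$recording, p$timeline, 1, pre = 0, post = 400, sigma = 0)
  r0 <- hurst_bands(s0, dfa_config(min_scale = 8))
  expect_equal(dfa_difference(r0, r0)$log_f_diff, rep(0, length(r0$scales)))
  sn <- action_series(p$recording, p$timeline, 1, pre = 0, post = 100,
                      sigma = 0.2, seed = 4)
  expect_false(identical(s, sn))
  expect_identical(sn, action_series(p$recording, p$timeline, 1, pre = 0,
                                     post = 100, sigma = 0.2, seed = 4))
  # out-of-bounds events are skipped with a warning
  expect_warning(
    sb <- action_series(p$recording, p$timeline, 1, pre = 600, post = 100),
    "skipped")
  expect_length(sb, 2 * 700)
  # a class with no trigger runs is an error
  empty <- p$timeline
  empty$triggers[2, ] <- 0
  expect_error(action_series(p$recording, empty, 2, 0, 10), "no trigger runs")
})

test_that("DFA recovers the generator's Hurst exponent across the fGn family", {
  for (h_true in c(0.3, 0.5, 0.8)) {
    est <- mean(sapply(1:8, function(s) {
      hurst_bands(generate_fgn(h_true, 2^13, seed = s + 100))$hurst_full
    }))
    expect_lt(abs(est - h_true), 0.1)
  }
})
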