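test_that("roc_auc matches hand and brute-force values", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  expect_equal(roc_auc(c(0, 1, 0, 1), c(0.2, 0.3, 0.4, 0.5)), 0.75)
  # ties count one half
  expect_equal(roc_auc(c(0, 1), c(0.4, 0.4)), 0.5)
  # antisymmetry under score reversal
  set.seed(1)
  l <- rbinom(30, 1, 0.4)
  s <- rnorm(30)
  expect_equal(roc_auc(l, -s), 1 - roc_auc(l, s))
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(l, exp(2 * s + 1)), roc_auc(l, s))
  expect_error(roc_auc(c(1, 1), c(0.1, 0.2)), "single class")
})

test_that("roc_auc equals pairwise concordance on random instances", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    l <- c(0, 1, rbinom(n - 2, 1, runif(1, 0.2, 0.8)))
    s <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    expect_equal(roc_auc(l, s), pairwise_auc(l, s))
  }
})

test_that("roc_auc agrees with the pROC reference implementation", {
  set.seed(8)
  for (i in 1:5) {
    l <- c(0, 1, rbinom(40, 1, 0.5))
    s <- rnorm(42)
    ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    expect_equal(roc_auc(l, s), ref)
  }
})

test_that("micro/macro aggregation collapses, averages and pools correctly", {
  set.seed(7)
  l1 <- cbind(a = c(0, 1, rbinom(28, 1, 0.5)))
  s1 <- cbind(a = rnorm(30))
  mm1 <- micro_macro_auc(l1, s1)
  expect_equal(mm1$micro, mm1$macro)
  expect_equal(mm1$micro, roc_auc(l1[, 1], s1[, 1]))

  # identical label/score multisets per class: micro equals macro
  l <- cbind(l1, l1, l1)
  s <- cbind(s1, s1, s1)
  mm <- micro_macro_auc(l, s)
  expect_equal(mm$macro, mean(mm$per_class))
  expect_equal(mm$micro, mm$macro)

  # random 3-class instance: micro equals the pooled brute force
  l3 <- cbind(rbinom(40, 1, .3), rbinom(40, 1, .5), rbinom(40, 1, .7))
  l3[1, ] <- c(0, 0, 0); l3[2, ] <- c(1, 1, 1)
  s3 <- matrix(rnorm(120), 40, 3)
  mm3 <- micro_macro_auc(l3, s3)
  expect_equal(mm3$micro, pairwise_auc(as.vector(l3), as.vector(s3)))
  expect_equal(mm3$macro, mean(sapply(1:3, function(j) roc_auc(l3[, j], s3[, j]))))

  # degenerate class is skipped and flagged, not imputed
  ld <- cbind(rep(0, 20), rbinom(20, 1, 0.5))
  ld[1:2, 2] <- c(0, 1)
  sd_ <- matrix(rnorm(40), 20, 2)
  expect_warning(mmd <- micro_macro_auc(ld, sd_), "skipped")
  expect_true(is.na(mmd$per_class[1]))
  expect_equal(mmd$macro, mmd$per_class[[2]])
  expect_error(suppressWarnings(micro_macro_auc(cbind(rep(0, 5)), cbind(rnorm(5)))),
               "degenerate")
})

test_that("steady statistics summarize only the in-region points", {
  st <- steady_stats(c(500, 1000, 1500, 2000, 12000), c(9, 0.7, 0.8, 0.9, 9))
  expect_equal(st$mean, 0.8)
  expect_equal(st$range, 0.2)
  expect_equal(st$max, 0.9)
  expect_equal(st$std, stats::sd(c(0.7, 0.8, 0.9)))
  expect_equal(st$n_points, 3L)
  expect_equal(st$region, c(1000, 10000))  # default steady region
  cst <- steady_stats(c(1000, 2000, 3000), rep(0.75, 3))
  expect_equal(cst$std, 0)
  expect_equal(cst$range, 0)
  expect_error(steady_stats(c(1, 2), c(0.5, 0.6)), "2 points")
})

test_that("lowess reproduces constants and straight lines exactly", {
  x <- seq(1, 20)
  expect_equal(lowess_smooth(x, rep(0.6, 20), 0.4), rep(0.6, 20))
  y <- 2.5 * x - 3
  expect_equal(lowess_smooth(x, y, 0.3), y, tolerance = 1e-10)
  expect_error(lowess_smooth(1:2, 1:2), "3 points")
})

test_that("lowess matches a per-point weighted least squares oracle", {
  set.seed(9)
  x <- sort(runif(20, 0, 10))
  y <- sin(x) + rnorm(20, 0, 0.1)
  frac <- 0.4
  q <- ceiling(frac * 20)
  oracle <- sapply(seq_along(x), function(i) {
    d <- abs(x - x[i])
    idx <- order(d)[1:q]
    w <- (1 - (d[idx] / max(d[idx]))^3)^3
    df <- data.frame(xi = x[idx], yi = y[idx])
    fit <- stats::lm(yi ~ xi, data = df, weights = w)
    unname(sum(stats::coef(fit) * c(1, x[i])))
  })
  expect_equal(lowess_smooth(x, y, frac), oracle, tolerance = 1e-10)
  # invariant to input ordering
  perm <- sample(20)
  expect_equal(lowess_smooth(x[perm], y[perm], frac)[order(perm)],
               lowess_smooth(x, y, frac), tolerance = 1e-12)
})

test_that("lowess agrees with the reference implementation where the neighbour rules coincide", {
  set.seed(3)
  x <- 1:20
  y <- cos(x / 3) + rnorm(20, 0, 0.05)
  # f * n integer: floor and ceiling neighbourhoods are identical
  ref <- stats::lowess(x, y, f = 0.5, iter = 0, delta = 0)
  expect_equal(lowess_smooth(x, y, 0.5), ref$y, tolerance = 1e-8)
})
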