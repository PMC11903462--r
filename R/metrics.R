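#' Area under the ROC curve (rank formulation)
#'
#' Computes the probability that a random positive outranks a random
#' negative, with ties counted one half (the Mann-Whitney statistic, which
#' equals trapezoidal ROC integration).
#'
#' @param labels Binary vector (0/1 or logical) with at least one positive
#'   and one negative.
#' @param scores Numeric score vector of the same length.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)) # 1
#' roc_auc(c(0, 1, 0, 1), c(0.2, 0.3, 0.4, 0.5)) # 0.75
roc_auc <- function(labels, scores) {
  labels <- as.numeric(labels)
  if (length(labels) != length(scores)) stopf("labels and scores lengths differ")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stopf("AUC undefined: labels contain a single class")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Micro, macro and per-class ROC-AUC for multi-label scores
#'
#' Macro AUC is the unweighted mean of per-class AUCs; micro AUC pools all
#' (label, score) pairs across classes into a single ranking. Classes with no
#' positives or no negatives are excluded from the macro average and flagged
#' (their per-class AUC is `NA`); they still contribute their pairs to the
#' micro pool. If every class is degenerate the AUC is undefined and an
#' error is raised.
#'
#' @param labels Binary matrix `[count x n_classes]`.
#' @param scores Numeric matrix of the same shape.
#' @return List with `micro`, `macro`, `per_class` (named numeric, `NA` for
#'   skipped classes) and `skipped` (character vector of skipped classes).
#' @export
micro_macro_auc <- function(labels, scores) {
  if (!all(dim(labels) == dim(scores))) stopf("labels/scores shape mismatch")
  k <- ncol(labels)
  cls <- colnames(labels) %||% paste0("class", seq_len(k))
  per_class <- stats::setNames(rep(NA_real_, k), cls)
  for (j in seq_len(k)) {
    lj <- labels[, j]
    if (sum(lj == 1) > 0 && sum(lj == 0) > 0) {
      per_class[j] <- roc_auc(lj, scores[, j])
    }
  }
  skipped <- cls[is.na(per_class)]
  if (length(skipped) == k) stopf("AUC undefined: every class is degenerate")
  if (length(skipped)) {
    warning(sprintf("classes skipped in macro AUC (degenerate labels): %s",
                    paste(skipped, collapse = ", ")), call. = FALSE)
  }
  list(micro = roc_auc(as.vector(labels), as.vector(scores)),
       macro = mean(per_class, na.rm = TRUE),
       per_class = per_class, skipped = skipped)
}

#' Summary statistics over the steady region of a metric-vs-N series
#'
#' Mean, sample standard deviation, maximum, minimum and range of the values
#' whose N falls inside the region (defaults to N in `[1000, 10000]`, the
#' steady region of the AUC-vs-N curves).
#'
#' @param n Vector of N values (window lengths).
#' @param values Metric values paired with `n`.
#' @param region Length-2 inclusive bounds `c(n_min, n_max)`.
#' @return List with `region`, `n_points`, `mean`, `std`, `max`, `min`,
#'   `range`.
#' @export
steady_stats <- function(n, values, region = c(1000, 10000)) {
  if (length(n) != length(values)) stopf("n and values lengths differ")
  if (length(region) != 2 || region[1] >= region[2]) {
    stopf("region must be c(n_min, n_max) with n_min < n_max")
  }
  keep <- n >= region[1] & n <= region[2] & is.finite(values)
  if (sum(keep) < 2) stopf("need >= 2 points inside the steady region")
  v <- values[keep]
  list(region = region, n_points = sum(keep), mean = mean(v),
       std = stats::sd(v), max = max(v), min = min(v),
       range = max(v) - min(v))
}

#' LOWESS smoothing of a metric curve
#'
#' Locally weighted linear regression: at each point, a degree-1 polynomial
#' is fitted by weighted least squares over the `ceiling(frac * n)` nearest
#' neighbours with tricube weights `w(d) = (1 - (d/d_max)^3)^3` (no
#' robustness iterations). When the local design is degenerate (all
#' neighbours at one x), the fit falls back to the weighted mean. Fitted
#' values are returned in the input point order, so the smoother is
#' invariant to how the points were ordered.
#'
#' @param x Predictor values (>= 3 points).
#' @param y Response values.
#' @param frac Neighbourhood fraction in `(0, 1]` (default 0.3).
#' @return Numeric vector of fitted values aligned with the input order.
#' @export
lowess_smooth <- function(x, y, frac = 0.3) {
  n <- length(x)
  if (n < 3) stopf("need >= 3 points")
  if (n != length(y)) stopf("x and y lengths differ")
  if (frac <= 0 || frac > 1) stopf("frac must lie in (0, 1]")
  q <- max(2L, as.integer(ceiling(frac * n)))
  vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    idx <- order(d)[seq_len(min(q, n))]
    dmax <- max(d[idx])
    w <- if (dmax > 0) (1 - pmin(d[idx] / dmax, 1)^3)^3 else rep(1, length(idx))
    # guard against all-zero weights (can happen when every neighbour sits
    # exactly at distance dmax)
    if (sum(w) == 0) w <- rep(1, length(idx))
    xi <- x[idx]
    yi <- y[idx]
    sw <- sum(w)
    xbar <- sum(w * xi) / sw
    sxx <- sum(w * (xi - xbar)^2)
    if (sxx <= .Machine$double.eps * sum(w * xi^2 + 1)) {
      return(sum(w * yi) / sw)  # degenerate local design: weighted mean
    }
    beta <- sum(w * (xi - xbar) * yi) / sxx
    alpha <- sum(w * yi) / sw - beta * xbar
    alpha + beta * x[i]
  }, numeric(1))
}
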