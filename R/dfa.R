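#' Configuration for detrended fluctuation analysis
#'
#' @param min_scale Smallest window scale in samples (default 8; must be at
#'   least `detrend_order + 2` so each window over-determines its local fit).
#' @param max_scale Largest window scale; defaults to a quarter of the series
#'   length at run time, capped at 10000.
#' @param scales_per_decade Density of the log-spaced scale grid (default 20).
#' @param detrend_order Local polynomial detrending order (default 1, the
#'   canonical first-order DFA).
#' @param band_split Scale separating the low and high bands for the banded
#'   Hurst fits (default 1000 samples, i.e. 2 s at 500 Hz).
#' @return An object of class `dfa_config`.
#' @export
dfa_config <- function(min_scale = 8L, max_scale = NULL, scales_per_decade = 20L,
                       detrend_order = 1L, band_split = 1000L) {
  if (min_scale < detrend_order + 2) {
    stopf("min_scale must be >= detrend_order + 2")
  }
  if (scales_per_decade < 2) stopf("scales_per_decade must be >= 2")
  structure(list(min_scale = as.integer(min_scale),
                 max_scale = if (is.null(max_scale)) NULL else as.integer(max_scale),
                 scales_per_decade = as.integer(scales_per_decade),
                 detrend_order = as.integer(detrend_order),
                 band_split = as.integer(band_split)),
            class = "dfa_config")
}

#' Profile (integrated, mean-centered series) for DFA
#'
#' The cumulative sum of the mean-centered series; its last value is always
#' zero, and adding any constant to the raw series leaves it unchanged.
#'
#' @param series Numeric vector, length >= 2.
#' @return Numeric vector of the same length.
#' @export
dfa_profile <- function(series) {
  if (length(series) < 2) stopf("series must have length >= 2")
  if (anyNA(series)) stopf("series must not contain NA")
  cumsum(series - mean(series))
}

# log-spaced integer scale grid
dfa_scales <- function(len, cfg) {
  max_scale <- cfg$max_scale %||% min(len %/% 4L, 10000L)
  if (max_scale <= cfg$min_scale) {
    stopf("max_scale (%d) must exceed min_scale (%d); series too short?",
          max_scale, cfg$min_scale)
  }
  n_scales <- max(2L, round(cfg$scales_per_decade * log10(max_scale / cfg$min_scale)))
  s <- round(exp(seq(log(cfg$min_scale), log(max_scale), length.out = n_scales)))
  sort(unique(as.integer(s)))
}

#' Fluctuation function of a DFA profile
#'
#' For each scale n, the profile is partitioned into `floor(len/n)`
#' non-overlapping windows from the front and, to use the trailing samples
#' when n does not divide the length, again from the back; a polynomial of
#' the configured order is fitted in each window and F(n) is the root mean
#' square of all residuals over both passes. Scales with fewer than two
#' windows are dropped with a warning.
#'
#' @param prof Profile from [dfa_profile()].
#' @param cfg A [dfa_config()].
#' @return List with `scales` (strictly increasing integer vector) and
#'   `fluctuations` (F(n), same length).
#' @export
fluctuation_function <- function(prof, cfg = dfa_config()) {
  stopifnot(inherits(cfg, "dfa_config"))
  len <- length(prof)
  scales <- dfa_scales(len, cfg)
  usable <- scales[scales <= len %/% 2L]
  if (length(usable) < length(scales)) {
    warning(sprintf("%d scale(s) with fewer than 2 windows dropped",
                    length(scales) - length(usable)), call. = FALSE)
  }
  if (length(usable) == 0) stopf("all scales dropped; series too short")
  rev_prof <- rev(prof)
  f <- vapply(usable, function(n) {
    m <- len %/% n
    used <- m * n
    # design matrix shared by every window of this scale
    tt <- seq_len(n)
    x <- outer(tt, 0:cfg$detrend_order, `^`)
    qx <- qr(x)
    fwd <- matrix(prof[seq_len(used)], nrow = n)
    bwd <- matrix(rev_prof[seq_len(used)], nrow = n)
    r1 <- qr.resid(qx, fwd)
    r2 <- qr.resid(qx, bwd)
    sqrt(mean(c(r1^2, r2^2)))
  }, numeric(1))
  list(scales = usable, fluctuations = f)
}

#' Fit the Hurst exponent from a fluctuation function
#'
#' Ordinary least-squares slope of log F(n) versus log n restricted to the
#' given scale range. Points with F = 0 carry no information on a log scale
#' and are excluded with a warning.
#'
#' @param scales Integer scales n.
#' @param fluctuations F(n) values.
#' @param range Inclusive scale range `c(n_a, n_b)` (default: all scales).
#' @return List with `hurst` (slope), `intercept` and `n_points`.
#' @export
hurst_fit <- function(scales, fluctuations, range = NULL) {
  if (is.null(range)) range <- c(min(scales), max(scales))
  keep <- scales >= range[1] & scales <= range[2]
  if (any(fluctuations[keep] <= 0)) {
    warning("zero fluctuation values excluded from the log-log fit", call. = FALSE)
    keep <- keep & fluctuations > 0
  }
  if (sum(keep) < 2) stopf("fewer than 2 usable scales in range [%g, %g]",
                           range[1], range[2])
  lx <- log(scales[keep])
  ly <- log(fluctuations[keep])
  slope <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  list(hurst = slope, intercept = mean(ly) - slope * mean(lx),
       n_points = sum(keep))
}

#' Full and banded Hurst exponents of a series
#'
#' Runs profile construction, the fluctuation function and three log-log
#' fits: over all scales (`hurst_full`), over scales below `band_split`
#' (`hurst_low`, short fragments) and over scales above `band_split`
#' (`hurst_high`, long fragments). A band containing fewer than two scales
#' is reported as `NA` while the other fits are still returned.
#'
#' @param series Numeric series.
#' @param cfg A [dfa_config()].
#' @return Object of class `dfa_result`: list with `scales`, `fluctuations`,
#'   `hurst_full`, `hurst_low`, `hurst_high`, `fit_intercepts` and `config`.
#' @export
#' @examples
#' r <- hurst_bands(generate_fgn(0.5, 4096, seed = 3))
#' round(r$hurst_full, 2)
hurst_bands <- function(series, cfg = dfa_config()) {
  prof <- dfa_profile(series)
  ff <- fluctuation_function(prof, cfg)
  fit_band <- function(range) {
    tryCatch(hurst_fit(ff$scales, ff$fluctuations, range),
             error = function(e) list(hurst = NA_real_, intercept = NA_real_,
                                      n_points = 0L))
  }
  full <- fit_band(NULL)
  low <- fit_band(c(min(ff$scales), cfg$band_split - 1L))
  high <- fit_band(c(cfg$band_split + 1L, max(ff$scales)))
  structure(list(scales = ff$scales, fluctuations = ff$fluctuations,
                 hurst_full = full$hurst, hurst_low = low$hurst,
                 hurst_high = high$hurst,
                 fit_intercepts = c(full = full$intercept, low = low$intercept,
                                    high = high$intercept),
                 config = cfg),
            class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("<dfa_result> %d scales [%d, %d]; H_full = %.2f, H_low = %.2f, H_high = %.2f\n",
              length(x$scales), min(x$scales), max(x$scales),
              x$hurst_full, x$hurst_low, x$hurst_high))
  invisible(x)
}

#' Log-fluctuation difference between two DFA results
#'
#' `log F_b(n) - log F_a(n)` on the common scales; identically zero when the
#' two results come from the same series.
#'
#' @param a,b `dfa_result` objects (e.g. clean vs noise-augmented).
#' @return data.frame with columns `scale` and `log_f_diff`.
#' @export
dfa_difference <- function(a, b) {
  common <- intersect(a$scales, b$scales)
  ia <- match(common, a$scales)
  ib <- match(common, b$scales)
  data.frame(scale = common,
             log_f_diff = log(b$fluctuations[ib]) - log(a$fluctuations[ia]))
}

#' Concatenated per-event series for DFA of action-related EEG
#'
#' For every trigger onset of one class, extracts the channel-aggregated
#' signal over `[onset - pre, onset + post)`, concatenates the extracts in
#' temporal order and optionally perturbs the result with i.i.d. Gaussian
#' noise. Events whose window would exceed the recording bounds are skipped
#' with a warning.
#'
#' @param recording An [eeg_recording].
#' @param timeline Aligned [event_timeline].
#' @param class_id Class index 1..6 or canonical class name.
#' @param pre,post Samples before onset / after onset to extract.
#' @param sigma Gaussian noise standard deviation (default 0, none).
#' @param seed Seed for the noise draw.
#' @param aggregate `"mean"` (cross-channel mean, default) or a channel index.
#' @return Numeric series.
#' @export
action_series <- function(recording, timeline, class_id, pre = 0, post = NULL,
                          sigma = 0, seed = 1L, aggregate = "mean") {
  check_aligned(recording, timeline)
  if (is.character(class_id)) class_id <- match(class_id, gal_class_names())
  if (is.na(class_id) || class_id < 1 || class_id > 6) stopf("invalid class")
  runs <- indicator_runs(timeline$triggers[class_id, ])
  if (nrow(runs) == 0) stopf("class has no trigger runs")
  if (is.null(post)) post <- max(runs$length)
  n_samples <- ncol(recording$data)
  sig <- if (identical(aggregate, "mean")) {
    colMeans(recording$data)
  } else {
    recording$data[as.integer(aggregate), ]
  }
  pieces <- list()
  skipped <- 0L
  for (i in seq_len(nrow(runs))) {
    a <- runs$start[i] - pre
    b <- runs$start[i] + post - 1L
    if (a < 1L || b > n_samples) {
      skipped <- skipped + 1L
      next
    }
    pieces[[length(pieces) + 1L]] <- sig[a:b]
  }
  if (skipped > 0) {
    warning(sprintf("%d event(s) skipped (window exceeds recording bounds)",
                    skipped), call. = FALSE)
  }
  if (length(pieces) == 0) stopf("no events left after bounds filtering")
  out <- unlist(pieces, use.names = FALSE)
  if (sigma > 0) {
    out <- out + with_seed(seed, stats::rnorm(length(out), 0, sigma))
  }
  out
}
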