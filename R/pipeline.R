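#' Configuration of the N x offset x sigma experiment sweep
#'
#' Defaults encode the full experimental design: window lengths 100..2000 in steps of 100
#' (20 training iterations), label offsets 0/0.5/1, Gaussian noise levels
#' 0/0.001/0.01/0.1/0.2, and an 82/9/9 train/validation/test split. Each
#' (N, offset, sigma) cell trains one single-epoch model on freshly drawn
#' windows with a seed derived deterministically from `master_seed`.
#'
#' @param n_grid Strictly increasing window lengths (default `seq(100, 2000, 100)`).
#' @param offsets Label offsets in `[0, 1]` (default `c(0, 0.5, 1)`).
#' @param sigmas Gaussian noise standard deviations (default
#'   `c(0, 0.001, 0.01, 0.1, 0.2)`).
#' @param split_fractions Train/val/test fractions (default `c(0.82, 0.09, 0.09)`).
#' @param windows_per_iteration Windows drawn per cell (default 500).
#' @param steady_region Steady-region bounds for summaries (default
#'   `c(1000, 10000)`).
#' @param data Data source: a [synth_config()] or a list with `data_path` and
#'   `events_path` naming a grasp-and-lift CSV pair.
#' @param train A [train_config()]; its seed is re-derived per cell.
#' @param split_mode `"random"` (the design default) or `"blocked"` (leakage-safe).
#' @param noise_apply `"all"` (default: noise injected into every fold — the
#'   noise models an environmental disturbance) or `"train"` (train-fold
#'   only, the conventional data-augmentation comparison).
#' @param enrich_positive Positive-enrichment fraction passed to
#'   [sample_windows()] (default 0).
#' @param master_seed Master seed; every cell seed derives from it.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(n_grid = seq(100L, 2000L, by = 100L),
                         offsets = c(0, 0.5, 1),
                         sigmas = c(0, 0.001, 0.01, 0.1, 0.2),
                         split_fractions = c(0.82, 0.09, 0.09),
                         windows_per_iteration = 500L,
                         steady_region = c(1000, 10000),
                         data = synth_config(),
                         train = train_config(),
                         split_mode = c("random", "blocked"),
                         noise_apply = c("all", "train"),
                         enrich_positive = 0,
                         master_seed = 1L) {
  if (any(diff(n_grid) <= 0)) stopf("n_grid must be strictly increasing")
  if (any(offsets < 0 | offsets > 1)) stopf("offsets must lie in [0, 1]")
  if (any(sigmas < 0)) stopf("sigmas must be >= 0")
  split_mode <- match.arg(split_mode)
  noise_apply <- match.arg(noise_apply)
  structure(list(n_grid = as.integer(n_grid), offsets = offsets,
                 sigmas = sigmas, split_fractions = split_fractions,
                 windows_per_iteration = as.integer(windows_per_iteration),
                 steady_region = steady_region, data = data, train = train,
                 split_mode = split_mode, noise_apply = noise_apply,
                 enrich_positive = enrich_positive,
                 master_seed = as.integer(master_seed)),
            class = "sweep_config")
}

#' Reduced-scale sweep profile for desktop experiments
#'
#' The scaled-down study profile used by the `demo` CLI subcommand and the
#' package's own validation runs: window grid 100..600 step 100 with steady
#' region `[300, 600]`, offsets 0/0.5/1, noise levels 0 and 0.2, a 200 s
#' synthetic recording with 40 trials per class, onset-centred signatures
#' (lead = lag = 0.2 s) and signal amplitude calibrated to mid-range AUC,
#' 500 windows per cell with 25% positive enrichment, and two training
#' epochs at batch size 32. Runs in minutes on one CPU.
#'
#' @param master_seed Master seed.
#' @param windows_per_iteration Windows per sweep cell (default 500).
#' @return A [sweep_config()].
#' @export
demo_sweep_config <- function(master_seed = 1L, windows_per_iteration = 500L) {
  sweep_config(
    n_grid = seq(100L, 600L, by = 100L),
    offsets = c(0, 0.5, 1),
    sigmas = c(0, 0.2),
    windows_per_iteration = windows_per_iteration,
    steady_region = c(300, 600),
    data = synth_config(duration = 200, n_trials_per_class = 40,
                        lead_time = 0.2, lag_time = 0.2, snr = 1.2,
                        min_gap = 0.5),
    train = train_config(epochs = 2L, batch_size = 32L),
    enrich_positive = 0.25,
    master_seed = master_seed)
}

# resolve a sweep data source into a normalized recording/timeline pair.
# synthetic sources are re-seeded from the master seed so that independent
# master seeds yield independent recordings.
resolve_data <- function(cfg) {
  src <- cfg$data
  if (inherits(src, "synth_config")) {
    src$seed <- derive_seed(cfg$master_seed, 9001L, src$seed)
    g <- generate_eeg(src)
    rec <- g$recording
    tl <- g$timeline
  } else if (is.list(src) && !is.null(src$data_path)) {
    r <- read_gal(src$data_path, src$events_path,
                  sampling_rate = src$sampling_rate %||% 500)
    rec <- r$recording
    tl <- r$timeline
  } else {
    stopf("data source must be a synth_config or a list(data_path=, events_path=)")
  }
  norm <- normalize_recording(rec)
  list(recording = norm$recording, timeline = tl, stats = norm$stats)
}

# evaluate one checkpoint of a trained model on the test split
cell_records <- function(trained, test, n, offset, sigma, seed, checkpoint) {
  scores <- predict(trained, test, which = checkpoint)
  mm <- suppressWarnings(micro_macro_auc(test$labels, scores))
  cls <- c(gal_class_names(), "micro", "macro")
  auc <- c(unname(mm$per_class), mm$micro, mm$macro)
  data.frame(n_samples = n, offset = offset, sigma = sigma,
             checkpoint = checkpoint, seed = seed, class = cls, auc = auc,
             micro_auc = mm$micro, macro_auc = mm$macro)
}

#' Run the full N x offset x sigma sweep
#'
#' For every grid cell: draw windows, inject Gaussian noise, split, build and
#' train one model, and evaluate per-class/micro/macro test AUC for both the
#' best-loss and best-accuracy checkpoints. A failing cell is recorded as
#' missing (NA AUCs) with a warning carrying its coordinates, and the sweep
#' continues. The whole sweep is deterministic given `master_seed`.
#'
#' @param cfg A [sweep_config()].
#' @param progress Print per-cell progress to stderr (default FALSE).
#' @return data.frame with one row per (N, offset, sigma, checkpoint, class),
#'   where class also takes the values `"micro"` and `"macro"`.
#' @export
run_sweep <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "sweep_config"))
  src <- resolve_data(cfg)
  rows <- list()
  for (i_n in seq_along(cfg$n_grid)) {
    n <- cfg$n_grid[i_n]
    for (i_off in seq_along(cfg$offsets)) {
      offset <- cfg$offsets[i_off]
      for (i_sig in seq_along(cfg$sigmas)) {
        sigma <- cfg$sigmas[i_sig]
        seed <- derive_seed(cfg$master_seed, i_n, i_off, i_sig)
        if (progress) {
          message(sprintf("[sweep] N=%d offset=%g sigma=%g seed=%d",
                          n, offset, sigma, seed))
        }
        cell <- tryCatch({
          batch <- sample_windows(src$recording, src$timeline, n,
                                  count = cfg$windows_per_iteration,
                                  offset = offset, seed = seed,
                                  enrich_positive = cfg$enrich_positive)
          if (cfg$noise_apply == "all") {
            batch <- add_gaussian_noise(batch, sigma, seed = derive_seed(seed, 2L))
          }
          sp <- split_windows(batch, cfg$split_fractions, mode = cfg$split_mode,
                              seed = derive_seed(seed, 3L))
          if (cfg$noise_apply == "train") {
            sp$train <- add_gaussian_noise(sp$train, sigma,
                                           seed = derive_seed(seed, 2L))
          }
          spec <- model_spec(n_channels = dim(batch$data)[2], window_length = n,
                             seed = derive_seed(seed, 4L))
          tcfg <- cfg$train
          tcfg$seed <- derive_seed(seed, 5L)
          trained <- train_model(build_model(spec), sp$train, sp$val, tcfg)
          rbind(cell_records(trained, sp$test, n, offset, sigma, seed, "best_loss"),
                cell_records(trained, sp$test, n, offset, sigma, seed, "best_acc"))
        }, error = function(e) {
          warning(sprintf("cell (N=%d, offset=%g, sigma=%g, seed=%d) failed: %s",
                          n, offset, sigma, seed, conditionMessage(e)),
                  call. = FALSE)
          data.frame(n_samples = n, offset = offset, sigma = sigma,
                     checkpoint = rep(c("best_loss", "best_acc"), each = 8L),
                     seed = seed, class = rep(c(gal_class_names(), "micro", "macro"), 2L),
                     auc = NA_real_, micro_auc = NA_real_, macro_auc = NA_real_)
        })
        rows[[length(rows) + 1L]] <- cell
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Steady-region tables and smoothed AUC-vs-N curves
#'
#' Per (offset, sigma, checkpoint, class): mean, sample standard deviation,
#' maximum, minimum and range of AUC over the steady region, plus
#' LOWESS-smoothed AUC-vs-N curves.
#'
#' @param records Sweep records from [run_sweep()].
#' @param steady_region Inclusive N bounds (default `c(1000, 10000)`).
#' @param lowess_frac LOWESS neighbourhood fraction (default 0.3).
#' @return List with data.frames `steady` and `smooth`.
#' @export
summarize_sweep <- function(records, steady_region = c(1000, 10000),
                            lowess_frac = 0.3) {
  if (nrow(records) == 0) stopf("no records to summarize")
  key <- interaction(records$offset, records$sigma, records$checkpoint,
                     records$class, drop = TRUE)
  groups <- split(records, key)
  steady <- do.call(rbind, lapply(groups, function(g) {
    st <- tryCatch(steady_stats(g$n_samples, g$auc, steady_region),
                   error = function(e) NULL)
    data.frame(offset = g$offset[1], sigma = g$sigma[1],
               checkpoint = g$checkpoint[1], class = g$class[1],
               mean = st$mean %||% NA_real_, std = st$std %||% NA_real_,
               max = st$max %||% NA_real_, min = st$min %||% NA_real_,
               range = st$range %||% NA_real_,
               n_points = st$n_points %||% 0L)
  }))
  smooth <- do.call(rbind, lapply(groups, function(g) {
    g <- g[is.finite(g$auc), , drop = FALSE]
    if (nrow(g) < 3) return(NULL)
    data.frame(offset = g$offset, sigma = g$sigma, checkpoint = g$checkpoint,
               class = g$class, n_samples = g$n_samples, auc = g$auc,
               smooth = lowess_smooth(g$n_samples, g$auc, lowess_frac))
  }))
  rownames(steady) <- NULL
  if (!is.null(smooth)) rownames(smooth) <- NULL
  list(steady = steady, smooth = smooth)
}

#' Banded Hurst-exponent table for action-related EEG under noise
#'
#' For each of the six classes and each noise level: builds the concatenated
#' per-event series ([action_series()]), runs [hurst_bands()] and collects
#' H_full/H_low/H_high (reported rounded to two decimals; full precision is
#' kept in the `results` element). Log-fluctuation difference curves against
#' the first (reference) noise level are included for each higher level.
#'
#' @param recording An [eeg_recording] (normalized units recommended).
#' @param timeline Aligned [event_timeline].
#' @param sigmas Noise levels (default `c(0, 0.2)`).
#' @param dfa A [dfa_config()].
#' @param pre,post Extraction span around each onset in samples; default
#'   one event duration before and three after the onset.
#' @param seed Seed for the noise draws.
#' @return List with `table` (data.frame class x sigma with rounded H
#'   columns), `results` (list of `dfa_result`), `differences` (data.frame of
#'   log F difference curves vs the reference level).
#' @export
run_dfa_stage <- function(recording, timeline, sigmas = c(0, 0.2),
                          dfa = dfa_config(), pre = NULL, post = NULL,
                          seed = 1L) {
  check_aligned(recording, timeline)
  act <- max(1L, round(stats::median(unlist(lapply(1:6, function(cl) {
    indicator_runs(timeline$triggers[cl, ])$length
  })))))
  if (is.null(pre)) pre <- act
  if (is.null(post)) post <- 3L * act
  rows <- list()
  results <- list()
  diffs <- list()
  for (cl in 1:6) {
    ref <- NULL
    for (i_sig in seq_along(sigmas)) {
      sigma <- sigmas[i_sig]
      res <- tryCatch({
        s <- action_series(recording, timeline, cl, pre = pre, post = post,
                           sigma = sigma, seed = derive_seed(seed, cl, i_sig))
        hurst_bands(s, dfa)
      }, error = function(e) {
        warning(sprintf("DFA row missing (class %s, sigma %g): %s",
                        gal_class_names()[cl], sigma, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
      key <- sprintf("%s_sigma%g", gal_class_names()[cl], sigma)
      results[[key]] <- res
      rows[[key]] <- data.frame(
        class = gal_class_names()[cl], sigma = sigma,
        h_full = if (is.null(res)) NA_real_ else round(res$hurst_full, 2),
        h_low = if (is.null(res)) NA_real_ else round(res$hurst_low, 2),
        h_high = if (is.null(res)) NA_real_ else round(res$hurst_high, 2))
      if (i_sig == 1L) {
        ref <- res
      } else if (!is.null(ref) && !is.null(res)) {
        d <- dfa_difference(ref, res)
        d$class <- gal_class_names()[cl]
        d$sigma <- sigma
        diffs[[key]] <- d
      }
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  differences <- if (length(diffs)) do.call(rbind, diffs) else
    data.frame(scale = integer(0), log_f_diff = numeric(0),
               class = character(0), sigma = numeric(0))
  rownames(differences) <- NULL
  list(table = table, results = results, differences = differences)
}
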