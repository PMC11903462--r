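#' Configuration for the synthetic grasp-and-lift style EEG generator
#'
#' Describes a synthetic multi-channel recording with six partially
#' overlapping binary event (trigger) series. Each "trial" contains one
#' occurrence of every action class in the canonical order, with the
#' configured pair of classes sharing onsets (emulating the strong temporal
#' overlap between FirstDigitTouch and BothStartLoadPhase). Class signatures
#' are damped-oscillation (Hann-windowed sinusoid) templates with a
#' class-specific frequency and channel-weight vector, injected on top of
#' 1/f-type background noise.
#'
#' @param n_channels Number of EEG channels (default 32).
#' @param sampling_rate Sampling rate in Hz (default 500).
#' @param duration Recording length in seconds.
#' @param n_trials_per_class Number of occurrences of each class.
#' @param action_duration Trigger (event) duration in seconds (default 0.3,
#'   i.e. 150 samples at 500 Hz).
#' @param lead_time Pre-onset signature extent in seconds; scalar or length-6
#'   vector. Defaults to 0.4 s for HandStart, Replace and BothReleased
#'   (classes with anticipatory activity) and 0.1 s for the others.
#' @param lag_time Post-offset signature extent in seconds; scalar or
#'   length-6 vector (default 0.2).
#' @param snr Signal amplitude ratio: peak per-channel signature amplitude
#'   relative to the unit-variance background. `snr = 0` injects no signal.
#' @param overlap_classes Pair of class indices forced to share onsets
#'   (default `c(2, 3)`).
#' @param background_exponent Spectral slope beta of the 1/f^beta background
#'   (default 1, pink noise).
#' @param min_gap Minimum gap in seconds between the end of one trial's last
#'   signature and the next trial block (default 1).
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   full configuration.
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_channels = 32, sampling_rate = 500, duration = 60,
                         n_trials_per_class = 10, action_duration = 0.3,
                         lead_time = NULL, lag_time = 0.2, snr = 1,
                         overlap_classes = c(2L, 3L),
                         background_exponent = 1, min_gap = 1, seed = 1L) {
  if (n_channels < 1) stopf("n_channels must be >= 1")
  if (sampling_rate <= 0) stopf("sampling_rate must be > 0")
  if (duration <= 0) stopf("duration must be > 0")
  if (n_trials_per_class < 1) stopf("n_trials_per_class must be >= 1")
  if (snr < 0) stopf("snr must be >= 0")
  action_samples <- round(action_duration * sampling_rate)
  if (action_samples < 1) stopf("action_duration x sampling_rate must round to >= 1")
  if (is.null(lead_time)) {
    lead_time <- c(0.4, 0.1, 0.1, 0.1, 0.4, 0.4)
  }
  lead_time <- rep_len(lead_time, 6L)
  lag_time <- rep_len(lag_time, 6L)
  if (any(lead_time < 0) || any(lag_time < 0)) stopf("lead/lag times must be >= 0")
  overlap_classes <- as.integer(overlap_classes)
  if (length(overlap_classes) != 2L || any(overlap_classes < 1L) ||
      any(overlap_classes > 6L) || overlap_classes[1] == overlap_classes[2]) {
    stopf("overlap_classes must be two distinct class indices in 1..6")
  }
  structure(
    list(n_channels = as.integer(n_channels), sampling_rate = sampling_rate,
         duration = duration, n_trials_per_class = as.integer(n_trials_per_class),
         action_duration = action_duration, lead_time = lead_time,
         lag_time = lag_time, snr = snr, overlap_classes = overlap_classes,
         background_exponent = background_exponent, min_gap = min_gap,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# 1/f^beta background: spectrally shaped white Gaussian noise, z-scored
spectral_noise <- function(n, beta, sampling_rate) {
  w <- stats::rnorm(n)
  if (beta == 0) return(as.numeric(scale(w)))
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) * sampling_rate / n
  amp <- ifelse(f > 0, f^(-beta / 2), 0)
  x <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Generate a synthetic EEG recording with embedded action events
#'
#' Produces a recording (1/f-type background plus class-specific
#' spatiotemporal signatures) and the paired binary event timeline. For each
#' occurrence of class `c` with trigger run `[onset, onset + action)`, the
#' signature spans `[onset - lead_time_c, onset + action + lag_time_c)`. The
#' two `overlap_classes` share onsets exactly.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_eeg` with elements `recording`
#'   ([eeg_recording]), `timeline` ([event_timeline]), `onsets` (list of
#'   1-based onset sample indices per class), `signatures` (per-class
#'   template, channel weights, frequency) and `config`.
#' @export
#' @examples
#' g <- generate_eeg(synth_config(duration = 30, n_trials_per_class = 4, seed = 7))
#' g$recording
#' g$timeline
generate_eeg <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$sampling_rate
  n_samples <- round(config$duration * fs)
  act <- round(config$action_duration * fs)
  lead <- round(config$lead_time * fs)
  lag <- round(config$lag_time * fs)
  n_trials <- config$n_trials_per_class

  # event slots per trial block: canonical order, overlap pair merged
  pair <- sort(config$overlap_classes)
  slot_classes <- list()
  for (cl in 1:6) {
    if (cl == pair[2]) next
    slot_classes[[length(slot_classes) + 1L]] <- if (cl == pair[1]) pair else cl
  }
  n_slots <- length(slot_classes)

  block_len <- n_samples / n_trials
  margin_front <- max(lead) + 1
  margin_back <- act + max(lag) + round(config$min_gap * fs)
  avail <- block_len - margin_front - margin_back
  min_step <- act
  if (avail < (n_slots - 1) * min_step) {
    stopf(paste0("duration too short: each trial block needs >= %.2f s ",
                 "(lead + %d events + lag + gap) but only %.2f s available"),
          (margin_front + margin_back + (n_slots - 1) * min_step) / fs,
          n_slots, block_len / fs)
  }
  step <- if (n_slots > 1) avail / (n_slots - 1) else 0
  jit_amp <- max(0, 0.3 * (step - min_step))

  out <- with_seed(config$seed, {
    # class signatures, drawn once per seed
    signatures <- vector("list", 6L)
    for (cl in 1:6) {
      len <- lead[cl] + act + lag[cl]
      freq <- stats::runif(1, 8, 25)
      phase <- stats::runif(1, 0, 2 * pi)
      w <- stats::rnorm(config$n_channels)
      w <- w / max(abs(w))
      tt <- (seq_len(len) - 1) / fs
      env <- 0.5 * (1 - cos(2 * pi * (seq_len(len) - 1) / (len - 1)))
      tmpl <- env * sin(2 * pi * freq * tt + phase)
      tmpl <- tmpl / sqrt(mean(tmpl^2))
      signatures[[cl]] <- list(template = tmpl, weights = w, freq = freq,
                               lead = lead[cl], lag = lag[cl])
    }

    data <- matrix(0, config$n_channels, n_samples)
    for (ch in seq_len(config$n_channels)) {
      data[ch, ] <- spectral_noise(n_samples, config$background_exponent, fs)
    }

    onsets <- rep(list(integer(0)), 6L)
    for (b in seq_len(n_trials)) {
      block_start <- (b - 1) * block_len
      for (k in seq_len(n_slots)) {
        jit <- if (jit_amp > 0) stats::runif(1, -jit_amp, jit_amp) else 0
        onset <- round(block_start + margin_front + (k - 1) * step + jit) + 1L
        onset <- max(1L + max(lead), min(onset, n_samples - act - max(lag)))
        for (cl in slot_classes[[k]]) {
          onsets[[cl]] <- c(onsets[[cl]], onset)
        }
      }
    }

    triggers <- matrix(0, 6L, n_samples)
    if (config$snr > 0) {
      for (cl in 1:6) {
        sig <- signatures[[cl]]
        for (onset in onsets[[cl]]) {
          idx <- (onset - sig$lead):(onset + act + sig$lag - 1L)
          add <- config$snr * outer(sig$weights, sig$template)
          data[, idx] <- data[, idx] + add
        }
      }
    }
    for (cl in 1:6) {
      for (onset in onsets[[cl]]) {
        triggers[cl, onset:(onset + act - 1L)] <- 1
      }
    }
    list(data = data, triggers = triggers, onsets = onsets,
         signatures = signatures)
  })

  structure(
    list(recording = eeg_recording(out$data, sampling_rate = fs),
         timeline = event_timeline(out$triggers),
         onsets = out$onsets, signatures = out$signatures, config = config),
    class = "synth_eeg"
  )
}

#' @export
print.synth_eeg <- function(x, ...) {
  cat("<synth_eeg>\n")
  print(x$recording)
  print(x$timeline)
  invisible(x)
}

#' Generate fractional Gaussian noise of known Hurst exponent
#'
#' Exact synthesis by Davies-Harte circulant embedding of the fGn
#' autocovariance gamma(k) = (|k+1|^(2H) - 2|k|^(2H) + |k-1|^(2H)) / 2.
#' The output is a stationary zero-mean process with theoretical unit
#' variance; `hurst = 0.5` reduces to i.i.d. standard Gaussian noise. Used to
#' validate the detrended-fluctuation Hurst estimator.
#'
#' @param hurst Target Hurst exponent in (0, 1].
#' @param length Series length (>= 2).
#' @param seed Integer seed; output is deterministic given `seed`.
#' @return Numeric vector of the requested length.
#' @export
#' @examples
#' x <- generate_fgn(0.8, 1024, seed = 1)
#' var(x) # close to 1
generate_fgn <- function(hurst, length, seed = 1L) {
  if (!is.numeric(hurst) || hurst <= 0 || hurst > 1) {
    stopf("hurst must lie in (0, 1]")
  }
  n <- as.integer(length)
  if (is.na(n) || n < 2L) stopf("length must be >= 2")

  k <- 0:n
  gamma_k <- 0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                      abs(k - 1)^(2 * hurst))
  m <- 2L * n
  circ <- c(gamma_k[1:n], gamma_k[n + 1L], rev(gamma_k[2:n]))
  lambda <- Re(stats::fft(circ))
  lambda[lambda < 0 & lambda > -1e-8] <- 0
  if (any(lambda < 0)) {
    stopf("circulant embedding failed (negative eigenvalue); hurst = %g", hurst)
  }

  with_seed(seed, {
    w <- complex(length.out = m)
    z <- stats::rnorm(2L)
    w[1] <- sqrt(lambda[1]) * z[1]
    w[n + 1L] <- sqrt(lambda[n + 1L]) * z[2]
    v1 <- stats::rnorm(n - 1L)
    v2 <- stats::rnorm(n - 1L)
    w[2:n] <- sqrt(lambda[2:n] / 2) * complex(real = v1, imaginary = v2)
    w[m:(n + 2L)] <- Conj(w[2:n])
    x <- Re(stats::fft(w)) / sqrt(m)
    x[1:n]
  })
}
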