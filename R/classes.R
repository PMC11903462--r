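#' Canonical grasp-and-lift action class names
#'
#' The six hand-action event classes of the grasp-and-lift paradigm, in the
#' fixed order used by every module of this package (single source of truth).
#'
#' @return Character vector of length 6.
#' @export
#' @examples
#' gal_class_names()
gal_class_names <- function() {
  c("HandStart", "FirstDigitTouch", "BothStartLoadPhase",
    "LiftOff", "Replace", "BothReleased")
}

#' Construct an EEG recording container
#'
#' A thin validated container: a channels x time numeric matrix plus the
#' sampling rate and channel names.
#'
#' @param data Numeric matrix `[n_channels x n_samples]`, no missing values.
#' @param sampling_rate Sampling rate in Hz (default 500, the grasp-and-lift
#'   acquisition rate).
#' @param channel_names Optional character vector; defaults to Ch01..ChNN.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate = 500, channel_names = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stopf("`data` must be a numeric matrix [n_channels x n_samples]")
  }
  if (anyNA(data)) stopf("recording data must not contain missing values")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stopf("`sampling_rate` must be > 0")
  }
  if (is.null(channel_names)) {
    channel_names <- sprintf("Ch%02d", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data)) {
    stopf("length(channel_names) must equal n_channels")
  }
  structure(
    list(data = data, sampling_rate = sampling_rate,
         channel_names = as.character(channel_names)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  invisible(x)
}

#' Construct an event timeline container
#'
#' Binary trigger series (one row per action class) aligned sample-for-sample
#' with an [eeg_recording].
#'
#' @param triggers Binary matrix `[6 x n_samples]`, entries in `{0, 1}`.
#' @param class_names Class names; must be the canonical six in canonical
#'   order (see [gal_class_names()]).
#' @return An object of class `event_timeline`.
#' @export
event_timeline <- function(triggers, class_names = gal_class_names()) {
  if (!is.matrix(triggers)) stopf("`triggers` must be a matrix [classes x samples]")
  if (!all(triggers %in% c(0, 1))) stopf("trigger entries must all be 0 or 1")
  if (!identical(as.character(class_names), gal_class_names())) {
    stopf("class_names must be the canonical six grasp-and-lift names in order")
  }
  if (nrow(triggers) != length(class_names)) {
    stopf("triggers must have one row per class")
  }
  storage.mode(triggers) <- "double"
  rownames(triggers) <- class_names
  structure(list(triggers = triggers, class_names = as.character(class_names)),
            class = "event_timeline")
}

#' @export
print.event_timeline <- function(x, ...) {
  act <- rowSums(x$triggers)
  cat(sprintf("<event_timeline> 6 classes x %d samples; active samples per class:\n",
              ncol(x$triggers)))
  print(stats::setNames(as.integer(act), x$class_names))
  invisible(x)
}

# internal: check a recording/timeline pair is aligned
check_aligned <- function(recording, timeline) {
  stopifnot(inherits(recording, "eeg_recording"), inherits(timeline, "event_timeline"))
  if (ncol(recording$data) != ncol(timeline$triggers)) {
    stopf("recording (%d samples) and timeline (%d samples) are not aligned",
          ncol(recording$data), ncol(timeline$triggers))
  }
  invisible(TRUE)
}

#' Locate contiguous runs of an indicator vector
#'
#' @param x Numeric/logical vector of 0/1.
#' @return data.frame with columns `start`, `end` (inclusive, 1-based) and `length`.
#' @keywords internal
indicator_runs <- function(x) {
  r <- rle(as.numeric(x) > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}
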