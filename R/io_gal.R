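#' Read a grasp-and-lift CSV file pair
#'
#' Reads the Kaggle grasp-and-lift dialect: a `*_data.csv` with an `id`
#' column plus one column per EEG channel, and a `*_events.csv` with an `id`
#' column plus exactly the six canonical event columns. Row order is
#' preserved; the two files must share identical id sequences row-for-row.
#' The sampling rate is not stored in these files; it defaults to the 500 Hz
#' acquisition rate of the dataset.
#'
#' @param data_path Path to the `*_data.csv` file.
#' @param events_path Path to the `*_events.csv` file.
#' @param sampling_rate Sampling rate in Hz (default 500).
#' @return A list with elements `recording` ([eeg_recording]) and `timeline`
#'   ([event_timeline]).
#' @export
read_gal <- function(data_path, events_path, sampling_rate = 500) {
  if (!file.exists(data_path)) stopf("data file not found: %s", data_path)
  if (!file.exists(events_path)) stopf("events file not found: %s", events_path)
  dat <- data.table::fread(data_path, header = TRUE, data.table = FALSE)
  ev <- data.table::fread(events_path, header = TRUE, data.table = FALSE)
  if (!"id" %in% names(dat) || !"id" %in% names(ev)) {
    stopf("both files must contain an 'id' column")
  }
  if (nrow(dat) != nrow(ev)) {
    stopf("alignment error: %d data rows vs %d event rows", nrow(dat), nrow(ev))
  }
  if (!identical(as.character(dat$id), as.character(ev$id))) {
    stopf("alignment error: id sequences of the two files differ")
  }
  ev_cols <- setdiff(names(ev), "id")
  if (!setequal(ev_cols, gal_class_names())) {
    stopf("schema error: event columns must be exactly {%s}; got {%s}",
          paste(gal_class_names(), collapse = ", "),
          paste(ev_cols, collapse = ", "))
  }
  trig <- t(as.matrix(ev[, gal_class_names(), drop = FALSE]))
  if (!all(trig %in% c(0, 1))) stopf("value error: event values must be 0 or 1")
  ch_cols <- setdiff(names(dat), "id")
  if (length(ch_cols) < 1) stopf("schema error: no channel columns in data file")
  x <- t(as.matrix(dat[, ch_cols, drop = FALSE]))
  if (!is.numeric(x) || anyNA(x)) stopf("value error: channel data must be numeric, no NA")
  list(recording = eeg_recording(x, sampling_rate = sampling_rate,
                                 channel_names = ch_cols),
       timeline = event_timeline(trig))
}

#' Write a recording/timeline pair in the grasp-and-lift CSV dialect
#'
#' Emits the two CSVs that [read_gal()] accepts. The `id` column is
#' `sample_0 .. sample_(n-1)`.
#'
#' @param recording An [eeg_recording].
#' @param timeline An aligned [event_timeline].
#' @param data_path Output path for the data CSV.
#' @param events_path Output path for the events CSV.
#' @return Invisibly, a list with the two paths.
#' @export
write_gal <- function(recording, timeline, data_path, events_path) {
  check_aligned(recording, timeline)
  n <- ncol(recording$data)
  id <- sprintf("sample_%d", seq_len(n) - 1L)
  dat <- data.table::as.data.table(t(recording$data))
  data.table::setnames(dat, recording$channel_names)
  dat <- cbind(data.table::data.table(id = id), dat)
  ev <- data.table::as.data.table(t(timeline$triggers))
  data.table::setnames(ev, gal_class_names())
  ev <- cbind(data.table::data.table(id = id), ev)
  data.table::fwrite(dat, data_path)
  data.table::fwrite(ev, events_path)
  invisible(list(data_path = data_path, events_path = events_path))
}

#' Write sweep results to CSV with a JSON run manifest
#'
#' One CSV row per (N, offset, sigma, checkpoint, class) including the
#' `micro` and `macro` aggregate rows, with the fixed column set
#' `n_samples, offset, sigma, checkpoint, seed, class, auc, micro_auc,
#' macro_auc`. A JSON sidecar (`<path basename>_manifest.json`) records the
#' run configuration and seeds.
#'
#' @param records A data.frame of sweep records (see [run_sweep()]).
#' @param path Output CSV path.
#' @param config Optional configuration object serialized into the manifest.
#' @return Invisibly, the CSV path.
#' @export
write_results <- function(records, path, config = NULL) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stopf("records must be a non-empty data.frame")
  }
  cols <- c("n_samples", "offset", "sigma", "checkpoint", "seed",
            "class", "auc", "micro_auc", "macro_auc")
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols)) {
    stopf("records missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  data.table::fwrite(records[, cols], path)
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    n_records = nrow(records),
    seeds = sort(unique(records$seed)),
    config = config
  )
  manifest_path <- paste0(sub("\\.csv$", "", path), "_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}
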