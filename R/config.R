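#' Default package configuration
#'
#' One nested list covering every stage, in the same shape the YAML config
#' file uses: `preprocess` (filter and window specs per modality),
#' `features`, `svm`, `cv`, `engine`, `synthetic`, `protocol`.
#' @export
default_config <- function() {
  list(
    preprocess = list(
      eeg = list(filter = list(family = "fir_hamming_sinc", low_hz = 3,
                               high_hz = 40, order = 2000),
                 window = list(length_s = 0.5, overlap_frac = 0.8,
                               ptp_reject_threshold = 150),
                 channels = c("Cz", "C3", "C4", "CPz", "CP1", "CP2")),
      sc = list(filter = list(family = "cheby1", low_hz = 0.05, high_hz = 2,
                              order = 3, ripple_db = 0.5),
                window = list(length_s = 2, overlap_frac = 0.8,
                              ptp_reject_threshold = 10)),
      patient = list(window = list(length_s = 1, overlap_frac = 0,
                                   ptp_reject_threshold = 150))),
    svm = list(C = 1, gamma = 0.01),
    cv = list(k = 4),
    engine = list(),
    synthetic = list(),
    protocol = list(mode = "healthy"))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a YAML configuration, merged over the defaults
#' @param path YAML file; `NULL` returns [default_config()].
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      abort_painbci(sprintf("config not found: %s", path),
                    "painbci_format_error")
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

spec_from_config <- function(cfg_mod) {
  f <- cfg_mod$filter
  list(filter = filter_spec(f$family, f$low_hz, f$high_hz, f$order,
                            f$ripple_db %||% 0.5),
       window = window_spec(cfg_mod$window$length_s,
                            cfg_mod$window$overlap_frac,
                            cfg_mod$window$ptp_reject_threshold))
}

#' Offline pipeline: recording + events to kept feature table
#'
#' Band-pass, (EEG) channel selection, ROW extraction, artifact rejection,
#' feature computation — the standard offline path for one modality.
#'
#' @param rec a `bci_recording`.
#' @param events a `bci_events` table.
#' @param config nested config list (see [default_config()]).
#' @param patient use the patient window spec for EEG.
#' @return A `bci_features` table of kept windows; rejected count in
#'   attribute `n_rejected`.
#' @export
offline_features <- function(rec, events, config = default_config(),
                             patient = FALSE) {
  key <- if (rec$modality == "EEG") "eeg" else "sc"
  sp <- spec_from_config(config$preprocess[[key]])
  if (patient && rec$modality == "EEG") {
    pw <- config$preprocess$patient$window
    sp$window <- window_spec(pw$length_s, pw$overlap_frac,
                             pw$ptp_reject_threshold)
  }
  filtered <- bandpass(rec, sp$filter)
  if (rec$modality == "EEG") {
    want <- config$preprocess$eeg$channels
    if (all(want %in% rec$channel_names))
      filtered <- select_channels(filtered, want)
  }
  ws <- extract_windows(filtered, events, sp$window)
  parts <- reject_artifacts(ws, sp$window$ptp_reject_threshold)
  ft <- compute_features(parts$kept)
  attr(ft, "n_rejected") <- n_windows(parts$rejected)
  ft
}

#' Select channels of a recording by name
#'
#' Returns the sub-recording with rows in the requested order. The default
#' selection is the centro-parietal montage over the somatosensory cortex
#' (Cz, C3, C4, CPz, CP1, CP2).
#'
#' @param rec a `bci_recording`.
#' @param names channel labels to keep, in output order.
#' @export
select_channels <- function(rec, names = c("Cz", "C3", "C4", "CPz",
                                           "CP1", "CP2")) {
  validate_recording(rec)
  missing <- setdiff(names, rec$channel_names)
  if (length(missing))
    abort_painbci(sprintf("channel(s) %s not present; available: %s",
                          paste(missing, collapse = ", "),
                          paste(rec$channel_names, collapse = ", ")),
                  "painbci_validation_error")
  idx <- match(names, rec$channel_names)
  recording(rec$data[idx, , drop = FALSE], rec$fs, names, rec$modality,
            rec$t0)
}
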