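#' Construct a uniformly sampled recording
#'
#' A recording is a channels-by-samples numeric matrix with a sampling rate,
#' ordered channel labels and a modality tag. EEG is in microvolts, skin
#' conductance (SC) in microsiemens. SC recordings carry exactly one channel.
#'
#' @param data numeric matrix, channels in rows, samples in columns. A bare
#'   vector is treated as a single channel.
#' @param fs sampling rate in Hz, strictly positive.
#' @param channel_names character vector, one label per row of `data`.
#' @param modality `"EEG"` or `"SC"`.
#' @param t0 start time in seconds (default 0).
#' @return An object of class `bci_recording`.
#' @export
recording <- function(data, fs, channel_names = NULL,
                      modality = c("EEG", "SC"), t0 = 0) {
  modality <- match.arg(modality)
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  if (!is.matrix(data) || !is.numeric(data))
    abort_painbci("`data` must be a numeric matrix (channels x samples)",
                  "painbci_validation_error")
  if (is.null(channel_names))
    channel_names <- if (modality == "SC" && nrow(data) == 1) "SC"
                     else paste0("ch", seq_len(nrow(data)))
  rec <- structure(list(data = data, fs = fs,
                        channel_names = as.character(channel_names),
                        modality = modality, t0 = t0),
                   class = "bci_recording")
  validate_recording(rec)
  rec
}

#' Validate a recording's invariants
#'
#' Checks positive sampling rate, matching channel labels, finite samples and
#' the single-channel constraint for SC. Invisibly returns its input.
#' @param rec a `bci_recording`.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "bci_recording"))
  if (!is.numeric(rec$fs) || length(rec$fs) != 1 || rec$fs <= 0)
    abort_painbci("sampling rate `fs` must be a single positive number",
                  "painbci_validation_error")
  if (nrow(rec$data) != length(rec$channel_names))
    abort_painbci("number of data rows must equal number of channel names",
                  "painbci_validation_error")
  if (!all(is.finite(rec$data)))
    abort_painbci("recording contains non-finite samples",
                  "painbci_validation_error")
  if (rec$modality == "SC" && nrow(rec$data) != 1)
    abort_painbci("SC recordings must have exactly one channel",
                  "painbci_validation_error")
  invisible(rec)
}

#' @export
print.bci_recording <- function(x, ...) {
  cat(sprintf("<bci_recording> %s: %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              x$modality, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a `bci_recording`.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

#' Construct an event table
#'
#' Condition markers for a session: onset and duration in seconds from the
#' recording start and a label from `P` (painful / focus-on-pain), `NP`
#' (non-painful) or `R` (rest). Stored in BIDS-events column order
#' (`onset`, `duration`, `trial_type`, `event_id`).
#'
#' @param onset numeric vector of onsets (s), non-decreasing.
#' @param duration numeric vector of durations (s), strictly positive.
#' @param label character vector of condition labels.
#' @param event_id unique integer ids; defaults to `1:n`.
#' @return A data frame of class `bci_events`.
#' @export
event_table <- function(onset, duration, label, event_id = seq_along(onset)) {
  tbl <- data.frame(onset = as.numeric(onset),
                    duration = as.numeric(duration),
                    trial_type = as.character(label),
                    event_id = as.integer(event_id),
                    stringsAsFactors = FALSE)
  class(tbl) <- c("bci_events", "data.frame")
  validate_events(tbl)
  tbl
}

#' Validate an event table's invariants
#' @param tbl a `bci_events` data frame.
#' @export
validate_events <- function(tbl) {
  need <- c("onset", "duration", "trial_type", "event_id")
  if (!all(need %in% names(tbl)))
    abort_painbci(paste("event table must have columns",
                        paste(need, collapse = ", ")),
                  "painbci_validation_error")
  if (nrow(tbl) == 0) return(invisible(tbl))
  bad <- setdiff(unique(tbl$trial_type), CONDITION_LABELS)
  if (length(bad))
    abort_painbci(sprintf("unknown label(s) %s; allowed: %s",
                          paste(bad, collapse = ", "),
                          paste(CONDITION_LABELS, collapse = ", ")),
                  "painbci_validation_error")
  if (is.unsorted(tbl$onset))
    abort_painbci("event onsets must be non-decreasing",
                  "painbci_validation_error")
  if (any(tbl$duration <= 0))
    abort_painbci("event durations must be > 0", "painbci_validation_error")
  if (anyDuplicated(tbl$event_id))
    abort_painbci("event ids must be unique", "painbci_validation_error")
  invisible(tbl)
}
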