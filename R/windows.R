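#' Running-observation-window specification
#'
#' ROWs are fixed-length, possibly overlapping segments cut from inside each
#' condition epoch; each window is one classification sample. Defaults per
#' modality: EEG 0.5 s with 80% overlap, SC 2 s with 80% overlap, patient
#' EEG 1 s with no overlap. `ptp_reject_threshold` is the peak-to-peak
#' artifact bound (150 uV EEG, 10 uS SC).
#'
#' @param length_s window length in seconds.
#' @param overlap_frac fractional overlap in `[0, 1)`.
#' @param ptp_reject_threshold peak-to-peak rejection threshold.
#' @export
window_spec <- function(length_s, overlap_frac = 0,
                        ptp_reject_threshold = Inf) {
  if (length_s <= 0 || overlap_frac < 0 || overlap_frac >= 1)
    abort_painbci("need length_s > 0 and overlap_frac in [0, 1)",
                  "painbci_validation_error")
  structure(list(length_s = length_s, overlap_frac = overlap_frac,
                 ptp_reject_threshold = ptp_reject_threshold),
            class = "bci_window_spec")
}

#' @rdname window_spec
#' @export
eeg_window_spec <- function() window_spec(0.5, 0.8, 150)

#' @rdname window_spec
#' @export
sc_window_spec <- function() window_spec(2, 0.8, 10)

#' @rdname window_spec
#' @export
patient_window_spec <- function() window_spec(1, 0, 150)

new_window_set <- function(data, meta, fs, channel_names, modality) {
  structure(list(data = data, meta = meta, fs = fs,
                 channel_names = channel_names, modality = modality),
            class = "bci_windows")
}

#' @export
print.bci_windows <- function(x, ...) {
  cat(sprintf("<bci_windows> %s: %d window(s) of %d sample(s), %d channel(s)\n",
              x$modality, nrow(x$meta), dim(x$data)[2], dim(x$data)[1]))
  if (nrow(x$meta)) print(table(x$meta$label))
  invisible(x)
}

#' Number of windows in a window set
#' @param ws a `bci_windows` object.
#' @export
n_windows <- function(ws) nrow(ws$meta)

#' Extract labeled running observation windows from epochs
#'
#' Within each event's epoch (`[onset, onset + duration)`), windows of
#' `spec$length_s` start at the epoch onset and advance by
#' `length_s * (1 - overlap_frac)` while they still fit inside the epoch.
#' Each window inherits its event's label and carries the event id as group
#' key, so overlapping windows can later be kept in the same
#' cross-validation fold. Epochs shorter than one window contribute zero
#' windows (with a message), never an error.
#'
#' @param rec a (typically band-passed) `bci_recording`.
#' @param events a `bci_events` table whose epochs fit inside the recording.
#' @param spec a [window_spec()].
#' @return A `bci_windows` object: `data` is a channels x samples x n array,
#'   `meta` a data frame (`window_id`, `event_id`, `start_s`, `label`).
#' @export
extract_windows <- function(rec, events, spec) {
  validate_recording(rec)
  validate_events(events)
  fs <- rec$fs
  len <- round(spec$length_s * fs)
  if (abs(spec$length_s * fs - len) > 1e-6)
    abort_painbci("window length is not an integer number of samples",
                  "painbci_validation_error")
  step <- round(len * (1 - spec$overlap_frac))
  if (step < 1) step <- 1L
  starts <- integer(0); ev_ids <- integer(0); labels <- character(0)
  for (r in seq_len(nrow(events))) {
    on_i <- round(events$onset[r] * fs)
    dur_i <- round(events$duration[r] * fs)
    if (on_i + dur_i > ncol(rec$data))
      abort_painbci(sprintf("epoch %d extends past end of recording",
                            events$event_id[r]), "painbci_validation_error")
    if (dur_i < len) {
      message(sprintf("epoch %d shorter than window; skipped",
                      events$event_id[r]))
      next
    }
    m <- floor((dur_i - len) / step) + 1L
    s <- on_i + step * (0:(m - 1L))
    starts <- c(starts, s)
    ev_ids <- c(ev_ids, rep(events$event_id[r], m))
    labels <- c(labels, rep(events$trial_type[r], m))
  }
  nwin <- length(starts)
  data <- array(0, dim = c(nrow(rec$data), len, nwin))
  for (i in seq_len(nwin))
    data[, , i] <- rec$data[, (starts[i] + 1L):(starts[i] + len),
                            drop = FALSE]
  meta <- data.frame(window_id = seq_len(nwin), event_id = ev_ids,
                     start_s = starts / fs, label = labels,
                     stringsAsFactors = FALSE)
  new_window_set(data, meta, fs, rec$channel_names, rec$modality)
}

#' Peak-to-peak artifact rejection
#'
#' A window is rejected iff the peak-to-peak amplitude (max minus min within
#' the window) of any channel exceeds `threshold` — the per-channel rule is
#' deliberately conservative. The two returned sets partition the input and
#' preserve its order.
#'
#' @param ws a `bci_windows` set.
#' @param threshold peak-to-peak bound (uV for EEG, uS for SC); defaults to
#'   the spec value carried by the window set's modality.
#' @return `list(kept =, rejected =)`, both `bci_windows`.
#' @export
reject_artifacts <- function(ws, threshold = NULL) {
  threshold <- threshold %||% if (ws$modality == "EEG") 150 else 10
  if (threshold <= 0)
    abort_painbci("threshold must be > 0", "painbci_validation_error")
  n <- n_windows(ws)
  if (n == 0) return(list(kept = ws, rejected = ws))
  ptp <- vapply(seq_len(n), function(i) {
    w <- ws$data[, , i, drop = FALSE]
    max(apply(matrix(w, dim(ws$data)[1]), 1,
              function(ch) max(ch) - min(ch)))
  }, 0)
  keep <- ptp <= threshold
  subset_ws <- function(sel) {
    meta <- ws$meta[sel, , drop = FALSE]
    rownames(meta) <- NULL
    new_window_set(ws$data[, , sel, drop = FALSE], meta, ws$fs,
                   ws$channel_names, ws$modality)
  }
  list(kept = subset_ws(keep), rejected = subset_ws(!keep))
}
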