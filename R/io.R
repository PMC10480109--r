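#' Write a recording to disk
#'
#' CSV stores one row per channel as full-precision decimal text with a JSON
#' sidecar (`<path>.json`) holding sampling rate, channel names, modality and
#' start time, so the round trip is bit-exact. EDF stores 16-bit scaled
#' samples in the standard European Data Format (record duration chosen so
#' samples-per-record is integral); the round trip is exact up to the 16-bit
#' quantization step.
#'
#' @param rec a `bci_recording`.
#' @param path output file path.
#' @param format `"csv"` or `"edf"`; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = NULL) {
  validate_recording(rec)
  format <- format %||% guess_format(path)
  switch(format,
         csv = write_recording_csv(rec, path),
         edf = write_recording_edf(rec, path),
         abort_painbci(sprintf("unsupported format '%s'", format),
                       "painbci_format_error"))
  invisible(path)
}

#' Read a recording written by [write_recording()]
#' @param path file path.
#' @param format `"csv"` or `"edf"`; default inferred from the extension.
#' @return A `bci_recording`.
#' @export
read_recording <- function(path, format = NULL) {
  if (!file.exists(path))
    abort_painbci(sprintf("file not found: %s", path), "painbci_format_error")
  format <- format %||% guess_format(path)
  switch(format,
         csv = read_recording_csv(path),
         edf = read_recording_edf(path),
         abort_painbci(sprintf("unsupported format '%s'", format),
                       "painbci_format_error"))
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "edf")) ext
  else abort_painbci(sprintf("cannot infer format from extension '%s'", ext),
                     "painbci_format_error")
}

write_recording_csv <- function(rec, path) {
  lines <- apply(rec$data, 1,
                 function(row) paste(sprintf("%.17g", row), collapse = ","))
  writeLines(lines, path)
  meta <- list(fs = rec$fs, channel_names = rec$channel_names,
               modality = rec$modality, t0 = rec$t0)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_recording_csv <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    abort_painbci(sprintf("missing sidecar metadata %s", sidecar),
                  "painbci_format_error")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dt <- data.table::fread(path, header = FALSE, colClasses = "character",
                          sep = ",")
  m <- as.matrix(dt)
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    abort_painbci(sprintf("non-numeric value '%s' at row %d, column %d of %s",
                          m[idx[1], idx[2]], idx[1], idx[2], path),
                  "painbci_format_error")
  }
  recording(num, fs = meta$fs, channel_names = meta$channel_names,
            modality = meta$modality, t0 = meta$t0 %||% 0)
}

# --- minimal EDF (European Data Format) ------------------------------------
# Fixed 256-byte header + 256 bytes per signal, then 16-bit little-endian
# samples interleaved by data record. The record duration is picked as the
# smallest value in {1, 2, 5, 10} s giving an integral samples-per-record.
# Modality is stashed in the transducer field.

pad_ascii <- function(x, width) formatC(as.character(x), width = -width)

# Format a physical min/max so it fits the 8-char EDF header field.
edf_num8 <- function(v) {
  vapply(v, function(x) {
    for (d in 7:1) {
      s <- sprintf(paste0("%.", d, "g"), x)
      if (nchar(s) <= 8) return(s)
    }
    substr(s, 1, 8)
  }, "")
}

edf_record_dur <- function(fs) {
  for (d in c(1, 2, 5, 10))
    if (abs(fs * d - round(fs * d)) < 1e-9) return(d)
  abort_painbci("sampling rate not representable in EDF records",
                "painbci_format_error")
}

write_recording_edf <- function(rec, path) {
  ns <- nrow(rec$data)
  dur <- edf_record_dur(rec$fs)
  spr <- as.integer(round(rec$fs * dur))
  nrec <- floor(ncol(rec$data) / spr)
  if (nrec < 1)
    abort_painbci("recording shorter than one EDF data record",
                  "painbci_format_error")
  used <- rec$data[, seq_len(nrec * spr), drop = FALSE]
  pmin_ <- apply(used, 1, min); pmax_ <- apply(used, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  # write truncated text and scale by the *written* values so the reader
  # reconstructs with exactly the stored calibration; out-of-range codes
  # from the text rounding are clamped (sub-quantization-step error)
  pmin_txt <- edf_num8(pmin_); pmax_txt <- edf_num8(pmax_)
  pmin_ <- as.numeric(pmin_txt); pmax_ <- as.numeric(pmax_txt)
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad_ascii("0", 8), pad_ascii("X X X X", 80),
                pad_ascii("Startdate X X X X", 80),
                "01.01.00", "00.00.00",
                pad_ascii(256 * (ns + 1), 8), pad_ascii("", 44),
                pad_ascii(nrec, 8), pad_ascii(format(dur), 8),
                pad_ascii(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width)
    writeChar(paste(vapply(vals, pad_ascii, "", width = width),
                    collapse = ""), con, eos = NULL)
  fld(rec$channel_names, 16)
  fld(rep(rec$modality, ns), 80)                      # transducer <- modality
  fld(rep(if (rec$modality == "EEG") "uV" else "uS", ns), 8)
  fld(pmin_txt, 8)
  fld(pmax_txt, 8)
  fld(rep(dmin, ns), 8)
  fld(rep(dmax, ns), 8)
  fld(rep("", ns), 80)
  fld(rep(spr, ns), 8)
  fld(rep("", ns), 32)

  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    for (s in seq_len(ns)) {
      dig <- pmin(pmax(round((used[s, cols] - pmin_[s]) / scale[s]) + dmin,
                       dmin), dmax)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdf <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- trimws(rdf(16))
  transducer <- trimws(rdf(80))
  rdf(8)                                  # physical dimension
  pmin_ <- as.numeric(rdf(8)); pmax_ <- as.numeric(rdf(8))
  dmin <- as.numeric(rdf(8)); dmax <- as.numeric(rdf(8))
  rdf(80)
  spr <- as.integer(rdf(8))
  rdf(32)
  data <- matrix(0, ns, nrec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2, endian = "little")
      data[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <-
        (dig - dmin[s]) * scale[s] + pmin_[s]
    }
  }
  modality <- if (any(transducer == "SC")) "SC" else "EEG"
  recording(data, fs = spr[1] / dur, channel_names = labels,
            modality = modality)
}

#' Write an event table as BIDS-style TSV
#' @param tbl a `bci_events` data frame.
#' @param path output path.
#' @export
write_events <- function(tbl, path) {
  validate_events(tbl)
  utils::write.table(as.data.frame(tbl)[, c("onset", "duration",
                                            "trial_type", "event_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event table from TSV
#' @param path file path with header `onset duration trial_type event_id`.
#' @export
read_events <- function(path) {
  if (!file.exists(path))
    abort_painbci(sprintf("file not found: %s", path), "painbci_format_error")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type", "event_id")
  if (!all(need %in% names(df)))
    abort_painbci(sprintf("events TSV must have header %s",
                          paste(need, collapse = "/")),
                  "painbci_format_error")
  if (nrow(df) == 0)
    return(event_table(numeric(0), numeric(0), character(0), integer(0)))
  event_table(df$onset, df$duration, df$trial_type, df$event_id)
}

#' Deterministic playback streaming of a recording
#'
#' Emulates live acquisition by slicing a recording into contiguous,
#' non-overlapping chunks of `chunk_s` seconds (half-open `[start,
#' start+chunk_s)` intervals). A final remainder shorter than one chunk is
#' dropped, matching fixed-size online classification.
#'
#' @param rec a `bci_recording`.
#' @param chunk_s chunk length in seconds; `chunk_s * fs` must be integral.
#' @return A list of chunks, each `list(start_s =, data =)`, with attribute
#'   `dropped_s` giving the discarded tail duration.
#' @export
playback_stream <- function(rec, chunk_s) {
  validate_recording(rec)
  if (chunk_s <= 0)
    abort_painbci("chunk_s must be > 0", "painbci_validation_error")
  n <- chunk_s * rec$fs
  if (abs(n - round(n)) > 1e-6)
    abort_painbci(sprintf("chunk of %g s is not an integer number of samples at %g Hz",
                          chunk_s, rec$fs), "painbci_validation_error")
  n <- as.integer(round(n))
  k <- floor(ncol(rec$data) / n)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    cols <- ((i - 1L) * n + 1L):(i * n)
    out[[i]] <- list(start_s = (i - 1) * chunk_s,
                     data = rec$data[, cols, drop = FALSE])
  }
  attr(out, "dropped_s") <- (ncol(rec$data) - k * n) / rec$fs
  out
}

#' Save a trained decoder to a JSON artifact
#'
#' The artifact is a single self-contained JSON file: z-scaler statistics,
#' support vectors and dual coefficients of every binary machine, Platt
#' sigmoid parameters, class set, modality, feature names, the window spec
#' the decoder expects, and a config/seed snapshot. Full double precision is
#' kept so reloaded decoders reproduce predictions exactly.
#'
#' @param decoder a `bci_decoder` from [train_decoder()].
#' @param path output path.
#' @export
save_decoder <- function(decoder, path) {
  stopifnot(inherits(decoder, "bci_decoder"))
  jsonlite::write_json(unclass_recursive(decoder), path,
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

unclass_recursive <- function(x) {
  if (is.list(x) && !is.data.frame(x))
    return(lapply(unclass(x), unclass_recursive))
  x
}

#' Load a decoder artifact saved by [save_decoder()]
#' @param path artifact path.
#' @export
load_decoder <- function(path) {
  if (!file.exists(path))
    abort_painbci(sprintf("file not found: %s", path), "painbci_format_error")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  obj$svm$machines <- lapply(obj$svm$machines, function(m) {
    m$sv <- if (is.list(m$sv)) do.call(rbind, m$sv)
            else if (is.matrix(m$sv)) m$sv
            else matrix(m$sv, nrow = 1)
    m$platt <- unlist(m$platt)
    m
  })
  obj$scaler$mean <- unlist(obj$scaler$mean)
  obj$scaler$sd <- unlist(obj$scaler$sd)
  class(obj$svm) <- "rbf_svm"
  class(obj) <- "bci_decoder"
  obj
}
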