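#' Feature configuration
#'
#' Frequency bands, PSD settings and entropy parameters used by the EEG
#' feature set. Band edges follow the standard conventions used for this
#' montage: theta 4-7, alpha 8-13, beta 13-30, gamma 30-40 Hz; `total` is
#' the filtered 3-40 Hz support. The PSD is a single Hamming-tapered
#' periodogram zero-padded to `nfft` = 1024 samples. Sample entropy uses
#' template length `sampen_m` = 2 and tolerance `sampen_r_frac` = 0.2 times
#' the window SD; Higuchi fractal dimension uses `higuchi_kmax` = 10.
#'
#' @param bands named list of `c(lo, hi)` Hz pairs.
#' @param nfft zero-padded FFT length.
#' @param sampen_m,sampen_r_frac sample-entropy template length and
#'   tolerance fraction of the window SD.
#' @param higuchi_kmax maximum Higuchi scale.
#' @param psd_taper `"hamming"` or `"rect"`.
#' @export
feature_config <- function(bands = list(theta = c(4, 7), alpha = c(8, 13),
                                        beta = c(13, 30), gamma = c(30, 40),
                                        total = c(3, 40)),
                           nfft = 1024, sampen_m = 2, sampen_r_frac = 0.2,
                           higuchi_kmax = 10,
                           psd_taper = c("hamming", "rect")) {
  psd_taper <- match.arg(psd_taper)
  if (sampen_m < 1 || higuchi_kmax < 2)
    abort_painbci("need sampen_m >= 1 and higuchi_kmax >= 2",
                  "painbci_validation_error")
  structure(list(bands = bands, nfft = nfft, sampen_m = sampen_m,
                 sampen_r_frac = sampen_r_frac,
                 higuchi_kmax = higuchi_kmax, psd_taper = psd_taper),
            class = "bci_feature_config")
}

psd_taper_vec <- function(n, taper) {
  if (taper == "hamming") 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  else rep(1, n)
}

# All-columns periodogram: windows in columns, returns one-sided PSD matrix.
psd_matrix <- function(w, fs, cfg) {
  n <- nrow(w)
  tap <- psd_taper_vec(n, cfg$psd_taper)
  nfft <- cfg$nfft
  padded <- rbind(w * tap, matrix(0, nfft - n, ncol(w)))
  sp <- mvfft(padded)
  half <- nfft / 2 + 1
  p <- (Mod(sp[seq_len(half), , drop = FALSE])^2) / (fs * sum(tap^2))
  p[2:(half - 1), ] <- 2 * p[2:(half - 1), ]
  p
}

#' Power spectral density of one window channel
#'
#' Single-segment tapered periodogram zero-padded to `cfg$nfft`, one-sided,
#' scaled so that `sum(power) * df` approximates the (taper-normalized)
#' signal variance (Parseval-consistent).
#'
#' @param x numeric vector (one channel of one window), length >= 2.
#' @param fs sampling rate in Hz.
#' @param cfg a [feature_config()].
#' @return A `bci_spectrum`: `freqs` (Hz, from 0), `power`, `nfft`.
#' @export
compute_psd <- function(x, fs, cfg = feature_config()) {
  if (length(x) < 2)
    abort_painbci("need at least 2 samples", "painbci_validation_error")
  p <- psd_matrix(matrix(x, ncol = 1), fs, cfg)[, 1]
  structure(list(freqs = seq(0, fs / 2, length.out = cfg$nfft / 2 + 1),
                 power = p, nfft = cfg$nfft),
            class = "bci_spectrum")
}

band_idx <- function(freqs, lo, hi) which(freqs >= lo & freqs < hi)

#' Band power by rectangle-rule integration of the PSD
#' @param spec a `bci_spectrum`.
#' @param lo,hi band edges in Hz; bins with `lo <= f < hi` are summed.
#' @export
band_power <- function(spec, lo, hi) {
  idx <- band_idx(spec$freqs, lo, hi)
  if (!length(idx))
    abort_painbci(sprintf("no PSD bins in [%g, %g) Hz", lo, hi),
                  "painbci_validation_error")
  df <- spec$freqs[2] - spec$freqs[1]
  sum(spec$power[idx]) * df
}

#' Frequency of the maximum PSD bin in a band
#'
#' Ties (including an all-zero spectrum) break toward the lowest frequency.
#' @inheritParams band_power
#' @export
peak_frequency <- function(spec, lo = 3, hi = 40) {
  idx <- band_idx(spec$freqs, lo, hi)
  if (!length(idx))
    abort_painbci(sprintf("no PSD bins in [%g, %g) Hz", lo, hi),
                  "painbci_validation_error")
  p <- spec$power[idx]
  if (all(p == p[1]))
    message("flat spectrum in band; peak frequency is the lowest bin")
  spec$freqs[idx[which.max(p)]]
}

#' Normalized spectral entropy over a band
#'
#' Shannon entropy of the PSD treated as a probability distribution over the
#' band's bins, divided by `log(#bins)` so the value lies in `[0, 1]`.
#' A degenerate all-zero band returns 0.
#' @inheritParams band_power
#' @export
spectral_entropy <- function(spec, lo = 3, hi = 40) {
  idx <- band_idx(spec$freqs, lo, hi)
  if (!length(idx))
    abort_painbci(sprintf("no PSD bins in [%g, %g) Hz", lo, hi),
                  "painbci_validation_error")
  p <- spec$power[idx]
  tot <- sum(p)
  if (tot <= 0) return(0)
  p <- p / tot
  nz <- p > 0
  -sum(p[nz] * log(p[nz])) / log(length(p))
}

#' Sample entropy
#'
#' `-ln(A/B)` where `B` counts pairs of length-`m` templates within
#' Chebyshev distance `r` and `A` the same for length `m + 1`; self-matches
#' are excluded. `A == 0` maps to the capped sentinel `log(B)`; a constant
#' signal gives 0.
#'
#' @param x numeric vector, length > `m + 1`.
#' @param m template length.
#' @param r tolerance; defaults to `0.2 * sd(x)`.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  if (length(x) <= m + 1)
    abort_painbci("series too short for sample entropy",
                  "painbci_validation_error")
  .sampen_cpp(as.numeric(x), as.integer(m), r)
}

#' Higuchi fractal dimension
#'
#' Curve-length complexity estimate between 1 (smooth) and 2 (noise-like):
#' average normalized curve lengths over `k = 1..kmax` decimations, fit
#' `ln L(k)` against `ln k` by least squares and negate the slope.
#'
#' @param x numeric vector.
#' @param kmax maximum decimation scale.
#' @export
higuchi_fd <- function(x, kmax = 10) {
  .higuchi_cpp(as.numeric(x), as.integer(kmax))
}

#' Root mean square
#' @param x numeric vector.
#' @export
signal_rms <- function(x) sqrt(mean(x^2))

eeg_feature_basenames <- function(cfg)
  c(paste0(names(cfg$bands), "_power"),
    "peak_frequency", "sample_entropy", "spectral_entropy",
    "higuchi_fd", "rms")

#' EEG feature vector for one window
#'
#' The ten per-channel features — theta/alpha/beta/gamma/total band power,
#' peak frequency, sample entropy, spectral entropy, Higuchi fractal
#' dimension and RMS — computed per channel and concatenated, giving
#' `10 * n_channels` named columns `<feature>__<channel>`.
#'
#' @param window channels-by-samples matrix (one window).
#' @param fs sampling rate in Hz.
#' @param cfg a [feature_config()].
#' @param channel_names labels for the rows of `window`.
#' @return Named numeric vector.
#' @export
eeg_feature_vector <- function(window, fs, cfg = feature_config(),
                               channel_names = rownames(window)) {
  if (is.vector(window)) window <- matrix(window, nrow = 1)
  if (anyNA(window))
    abort_painbci("NaN/NA in window", "painbci_validation_error")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(window)))
  total <- cfg$bands$total
  out <- numeric(0)
  for (ch in seq_len(nrow(window))) {
    x <- window[ch, ]
    spec <- compute_psd(x, fs, cfg)
    vals <- c(vapply(cfg$bands, function(b) band_power(spec, b[1], b[2]), 0),
              peak_frequency = suppressMessages(
                peak_frequency(spec, total[1], total[2])),
              sample_entropy = sample_entropy(x, cfg$sampen_m,
                                              cfg$sampen_r_frac * sd(x)),
              spectral_entropy = spectral_entropy(spec, total[1], total[2]),
              higuchi_fd = higuchi_fd(x, cfg$higuchi_kmax),
              rms = signal_rms(x))
    names(vals) <- paste0(eeg_feature_basenames(cfg), "__",
                          channel_names[ch])
    out <- c(out, vals)
  }
  out
}

sc_feature_names <- function()
  c("mean", "max", "median", "sd", "var", "iqr", "rms", "range",
    "slope", "mad", "auc")

#' Skin-conductance feature vector for one window
#'
#' Eleven amplitude-based features on the band-passed SC window: mean, max,
#' median, SD (n-1), variance, IQR (linear-interpolation quantiles), RMS,
#' range, least-squares slope versus time in seconds, median absolute
#' deviation (unscaled) and trapezoid area under the curve versus time in
#' seconds. The AUC is computed on the signed signal: after the 0.05-2 Hz
#' band-pass the tonic level is removed, so signed area is the phasic
#' readout.
#'
#' @param window 1-by-samples matrix or numeric vector.
#' @param fs sampling rate in Hz.
#' @return Named numeric vector of length 11.
#' @export
sc_feature_vector <- function(window, fs) {
  x <- as.numeric(window)
  if (anyNA(x))
    abort_painbci("NaN/NA in window", "painbci_validation_error")
  t <- (seq_along(x) - 1) / fs
  tc <- t - mean(t)
  slope <- if (sum(tc^2) > 0) sum(tc * (x - mean(x))) / sum(tc^2) else 0
  q <- unname(quantile(x, c(0.25, 0.75), type = 7))
  s <- sd(x)    # var reported as sd^2 so the pair is exactly consistent
  vals <- c(mean(x), max(x), median(x), s, s^2, q[2] - q[1],
            signal_rms(x), max(x) - min(x), slope,
            median(abs(x - median(x))),
            sum((x[-1] + x[-length(x)]) / 2) / fs)
  names(vals) <- sc_feature_names()
  vals
}

#' Compute the feature table for a window set
#'
#' Dispatches on the window set's modality: the 60-column EEG set or the
#' 11-column SC set. Internally vectorized across windows (one FFT batch for
#' all spectra, compiled loops for the entropies), but numerically identical
#' to calling [eeg_feature_vector()] / [sc_feature_vector()] per window.
#'
#' @param ws a `bci_windows` set (after artifact rejection).
#' @param cfg a [feature_config()] (EEG only).
#' @return A data frame of class `bci_features` with bookkeeping columns
#'   `window_id`, `event_id`, `label` followed by the feature columns (the
#'   feature names are in attribute `feature_names`).
#' @export
compute_features <- function(ws, cfg = feature_config()) {
  n <- n_windows(ws)
  if (ws$modality == "SC") {
    feats <- t(vapply(seq_len(max(n, 0)), function(i)
      sc_feature_vector(ws$data[1, , i], ws$fs), numeric(11)))
    if (n == 0) feats <- matrix(0, 0, 11)
    colnames(feats) <- sc_feature_names()
  } else {
    feats <- eeg_features_vectorized(ws, cfg)
  }
  out <- cbind(ws$meta[, c("window_id", "event_id", "label"), drop = FALSE],
               as.data.frame(feats))
  rownames(out) <- NULL
  structure(out, feature_names = colnames(feats),
            class = c("bci_features", "data.frame"))
}

eeg_features_vectorized <- function(ws, cfg) {
  n <- n_windows(ws)
  nch <- dim(ws$data)[1]
  base <- eeg_feature_basenames(cfg)
  cols <- as.vector(t(outer(ws$channel_names, base,
                            function(ch, f) paste0(f, "__", ch))))
  if (n == 0) {
    m <- matrix(0, 0, nch * length(base)); colnames(m) <- cols
    return(m)
  }
  total <- cfg$bands$total
  df_hz <- ws$fs / cfg$nfft
  freqs <- seq(0, ws$fs / 2, length.out = cfg$nfft / 2 + 1)
  out <- matrix(NA_real_, n, 0)
  for (ch in seq_len(nch)) {
    w <- matrix(ws$data[ch, , ], nrow = dim(ws$data)[2])
    p <- psd_matrix(w, ws$fs, cfg)
    bp <- vapply(cfg$bands, function(b)
      colSums(p[band_idx(freqs, b[1], b[2]), , drop = FALSE]) * df_hz,
      numeric(n))
    if (!is.matrix(bp)) bp <- matrix(bp, nrow = 1)   # n == 1 edge case
    tidx <- band_idx(freqs, total[1], total[2])
    pt <- p[tidx, , drop = FALSE]
    pk <- freqs[tidx[max.col(t(pt), ties.method = "first")]]
    tot <- colSums(pt)
    se <- vapply(seq_len(n), function(i) {
      if (tot[i] <= 0) return(0)
      q <- pt[, i] / tot[i]; nz <- q > 0
      -sum(q[nz] * log(q[nz])) / log(length(q))
    }, 0)
    sds <- apply(w, 2, sd)
    samp <- .sampen_cols_cpp(w, as.integer(cfg$sampen_m),
                             cfg$sampen_r_frac * sds)
    hfd <- .higuchi_cols_cpp(w, as.integer(cfg$higuchi_kmax))
    rms <- sqrt(colMeans(w^2))
    block <- cbind(bp, pk, samp, se, hfd, rms)
    out <- cbind(out, block)
  }
  colnames(out) <- cols
  out
}

#' Write / read a feature table as CSV
#' @param ft a `bci_features` data frame.
#' @param path file path.
#' @export
write_features <- function(ft, path) {
  utils::write.csv(as.data.frame(ft), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(df,
            feature_names = setdiff(names(df),
                                    c("window_id", "event_id", "label")),
            class = c("bci_features", "data.frame"))
}

#' Feature-column names of a feature table
#' @param ft a `bci_features` data frame.
#' @export
feature_names <- function(ft) attr(ft, "feature_names")

#' Feature matrix (rows = windows) of a feature table
#' @param ft a `bci_features` data frame.
#' @export
feature_matrix <- function(ft)
  as.matrix(as.data.frame(ft)[, feature_names(ft), drop = FALSE])
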