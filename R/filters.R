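#' Band-pass filter specification
#'
#' Two families are supported, matching the two modalities' pipelines:
#' `fir_hamming_sinc` — a linear-phase windowed-sinc FIR (EEG default:
#' 3–40 Hz, order 2000) — and `cheby1` — a Chebyshev type I IIR (SC default:
#' 0.05–2 Hz, order 3, 0.5 dB passband ripple).
#'
#' @param family `"fir_hamming_sinc"` or `"cheby1"`.
#' @param low_hz,high_hz band edges in Hz, `0 <= low_hz < high_hz`.
#' @param order filter order: taps for FIR, poles (per lowpass prototype)
#'   for Chebyshev.
#' @param ripple_db passband ripple in dB (cheby1 only).
#' @export
filter_spec <- function(family = c("fir_hamming_sinc", "cheby1"),
                        low_hz, high_hz, order, ripple_db = 0.5) {
  family <- match.arg(family)
  if (!(low_hz >= 0 && low_hz < high_hz))
    abort_painbci("need 0 <= low_hz < high_hz", "painbci_validation_error")
  if (order <= 0)
    abort_painbci("filter order must be > 0", "painbci_validation_error")
  structure(list(family = family, low_hz = low_hz, high_hz = high_hz,
                 order = order, ripple_db = ripple_db),
            class = "bci_filter_spec")
}

#' Default EEG band-pass (3–40 Hz windowed-sinc FIR, order 2000)
#' @export
eeg_filter_spec <- function()
  filter_spec("fir_hamming_sinc", 3, 40, 2000)

#' Default SC band-pass (0.05–2 Hz Chebyshev type I, order 3)
#' @export
sc_filter_spec <- function()
  filter_spec("cheby1", 0.05, 2, 3)

# Windowed-sinc band-pass taps: difference of two ideal lowpass sincs,
# Hamming-windowed, gain normalized to 1 at the passband center.
design_fir_bandpass <- function(low_hz, high_hz, order, fs) {
  m <- order                      # order taps + 1 coefficients
  n <- 0:m
  fl <- low_hz / fs; fh <- high_hz / fs
  x <- n - m / 2
  sinc <- function(f, x) ifelse(x == 0, 2 * f, sin(2 * pi * f * x) / (pi * x))
  h <- (sinc(fh, x) - sinc(fl, x)) *
    (0.54 - 0.46 * cos(2 * pi * n / m))   # Hamming
  fc <- (low_hz + high_hz) / 2
  gain <- sum(h * cos(2 * pi * fc / fs * x))   # response magnitude at fc
  h / gain
}

# Chebyshev type I analog lowpass prototype poles and gain (cutoff 1 rad/s).
cheby1_prototype <- function(order, ripple_db) {
  eps <- sqrt(10^(ripple_db / 10) - 1)
  mu <- asinh(1 / eps) / order
  k <- seq_len(order)
  theta <- pi * (2 * k - 1) / (2 * order)
  p <- complex(real = -sinh(mu) * sin(theta),
               imaginary = cosh(mu) * cos(theta))
  gain <- Re(prod(-p))
  if (order %% 2 == 0) gain <- gain / sqrt(1 + eps^2)
  list(p = p, k = gain)
}

# Analog lowpass -> bandpass transform, then bilinear transform with
# prewarped edges; returns transfer-function coefficients b, a.
design_cheby1_bandpass <- function(low_hz, high_hz, order, fs,
                                   ripple_db = 0.5) {
  proto <- cheby1_prototype(order, ripple_db)
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low_hz / fs)      # prewarped rad/s
  w2 <- fs2 * tan(pi * high_hz / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # lp2bp: each prototype pole p -> two roots of s^2 - p*bw*s + w0^2 = 0
  p_bp <- unlist(lapply(proto$p, function(p) {
    disc <- sqrt((p * bw / 2)^2 - w0^2)
    c(p * bw / 2 + disc, p * bw / 2 - disc)
  }))
  z_bp <- rep(0 + 0i, order)
  k_bp <- proto$k * bw^order
  # bilinear transform z = (1 + s/fs2)/(1 - s/fs2)
  pd <- (1 + p_bp / fs2) / (1 - p_bp / fs2)
  zd <- (1 + z_bp / fs2) / (1 - z_bp / fs2)
  kd <- Re(k_bp * prod(fs2 - z_bp) / prod(fs2 - p_bp))
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  b <- Re(poly_from_roots(zd)) * kd
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (x in r) p <- c(p, 0) - c(0, p * x)
  p
}

design_filter <- function(spec, fs) {
  if (spec$high_hz >= fs / 2)
    abort_painbci(sprintf("high edge %g Hz must be below Nyquist (%g Hz)",
                          spec$high_hz, fs / 2), "painbci_validation_error")
  if (spec$family == "fir_hamming_sinc")
    list(type = "fir",
         h = design_fir_bandpass(spec$low_hz, spec$high_hz, spec$order, fs))
  else {
    ba <- design_cheby1_bandpass(spec$low_hz, spec$high_hz, spec$order, fs,
                                 spec$ripple_db)
    list(type = "iir", b = ba$b, a = ba$a)
  }
}

# FFT-based full convolution (open), exact to numeric precision.
conv_fft <- function(x, h) {
  n <- length(x) + length(h) - 1
  nf <- stats::nextn(n, 2)
  y <- Re(fft(fft(c(x, rep(0, nf - length(x)))) *
              fft(c(h, rep(0, nf - length(h)))), inverse = TRUE)) / nf
  y[seq_len(n)]
}

#' Band-pass filter a recording
#'
#' Per-channel filtering. The FIR path runs one pass and compensates the
#' linear-phase group delay (`order/2` samples) so filtered samples stay
#' time-aligned with the event table; output length equals input length and
#' the transient-affected edge duration is recorded in attribute `edge_s`.
#' The Chebyshev path filters causally from zero initial state.
#'
#' @param rec a `bci_recording`.
#' @param spec a [filter_spec()]; defaults to the modality's standard spec.
#' @return The filtered `bci_recording`.
#' @export
bandpass <- function(rec, spec = NULL) {
  validate_recording(rec)
  spec <- spec %||%
    if (rec$modality == "EEG") eeg_filter_spec() else sc_filter_spec()
  flt <- design_filter(spec, rec$fs)
  n <- ncol(rec$data)
  out <- rec
  if (flt$type == "fir") {
    half <- length(flt$h) %/% 2
    for (i in seq_len(nrow(rec$data))) {
      y <- conv_fft(rec$data[i, ], flt$h)
      out$data[i, ] <- y[(half + 1):(half + n)]
    }
    attr(out, "edge_s") <- half / rec$fs
  } else {
    for (i in seq_len(nrow(rec$data))) {
      out$data[i, ] <- .iir_filter_cpp(flt$b, flt$a, rec$data[i, ],
                                       numeric(0))$y
    }
    attr(out, "edge_s") <- 3 / spec$low_hz   # rough settle time
  }
  out
}

#' Initialize a streaming (causal, stateful) filter
#'
#' Online chunks are filtered causally with per-channel state carried across
#' chunk boundaries, so a chunked stream produces exactly the same output as
#' filtering the concatenated signal in one pass. The FIR path therefore
#' delays its output by the group delay (`order/2` samples); callers that
#' need event alignment must account for `state$delay_s`.
#'
#' @param spec a [filter_spec()].
#' @param fs sampling rate of the incoming chunks.
#' @param n_channels number of channels per chunk.
#' @return A filter-state object for [stream_filter()].
#' @export
stream_filter_init <- function(spec, fs, n_channels) {
  flt <- design_filter(spec, fs)
  if (flt$type == "fir")
    list(type = "fir", h = flt$h,
         buf = matrix(0, n_channels, length(flt$h) - 1),
         delay_s = (length(flt$h) %/% 2) / fs)
  else
    list(type = "iir", b = flt$b, a = flt$a,
         z = matrix(0, n_channels, max(length(flt$a), length(flt$b)) - 1),
         delay_s = 0)
}

#' Filter one chunk, updating filter state
#' @param state state from [stream_filter_init()] or a previous call.
#' @param chunk channels-by-samples matrix.
#' @return `list(out = filtered chunk, state = updated state)`.
#' @export
stream_filter <- function(state, chunk) {
  if (is.vector(chunk)) chunk <- matrix(chunk, nrow = 1)
  out <- chunk
  if (state$type == "fir") {
    m <- ncol(state$buf)
    for (i in seq_len(nrow(chunk))) {
      x <- c(state$buf[i, ], chunk[i, ])
      y <- conv_fft(x, state$h)
      out[i, ] <- y[(m + 1):(m + ncol(chunk))]
    }
    xfull <- cbind(state$buf, chunk)
    state$buf <- xfull[, (ncol(xfull) - m + 1):ncol(xfull), drop = FALSE]
  } else {
    for (i in seq_len(nrow(chunk))) {
      r <- .iir_filter_cpp(state$b, state$a, chunk[i, ], state$z[i, ])
      out[i, ] <- r$y
      state$z[i, ] <- r$zf
    }
  }
  list(out = out, state = state)
}
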