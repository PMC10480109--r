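#' Synthetic-session generator configuration
#'
#' The generator emulates the statistical structure the decoders assume.
#' EEG per channel: pink background noise plus alpha (10 Hz) and beta
#' (22 Hz) oscillators plus white noise; during painful (P) epochs the
#' oscillator amplitudes are scaled down by `alpha_reduction` /
#' `beta_reduction` (event-related desynchronization) while the white-noise
#' SD is scaled up by `broadband_gain`, raising entropy and fractal
#' dimension and lowering narrow-band and total power. Non-painful (NP) and
#' rest (R) epochs leave the spectra untouched. SC: tonic level plus slow
#' drift plus a stimulus-locked double-exponential phasic response per
#' event (amplitude `scr_amp_p` for P, `scr_amp_np` for NP, none for R)
#' plus measurement noise. Amplitudes are in uV (EEG) and uS (SC).
#'
#' Oscillator and noise amplitudes are calibrated once so that default
#' decoding accuracy lands in the study's reported offline ranges (EEG
#' about 0.7, SC about 0.8 for the 2-class problem) — a calibration choice,
#' not a reproduction claim.
#'
#' @param fs_eeg,fs_sc sampling rates in Hz.
#' @param channels EEG channel labels (centro-parietal montage).
#' @param pink_sd,white_sd background noise SDs, uV.
#' @param alpha_hz,alpha_amp,beta_hz,beta_amp oscillator parameters.
#' @param alpha_reduction,beta_reduction fractional amplitude reduction
#'   during P epochs, in `[0, 1)`.
#' @param broadband_gain white-noise SD multiplier during P epochs.
#' @param artifact_rate_per_min,artifact_amp injected spike artifacts.
#' @param scr_latency,scr_rise,scr_decay SCR kernel timing, seconds.
#' @param scr_amp_p,scr_amp_np phasic amplitudes, uS.
#' @param sc_tonic,sc_drift_amp,sc_noise_sd tonic level, slow drift
#'   amplitude and measurement noise, uS.
#' @export
synth_config <- function(fs_eeg = 500, fs_sc = 5,
                         channels = c("Cz", "C3", "C4", "CPz", "CP1", "CP2"),
                         pink_sd = 10, white_sd = 5,
                         alpha_hz = 10, alpha_amp = 2.5,
                         beta_hz = 22, beta_amp = 3,
                         alpha_reduction = 0.4, beta_reduction = 0.3,
                         broadband_gain = 1.3,
                         artifact_rate_per_min = 1, artifact_amp = 300,
                         scr_latency = 1.5, scr_rise = 0.75, scr_decay = 2,
                         scr_amp_p = 1, scr_amp_np = 0.1,
                         sc_tonic = 2, sc_drift_amp = 0.1,
                         sc_noise_sd = 0.1) {
  if (alpha_reduction < 0 || alpha_reduction >= 1 ||
      beta_reduction < 0 || beta_reduction >= 1)
    abort_painbci("reductions must lie in [0, 1)", "painbci_validation_error")
  structure(as.list(environment()), class = "bci_synth_config")
}

#' Experimental protocol specification
#'
#' Healthy protocol: `n_per_class` (12) stimuli per condition in a seeded
#' random order, stimulation time `st` (4 s), inter-stimulus interval `isi`
#' (8 s). Patient protocol: `total_min` (6) minutes of alternating
#' `block_s` (30 s) rest / focus-on-pain blocks, starting with rest.
#'
#' @param mode `"healthy"` or `"patient"`.
#' @param n_per_class,st,isi healthy-protocol parameters.
#' @param total_min,block_s patient-protocol parameters.
#' @export
protocol_spec <- function(mode = c("healthy", "patient"),
                          n_per_class = 12, st = 4, isi = 8,
                          total_min = 6, block_s = 30) {
  mode <- match.arg(mode)
  if (n_per_class <= 0 || st <= 0 || isi <= 0 || total_min <= 0 ||
      block_s <= 0)
    abort_painbci("protocol counts and durations must be > 0",
                  "painbci_validation_error")
  structure(list(mode = mode, n_per_class = n_per_class, st = st,
                 isi = isi, total_min = total_min, block_s = block_s),
            class = "bci_protocol_spec")
}

#' Generate an event schedule for a protocol
#'
#' Healthy: `3 * n_per_class` events with a seeded shuffled label order,
#' onset `k * (st + isi)` and duration `st` (the rest condition is marked by
#' an epoch exactly like P/NP, just without stimulation). Patient:
#' alternating 30-s R/P blocks covering `total_min` minutes.
#'
#' @param spec a [protocol_spec()].
#' @param seed shuffle seed.
#' @return A `bci_events` table.
#' @export
make_event_schedule <- function(spec = protocol_spec(), seed = 0L) {
  if (spec$mode == "healthy") {
    labels <- withr::with_seed(seed,
      sample(rep(CONDITION_LABELS, spec$n_per_class)))
    n <- length(labels)
    event_table(onset = (seq_len(n) - 1) * (spec$st + spec$isi),
                duration = rep(spec$st, n), label = labels)
  } else {
    n <- as.integer(spec$total_min * 60 / spec$block_s)
    event_table(onset = (seq_len(n) - 1) * spec$block_s,
                duration = rep(spec$block_s, n),
                label = rep(c("R", "P"), length.out = n))
  }
}

# 1/f (power) background noise via spectral shaping, unit variance.
pink_noise <- function(n) {
  nf <- stats::nextn(n, 2)
  half <- nf / 2
  mag <- c(0, 1 / sqrt(seq_len(half)))
  phase <- runif(half + 1, 0, 2 * pi)
  sp <- mag * exp(1i * phase)
  full <- c(sp, Conj(rev(sp[2:half])))
  x <- Re(fft(full, inverse = TRUE))[seq_len(n)]
  x / sd(x)
}

# Smoothed 0/1 indicator of the P epochs (raised-cosine ramps, ramp_s each
# side) so condition transitions do not inject spurious broadband edges.
condition_gate <- function(t, events, ramp_s = 0.2) {
  g <- numeric(length(t))
  pe <- events[events$trial_type == "P", , drop = FALSE]
  for (r in seq_len(nrow(pe))) {
    on <- pe$onset[r]; off <- on + pe$duration[r]
    rise <- t >= on & t < on + ramp_s
    g[rise] <- pmax(g[rise], (1 - cos(pi * (t[rise] - on) / ramp_s)) / 2)
    mid <- t >= on + ramp_s & t < off - ramp_s
    g[mid] <- 1
    fall <- t >= off - ramp_s & t < off
    g[fall] <- pmax(g[fall], (1 + cos(pi * (t[fall] - off + ramp_s) / ramp_s)) / 2)
  }
  g
}

#' Synthesize an EEG session for an event schedule
#'
#' @param schedule a `bci_events` table.
#' @param cfg a [synth_config()].
#' @param seed RNG seed.
#' @param tail_s extra recording time after the last epoch (default = ISI).
#' @return A `bci_recording` (channels x samples, uV).
#' @export
synth_eeg <- function(schedule, cfg = synth_config(), seed = 0L,
                      tail_s = 8) {
  fs <- cfg$fs_eeg
  dur <- max(schedule$onset + schedule$duration, 0) + tail_s
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  gate <- condition_gate(t, schedule)
  withr::with_seed(seed, {
    data <- matrix(0, length(cfg$channels), n)
    for (ch in seq_along(cfg$channels)) {
      phase_a <- runif(1, 0, 2 * pi)
      phase_b <- runif(1, 0, 2 * pi)
      alpha <- cfg$alpha_amp * (1 - cfg$alpha_reduction * gate) *
        sin(2 * pi * cfg$alpha_hz * t + phase_a)
      beta <- cfg$beta_amp * (1 - cfg$beta_reduction * gate) *
        sin(2 * pi * cfg$beta_hz * t + phase_b)
      white <- rnorm(n) * cfg$white_sd *
        (1 + (cfg$broadband_gain - 1) * gate)
      data[ch, ] <- cfg$pink_sd * pink_noise(n) + alpha + beta + white
    }
    n_art <- stats::rpois(1, cfg$artifact_rate_per_min * dur / 60)
    if (n_art > 0) {
      width <- round(0.05 * fs)
      kern <- cfg$artifact_amp * exp(-((seq_len(width) - width / 2)^2) /
                                       (2 * (width / 6)^2))
      for (a in seq_len(n_art)) {
        at <- sample.int(n - width, 1)
        ch <- sample.int(length(cfg$channels), 1)
        data[ch, at:(at + width - 1)] <- data[ch, at:(at + width - 1)] + kern
      }
    }
    recording(data, fs, cfg$channels, "EEG")
  })
}

# SCR kernel: difference of exponentials, zero before latency.
scr_kernel <- function(dt, rise, decay) {
  k <- exp(-dt / decay) - exp(-dt / rise)
  k[dt < 0] <- 0
  k
}

#' Closed-form peak of the double-exponential SCR kernel
#'
#' The kernel `exp(-t/decay) - exp(-t/rise)` peaks at
#' `t* = log(decay/rise) * rise * decay / (decay - rise)`.
#' @param rise,decay time constants, s.
#' @return `list(t_peak, peak)` for a unit-amplitude kernel.
#' @export
scr_kernel_peak <- function(rise = 0.75, decay = 2) {
  t_peak <- log(decay / rise) * rise * decay / (decay - rise)
  list(t_peak = t_peak, peak = exp(-t_peak / decay) - exp(-t_peak / rise))
}

#' Synthesize a skin-conductance session for an event schedule
#'
#' @inheritParams synth_eeg
#' @param drift set `FALSE` to disable the slow tonic drift.
#' @return A single-channel `bci_recording` (uS).
#' @export
synth_sc <- function(schedule, cfg = synth_config(), seed = 0L,
                     tail_s = 8, drift = TRUE) {
  fs <- cfg$fs_sc
  dur <- max(schedule$onset + schedule$duration, 0) + tail_s
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  withr::with_seed(seed, {
    x <- rep(cfg$sc_tonic, n)
    if (drift && dur > 0) {
      ph <- runif(1, 0, 2 * pi)
      x <- x + cfg$sc_drift_amp * sin(2 * pi * t / dur + ph)
    }
    for (r in seq_len(nrow(schedule))) {
      amp <- switch(schedule$trial_type[r], P = cfg$scr_amp_p,
                    NP = cfg$scr_amp_np, R = 0)
      if (amp > 0)
        x <- x + amp * scr_kernel(t - schedule$onset[r] - cfg$scr_latency,
                                  cfg$scr_rise, cfg$scr_decay)
    }
    x <- x + rnorm(n) * cfg$sc_noise_sd
    recording(x, fs, "SC", modality = "SC")
  })
}

#' Generate a multi-subject synthetic dataset
#'
#' Per-subject seeds are derived from the master seed; subject variability
#' is emulated by jittering the condition effect sizes (multiplicative,
#' uniform 0.8-1.2). Patient-mode datasets reuse the EEG generator with the
#' focus blocks as P epochs and carry no SC condition effect.
#'
#' @param n_subjects number of subjects.
#' @param spec a [protocol_spec()].
#' @param cfg a [synth_config()].
#' @param seed master seed; per-subject seed is `seed * 1000 + subject`.
#' @return A list of `list(subject, seed, events, eeg, sc)` plus a
#'   `manifest` attribute summarizing the draw.
#' @export
make_dataset <- function(n_subjects, spec = protocol_spec(),
                         cfg = synth_config(), seed = 0L) {
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sseed <- as.integer(seed * 1000 + i)
    jit <- withr::with_seed(sseed, runif(3, 0.8, 1.2))
    scfg <- cfg
    scfg$alpha_reduction <- min(0.95, cfg$alpha_reduction * jit[1])
    scfg$beta_reduction <- min(0.95, cfg$beta_reduction * jit[2])
    if (spec$mode == "patient") scfg$scr_amp_p <- 0
    else scfg$scr_amp_p <- cfg$scr_amp_p * jit[3]
    events <- make_event_schedule(spec, seed = sseed)
    out[[i]] <- list(subject = i, seed = sseed, events = events,
                     eeg = synth_eeg(events, scfg, seed = sseed + 1),
                     sc = synth_sc(events, scfg, seed = sseed + 2))
  }
  attr(out, "manifest") <- data.frame(
    subject = seq_len(n_subjects),
    seed = vapply(out, function(s) s$seed, 0L),
    n_events = vapply(out, function(s) nrow(s$events), 0L))
  out
}
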