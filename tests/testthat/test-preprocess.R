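test_that("FIR band-pass has the designed pass/stop behavior", {
  fs <- 500; t <- (0:4999) / fs
  mid <- 2500:3500   # past the order/2 transient
  f25 <- bandpass(recording(matrix(sin(2 * pi * 25 * t), 1), fs, "Cz", "EEG"))
  expect_equal(max(abs(f25$data[1, mid])), 1, tolerance = 0.05)
  f1 <- bandpass(recording(matrix(sin(2 * pi * 1 * t), 1), fs, "Cz", "EEG"))
  expect_lt(20 * log10(max(abs(f1$data[1, mid]))), -20)
  expect_equal(attr(f25, "edge_s"), 2)   # order 2000 at 500 Hz
})

test_that("Chebyshev SC band-pass passes the phasic band within ripple", {
  fs <- 5; t <- (0:999) / fs
  f05 <- bandpass(recording(matrix(sin(2 * pi * 0.5 * t), 1), fs, "SC", "SC"))
  # 0.5 dB ripple floor ~ 0.944 amplitude
  expect_gt(max(abs(f05$data[1, 500:900])), 0.94)
  expect_lt(max(abs(f05$data[1, 500:900])), 1.01)
})

test_that("Chebyshev design matches reference coefficients", {
  # frozen from scipy.signal.cheby1(3, 0.5, [0.05, 2], 'bandpass', fs=5)
  ba <- painbci:::design_cheby1_bandpass(0.05, 2, 3, 5, 0.5)
  expect_equal(ba$b,
               c(0.4844435556, 0, -1.453330667, 0, 1.453330667, 0,
                 -0.4844435556), tolerance = 1e-9)
  expect_equal(ba$a,
               c(1, -1.134378263, -1.067300699, 0.7789185445, 1.022972895,
                 -0.4100893816, -0.1887365114), tolerance = 1e-9)
})

test_that("filtering is linear and rejects invalid band edges", {
  fs <- 500
  x <- matrix(rnorm(2000), 1)
  r1 <- bandpass(recording(x, fs, "Cz", "EEG"))
  r3 <- bandpass(recording(3 * x, fs, "Cz", "EEG"))
  expect_equal(r3$data, 3 * r1$data, tolerance = 1e-9)
  expect_error(bandpass(recording(x, 60, "Cz", "EEG"),
                        filter_spec("fir_hamming_sinc", 3, 40, 200)),
               class = "painbci_validation_error")
})

test_that("streaming filter equals one-pass causal filtering across chunks", {
  fs <- 500
  x <- matrix(rnorm(2 * 1500), 2)
  spec <- filter_spec("fir_hamming_sinc", 3, 40, 400)
  st <- stream_filter_init(spec, fs, 2)
  outs <- list()
  for (i in 1:6) {
    r <- stream_filter(st, x[, ((i - 1) * 250 + 1):(i * 250)])
    st <- r$state
    outs[[i]] <- r$out
  }
  streamed <- do.call(cbind, outs)
  h <- painbci:::design_fir_bandpass(3, 40, 400, fs)
  onepass <- t(apply(x, 1, function(ch)
    painbci:::conv_fft(ch, h)[seq_len(ncol(x))]))
  expect_equal(streamed, onepass, tolerance = 1e-9)

  # IIR path too
  spec2 <- sc_filter_spec()
  st2 <- stream_filter_init(spec2, 5, 1)
  y <- rnorm(100)
  r_a <- stream_filter(st2, matrix(y[1:40], 1))
  r_b <- stream_filter(r_a$state, matrix(y[41:100], 1))
  whole <- stream_filter(stream_filter_init(spec2, 5, 1), matrix(y, 1))
  expect_equal(cbind(r_a$out, r_b$out), whole$out, tolerance = 1e-10)
})

test_that("select_channels returns requested order and errors on missing", {
  data <- matrix(rnorm(24 * 100), 24)
  labs <- c(paste0("E", 1:18), "Cz", "C3", "C4", "CPz", "CP1", "CP2")
  rec <- recording(data, 500, labs, "EEG")
  sel <- select_channels(rec)
  expect_identical(sel$channel_names, c("Cz", "C3", "C4", "CPz", "CP1", "CP2"))
  expect_identical(sel$data[1, ], data[19, ])
  ident <- select_channels(rec, labs)
  expect_identical(ident$data, rec$data)
  err <- expect_error(select_channels(rec, "Fz"),
                      class = "painbci_validation_error")
  expect_match(conditionMessage(err), "available")
})

test_that("window extraction matches the closed-form counts", {
  fs <- 500
  rec <- recording(matrix(rnorm(6 * fs * 14), 6), fs,
                   c("Cz", "C3", "C4", "CPz", "CP1", "CP2"), "EEG")
  ev <- event_table(2, 4, "P")
  ws <- extract_windows(rec, ev, eeg_window_spec())
  expect_equal(n_windows(ws), 36)          # (2000 - 250)/50 + 1
  expect_equal(dim(ws$data)[2], 250)
  expect_true(all(ws$meta$label == "P"))
  expect_true(all(ws$meta$start_s >= 2 & ws$meta$start_s + 0.5 <= 6 + 1e-9))

  sc <- recording(matrix(rnorm(5 * 14), 1), 5, "SC", "SC")
  ws2 <- extract_windows(sc, ev, sc_window_spec())
  expect_equal(n_windows(ws2), 6)          # (20 - 10)/2 + 1
  expect_equal(dim(ws2$data)[2], 10)

  pat <- recording(matrix(rnorm(500 * 31), 1), 500, "Cz", "EEG")
  ws3 <- extract_windows(pat, event_table(0, 30, "P"),
                         patient_window_spec())
  expect_equal(n_windows(ws3), 30)
})

test_that("window bookkeeping follows floor((dur-len)/step)+1 and stays inside epochs", {
  fs <- 100
  rec <- recording(matrix(rnorm(fs * 60), 1), fs, "Cz", "EEG")
  for (dur in c(1, 2.5, 4)) for (len in c(0.5, 1)) for (ov in c(0, 0.5, 0.8)) {
    if (dur < len) next
    ev <- event_table(5, dur, "NP")
    ws <- extract_windows(rec, ev, window_spec(len, ov))
    step <- len * (1 - ov)
    expect_equal(n_windows(ws),
                 floor((round(dur * fs) - round(len * fs)) /
                         round(step * fs)) + 1,
                 info = sprintf("dur=%g len=%g ov=%g", dur, len, ov))
    expect_true(all(ws$meta$start_s >= 5 - 1e-9 &
                      ws$meta$start_s + len <= 5 + dur + 1e-9))
    expect_true(all(ws$meta$event_id == 1))
  }
  # epoch shorter than window: zero windows, message not error
  expect_message(ws0 <- extract_windows(rec, event_table(5, 0.3, "P"),
                                        window_spec(0.5, 0)),
                 "skipped")
  expect_equal(n_windows(ws0), 0)
})

test_that("artifact rejection partitions on the any-channel peak-to-peak rule", {
  fs <- 500
  dat <- matrix(0, 6, fs * 10)
  dat[3, 1000:1010] <- 200                       # spike on one channel
  rec <- recording(dat, fs, c("Cz", "C3", "C4", "CPz", "CP1", "CP2"), "EEG")
  ev <- event_table(c(1, 5), c(4, 4), c("P", "R"))
  ws <- extract_windows(rec, ev, eeg_window_spec())
  parts <- reject_artifacts(ws, 150)
  expect_equal(n_windows(parts$kept) + n_windows(parts$rejected),
               n_windows(ws))
  expect_true(all(parts$rejected$meta$event_id == 1))
  expect_gt(n_windows(parts$rejected), 0)
  # all-zero windows are kept
  expect_equal(n_windows(reject_artifacts(extract_windows(
    recording(matrix(0, 1, 5000), 500, "Cz", "EEG"),
    event_table(0, 4, "R"), eeg_window_spec()), 150)$rejected), 0)

  # SC ramp 0 -> 12 uS within one 2-s window exceeds the 10 uS rule
  ramp <- recording(matrix(c(seq(0, 12, length.out = 10), rep(12, 10)), 1),
                    5, "SC", "SC")
  wsr <- extract_windows(ramp, event_table(0, 4, "P"), window_spec(2, 0.8))
  rej <- reject_artifacts(wsr, 10)
  expect_gt(n_windows(rej$rejected), 0)
  expect_equal(rej$rejected$meta$start_s[1], 0)
})
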