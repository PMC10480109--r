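test_that("PSD localizes a sine, zeroes on silence, and is Parseval-consistent", {
  fs <- 500
  t <- (0:249) / fs
  spec <- compute_psd(sin(2 * pi * 10 * t), fs)
  expect_lt(abs(spec$freqs[which.max(spec$power)] - 10), fs / 1024 + 1e-9)
  expect_true(all(compute_psd(rep(0, 250), fs)$power == 0))

  # integral of PSD ~ variance for white noise (taper-normalized scaling)
  ratios <- vapply(1:100, function(s) withr::with_seed(s, {
    x <- rnorm(250)
    sp <- compute_psd(x, fs)
    sum(sp$power) * (sp$freqs[2] - sp$freqs[1]) / mean(x^2)
  }), 0)
  expect_equal(mean(ratios), 1, tolerance = 0.1)
})

test_that("band power concentrates, leaks little, and sub-bands stay below total", {
  fs <- 500
  t <- (0:249) / fs
  spec <- compute_psd(sin(2 * pi * 10 * t), fs)
  alpha <- band_power(spec, 8, 13)
  total <- band_power(spec, 3, 40)
  expect_gt(alpha / total, 0.95)
  expect_lt(band_power(spec, 4, 7) / total, 0.02)
  withr::with_seed(7, {
    spn <- compute_psd(rnorm(250), fs)
    parts <- band_power(spn, 4, 7) + band_power(spn, 8, 13) +
      band_power(spn, 13, 30) + band_power(spn, 30, 40)
    expect_lte(parts, band_power(spn, 3, 40) + 1e-12)
  })
  expect_error(band_power(spec, 0.01, 0.02),
               class = "painbci_validation_error")
})

test_that("peak frequency finds the dominant bin with low-frequency tie-break", {
  fs <- 500
  t <- (0:249) / fs
  df <- fs / 1024
  expect_lt(abs(peak_frequency(compute_psd(sin(2 * pi * 10 * t), fs)) - 10),
            df + 1e-9)
  two <- sin(2 * pi * 10 * t) + 0.4 * sin(2 * pi * 20 * t)
  expect_lt(abs(peak_frequency(compute_psd(two, fs)) - 10), df + 1e-9)
  expect_message(pf <- peak_frequency(compute_psd(rep(0, 250), fs)), "flat")
  expect_equal(pf, min(compute_psd(rep(0, 250), fs)$freqs[
    compute_psd(rep(0, 250), fs)$freqs >= 3]))
})

test_that("spectral entropy separates tones from noise and handles degeneracy", {
  fs <- 500
  t <- (0:249) / fs
  # frozen from an independent numpy periodogram oracle on the same case
  expect_equal(spectral_entropy(compute_psd(sin(2 * pi * 10 * t), fs)),
               0.5070187, tolerance = 1e-4)
  means <- vapply(1:100, function(s) withr::with_seed(s,
    spectral_entropy(compute_psd(rnorm(250), fs))), 0)
  expect_gt(mean(means), 0.9)
  onebin <- structure(list(freqs = seq(0, 250, length.out = 513),
                           power = c(rep(0, 20), 5, rep(0, 492)),
                           nfft = 1024), class = "bci_spectrum")
  expect_equal(spectral_entropy(onebin), 0)
})

test_that("sample entropy equals the naive counting oracle exactly", {
  for (s in 1:100) {
    x <- withr::with_seed(s, rnorm(100))
    r <- 0.2 * sd(x)
    expect_identical(sample_entropy(x, 2, r), naive_sampen(x, 2, r))
  }
  expect_equal(sample_entropy(rep(3, 50)), 0)
  # periodic more predictable than its shuffle
  saw <- rep(seq(0, 1, length.out = 25), 10)
  shuf <- withr::with_seed(1, sample(saw))
  expect_lt(sample_entropy(saw), sample_entropy(shuf))
  expect_error(sample_entropy(c(1, 2, 3), m = 2),
               class = "painbci_validation_error")
})

test_that("Higuchi FD hits the analytic limits and orders noise above tones", {
  expect_equal(higuchi_fd(2 * (0:249) / 500), 1, tolerance = 0.05)
  fds <- vapply(1:100, function(s) withr::with_seed(s,
    higuchi_fd(rnorm(250))), 0)
  expect_lt(abs(mean(fds) - 2), 0.15)
  t <- (0:249) / 500
  expect_gt(withr::with_seed(2, higuchi_fd(rnorm(250))),
            higuchi_fd(sin(2 * pi * 10 * t)))
})

test_that("RMS closed forms", {
  expect_equal(signal_rms(rep(-3, 100)), 3)
  t <- (0:499) / 500
  expect_equal(signal_rms(sin(2 * pi * 10 * t)), 1 / sqrt(2),
               tolerance = 0.01)
  expect_equal(signal_rms(numeric(10)), 0)
})

test_that("EEG feature vector: naming contract, zeros, scale equivariance", {
  fs <- 500
  chn <- c("Cz", "C3")
  w <- withr::with_seed(3, matrix(rnorm(2 * 250), 2))
  fv <- eeg_feature_vector(w, fs, channel_names = chn)
  expect_length(fv, 20)
  expect_identical(names(fv)[1:10],
                   paste0(c("theta_power", "alpha_power", "beta_power",
                            "gamma_power", "total_power", "peak_frequency",
                            "sample_entropy", "spectral_entropy",
                            "higuchi_fd", "rms"), "__Cz"))

  z <- suppressMessages(eeg_feature_vector(matrix(0, 2, 250), fs,
                                           channel_names = chn))
  expect_true(all(z[grep("power|rms", names(z))] == 0))
  expect_true(all(z[grep("sample_entropy|spectral_entropy", names(z))] == 0))

  f2 <- eeg_feature_vector(2 * w, fs, channel_names = chn)
  expect_equal(unname(f2["rms__Cz"]), unname(2 * fv["rms__Cz"]))
  expect_equal(unname(f2["alpha_power__Cz"]),
               unname(4 * fv["alpha_power__Cz"]))
  for (nm in c("spectral_entropy__Cz", "sample_entropy__Cz",
               "higuchi_fd__Cz"))
    expect_equal(unname(f2[nm]), unname(fv[nm]), tolerance = 1e-6)
  expect_error(eeg_feature_vector(matrix(NA_real_, 1, 250), fs),
               class = "painbci_validation_error")
})

test_that("SC feature vector closed forms and sort-based oracles", {
  fs <- 5
  ramp <- 0.5 * (0:9) / fs                    # x(t) = 0.5 t over 2 s
  fv <- sc_feature_vector(ramp, fs)
  expect_equal(unname(fv["slope"]), 0.5)
  expect_equal(unname(fv["range"]), 0.9)
  expect_equal(unname(fv["auc"]),
               sum((ramp[-1] + ramp[-10]) / 2) / fs)

  const <- sc_feature_vector(rep(3, 10), fs)
  expect_equal(unname(const[c("mean", "median", "max", "rms")]),
               rep(3, 4))
  expect_equal(unname(const[c("sd", "var", "iqr", "mad", "range",
                              "slope")]), rep(0, 6))
  expect_equal(unname(const["auc"]), 3 * 9 / fs)

  for (s in 1:25) {
    x <- withr::with_seed(s, rnorm(10))
    f <- sc_feature_vector(x, fs)
    expect_identical(unname(f["var"]), unname(f["sd"])^2)
    expect_equal(unname(f["iqr"]), sort_iqr(x))
    expect_equal(unname(f["mad"]), sort_mad(x))
    expect_equal(unname(f["median"]), sort_median(x))
  }
})

test_that("vectorized feature table equals the per-window reference path", {
  sub <- healthy_subject(1)
  ws <- extract_windows(bandpass(select_channels(sub$eeg)), sub$events,
                        eeg_window_spec())
  kept <- reject_artifacts(ws)$kept
  ft <- compute_features(kept)
  expect_true(all(is.finite(feature_matrix(ft))))
  for (i in c(1, 17, n_windows(kept))) {
    ref <- suppressMessages(eeg_feature_vector(
      matrix(kept$data[, , i], 6), kept$fs,
      channel_names = kept$channel_names))
    expect_equal(unlist(ft[i, names(ref)]), ref, tolerance = 1e-10)
  }
  # SC modality too
  ft_sc <- sub$ft_sc
  expect_identical(feature_names(ft_sc),
                   c("mean", "max", "median", "sd", "var", "iqr", "rms",
                     "range", "slope", "mad", "auc"))
  expect_true(all(is.finite(feature_matrix(ft_sc))))
})

test_that("feature tables survive the CSV round trip", {
  sub <- sc_subject(1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(sub$ft, path)
  back <- read_features(path)
  expect_identical(feature_names(back), feature_names(sub$ft))
  expect_equal(feature_matrix(back), feature_matrix(sub$ft),
               tolerance = 1e-12)
})
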