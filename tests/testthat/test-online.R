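test_that("fuse_recent implements the weighted-mean rule with strict threshold", {
  cls <- data.frame(id = 1:4, t = c(0.5, 1, 1, 1),
                    modality = c("EEG", "EEG", "SC", "SC"),
                    p_pain = c(1, 1, 1, 1))
  d <- fuse_recent(cls, 1)
  expect_equal(d$p_pain, 1)
  expect_true(d$trigger)

  cls$p_pain <- c(1, 1, 0, 0)
  d2 <- fuse_recent(cls, 1)
  expect_equal(d2$p_pain, 0.5)
  expect_false(d2$trigger)            # strict >

  sc_only <- data.frame(id = 1:2, t = c(0.6, 1), modality = "SC",
                        p_pain = c(0.8, 0.6))
  d3 <- fuse_recent(sc_only, 1)
  expect_equal(d3$p_pain, 0.7)        # weights renormalize to SC alone
  expect_true(d3$trigger)

  expect_null(fuse_recent(cls[0, ], 1))
})

test_that("classify_chunk: oracle path, artifact no-decision, determinism", {
  ev <- event_table(c(0, 12), c(4, 4), c("P", "R"))
  dec <- oracle_decoder(ev, "EEG")
  chunk <- matrix(0, 6, 250)
  r1 <- classify_chunk(dec, chunk, t_start = 1)     # inside P epoch
  expect_equal(r1$p_pain, 1)
  r2 <- classify_chunk(dec, chunk, t_start = 13)    # inside R epoch
  expect_equal(r2$p_pain, 0)
  expect_identical(classify_chunk(dec, chunk, t_start = 1)[1:3], r1[1:3])

  sub <- sc_subject(1)
  tdec <- train_decoder(sub$ft, c("P", "R"), modality = "SC")
  spike <- matrix(c(rep(0, 5), rep(300, 5)), 1)     # 300 uS step
  st <- NULL
  ra <- classify_chunk(tdec, spike, st, 0)
  expect_true(ra$no_decision)
  expect_equal(ra$p_pain, 0)                        # carry-forward from start
  expect_error(classify_chunk(tdec, matrix(0, 1, 7)),
               class = "painbci_validation_error")
})

test_that("oracle decoders drive the healthy engine to perfect event rates", {
  ev <- make_event_schedule(protocol_spec("healthy", n_per_class = 4),
                            seed = 9)
  cfgS <- synth_config(artifact_rate_per_min = 0)
  eeg <- synth_eeg(ev, cfgS, seed = 10)
  sc <- synth_sc(ev, cfgS, seed = 11)
  log <- run_healthy_engine(eeg, sc,
                            list(eeg = oracle_decoder(ev, "EEG"),
                                 sc = oracle_decoder(ev, "SC")))
  res <- evaluate_triggers(log, ev)
  expect_equal(unname(res$rates["P"]), 1)
  expect_equal(unname(res$rates["R"]), 1)
  expect_equal(unname(res$rates["NP"]), 1)
  # latency: every P event triggers within decision period + max chunk + 1 s
  pe <- ev[ev$trial_type == "P", ]
  for (i in seq_len(nrow(pe))) {
    lat <- min(log$triggers[log$triggers > pe$onset[i]]) - pe$onset[i]
    expect_lte(lat, 1 + 2 + 1)
  }
  # empty schedule: a pure-rest stream with oracle decoders never triggers
  rest <- event_table(numeric(0), numeric(0), character(0), integer(0))
  log0 <- run_healthy_engine(eeg, sc,
                             list(eeg = oracle_decoder(rest, "EEG"),
                                  sc = oracle_decoder(rest, "SC")))
  expect_length(log0$triggers, 0)
})

test_that("healthy engine is deterministic (byte-identical logs)", {
  ev <- make_event_schedule(protocol_spec("healthy", n_per_class = 2),
                            seed = 3)
  cfgS <- synth_config()
  eeg <- synth_eeg(ev, cfgS, seed = 4)
  sc <- synth_sc(ev, cfgS, seed = 5)
  decs <- list(eeg = oracle_decoder(ev, "EEG"),
               sc = oracle_decoder(ev, "SC"))
  expect_identical(run_healthy_engine(eeg, sc, decs),
                   run_healthy_engine(eeg, sc, decs))
})

test_that("trigger evaluation applies the 4-s grace boundary", {
  ev <- event_table(c(0, 20), c(4, 4), c("P", "P"))
  mk_log <- function(tr) painbci:::new_decision_log(
    data.frame(), data.frame(), tr, engine_config())
  r1 <- evaluate_triggers(mk_log(c(4 + 3.9)), ev)
  expect_true(r1$per_event$correct[1])
  expect_false(r1$per_event$correct[2])
  r2 <- evaluate_triggers(mk_log(c(4 + 4.1)), ev)
  expect_false(r2$per_event$correct[1])   # past end + grace
  r3 <- evaluate_triggers(mk_log(numeric(0)),
                          event_table(c(0, 12, 24), rep(4, 3),
                                      c("P", "NP", "R")))
  expect_equal(as.numeric(r3$rates[c("P", "NP", "R")]), c(0, 1, 1))
})

test_that("patient engine: majority vote, warm-up, 6-s chunk release", {
  blocks <- event_table(c(0, 30), c(30, 30), c("P", "R"))
  cfgS <- synth_config(artifact_rate_per_min = 0)
  eeg <- synth_eeg(blocks, cfgS, seed = 6, tail_s = 0)
  log <- run_patient_engine(eeg, oracle_decoder(blocks, "EEG"), blocks)
  # warm-up: no final classification before vote_n seconds
  expect_gte(min(log$final$t), 3)
  p_chunks <- log$chunks[log$chunks$truth == "P", ]
  expect_equal(nrow(p_chunks), 5)
  expect_true(all(p_chunks$released))
  m <- evaluate_triggers(log, mode = "patient")
  expect_equal(unname(m$recall["P"]), 1)

  # enumeration of vote windows: an isolated deviant label is absorbed
  # (no output flip), and the output never flips more often than the input
  vote <- function(labs) vapply(3:length(labs), function(i)
    names(which.max(table(labs[(i - 2):i]))), "")
  blip <- c("P", "P", "P", "R", "P", "P", "P")
  expect_true(all(vote(blip) == "P"))
  flips <- function(x) sum(x[-1] != x[-length(x)])
  alt <- rep(c("P", "R"), 15)
  expect_lte(flips(vote(alt)), flips(alt))
})

test_that("modality contribution is symmetric and respects dominance", {
  cfg <- engine_config()
  ev <- event_table(0, 4, "P")
  mk <- function(p_eeg, p_sc) {
    cls <- data.frame(id = 1:3, t = c(0.5, 1, 1),
                      modality = c("EEG", "EEG", "SC"),
                      p_pain = c(p_eeg, p_eeg, p_sc))
    dec <- data.frame(t = 1, p_pain = NA, trigger = TRUE)
    dec$used <- I(list(1:3))
    painbci:::new_decision_log(cls, dec, 1, cfg)
  }
  expect_equal(modality_contribution(mk(1, 0), ev, cfg),
               c(eeg = 1, sc = 0))
  expect_equal(modality_contribution(mk(0.7, 0.7), ev, cfg),
               c(eeg = 0.5, sc = 0.5))
  expect_gt(modality_contribution(mk(0.4, 0.9), ev, cfg)[["sc"]], 0.5)
})

test_that("pulse-width envelope peaks with the wave and vanishes off contact", {
  t <- seq(0, 10, by = 0.01)
  height <- pmax(0, 1 - abs(t - 5) / 2)        # triangular contact 3..7 s
  pw <- pulse_width_envelope(t, height, pw_max = 500)
  expect_equal(max(pw), 500)
  expect_equal(t[which.max(pw)], 5)
  expect_true(all(pw[t < 3 | t > 7] == 0))
  # symmetric wave -> symmetric envelope
  inside <- pw[t >= 3 & t <= 7]
  expect_equal(inside, rev(inside), tolerance = 1e-9)
  expect_equal(attr(pw, "freq_hz"), 50)
  expect_error(pulse_width_envelope(t, height - 2),
               class = "painbci_validation_error")
})

test_that("decoders trained on a disjoint session sustain online pain recall", {
  train <- healthy_subject(1)
  dec_e <- train_decoder(train$ft_eeg, c("P", "R"), modality = "EEG")
  dec_s <- train_decoder(train$ft_sc, c("P", "R"), modality = "SC")
  test_ev <- make_event_schedule(protocol_spec("healthy", n_per_class = 6),
                                 seed = 40)
  cfgS <- synth_config()
  eeg <- synth_eeg(test_ev, cfgS, seed = 41)
  sc <- synth_sc(test_ev, cfgS, seed = 42)
  log <- run_healthy_engine(eeg, sc, list(eeg = dec_e, sc = dec_s))
  res <- evaluate_triggers(log, test_ev)
  expect_gt(res$pain_recall, 0.6)
  mc <- modality_contribution(log, test_ev)
  expect_true(is.finite(mc[["sc"]]))
})
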