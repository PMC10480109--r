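#' Online engine configuration
#'
#' Healthy pipeline: EEG is classified on 0.5-s chunks and SC on a sliding
#' 2-s window; the final (fused) decision is made every second from the
#' most recent classifications (up to `fusion_window_n` = 4, at most 2 per
#' modality), weighting the per-modality mean pain posteriors. A trigger is
#' released when the fused posterior strictly exceeds `trigger_threshold`;
#' a released intervention suppresses re-triggering for `intervention_s`
#' (one wave cycle). A painful event counts as detected if a trigger falls
#' inside `(onset, end + grace_s]`. Patient pipeline: 1-s windows each
#' second, majority vote over the last `vote_n` = 3 labels, block split
#' into `patient_chunk_s` = 6-s chunks released iff any in-chunk final
#' label is pain.
#'
#' Note the SC hop is 1 s (not 0.5 s): at the 5 Hz SC rate a 0.5-s hop is
#' not an integer number of samples, so SC contributes one classification
#' per decision period.
#'
#' @param eeg_chunk_s,sc_chunk_s,sc_hop_s chunking, seconds.
#' @param decision_period_s fused-decision period, seconds.
#' @param fusion_window_n maximum classifications consumed per decision.
#' @param weights named weights `c(eeg =, sc =)`, non-negative, summing
#'   to 1.
#' @param trigger_threshold fused posterior must strictly exceed this.
#' @param grace_s correctness window after stimulus end, seconds.
#' @param intervention_s refractory period after a trigger, seconds.
#' @param patient_row_s,vote_n,patient_chunk_s patient-pipeline settings.
#' @export
engine_config <- function(eeg_chunk_s = 0.5, sc_chunk_s = 2, sc_hop_s = 1,
                          decision_period_s = 1, fusion_window_n = 4,
                          weights = c(eeg = 0.5, sc = 0.5),
                          trigger_threshold = 0.5, grace_s = 4,
                          intervention_s = 10,
                          patient_row_s = 1, vote_n = 3,
                          patient_chunk_s = 6) {
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    abort_painbci("weights must be non-negative and sum to 1",
                  "painbci_validation_error")
  if (vote_n %% 2 != 1)
    abort_painbci("vote_n must be odd", "painbci_validation_error")
  structure(as.list(environment()), class = "bci_engine_config")
}

#' Oracle decoder for closed-loop validation
#'
#' A stand-in decoder that knows the true event schedule and returns pain
#' posterior 1 for chunks whose midpoint falls inside a P epoch and 0
#' otherwise. Used to validate the engine's trigger logic independently of
#' decoding quality.
#'
#' @param events the true `bci_events` schedule.
#' @param modality tag carried in the log.
#' @export
oracle_decoder <- function(events, modality = "EEG") {
  validate_events(events)
  structure(list(events = events, modality = modality,
                 classes = c("P", "R")),
            class = "oracle_decoder")
}

in_p_epoch <- function(t, events) {
  pe <- events[events$trial_type == "P", , drop = FALSE]
  any(t >= pe$onset & t < pe$onset + pe$duration)
}

new_chunk_state <- function(decoder, channel_names = NULL) {
  if (inherits(decoder, "oracle_decoder")) return(list(oracle = TRUE))
  fspec <- structure(decoder$filter_spec, class = "bci_filter_spec")
  nch <- if (decoder$modality == "EEG") length(decoder$feature_names) / 10
         else 1
  list(oracle = FALSE,
       filter = stream_filter_init(fspec, decoder$fs, as.integer(nch)),
       channel_names = channel_names, last_p = 0)
}

#' Classify one streamed chunk
#'
#' Applies the decoder's causal (stateful) band-pass filter, the
#' peak-to-peak artifact check, feature extraction, the stored z-scaler and
#' the SVM posterior. Artifact-flagged chunks emit a no-decision marker and
#' carry the previous valid posterior forward (0 at stream start) so the
#' decision grid stays regular.
#'
#' @param decoder a `bci_decoder` or [oracle_decoder()].
#' @param chunk channels-by-samples matrix matching the decoder's expected
#'   window.
#' @param state chunk-classifier state from a previous call, or `NULL` to
#'   initialize; pass `channel_names` via [run_healthy_engine()] for named
#'   feature columns.
#' @param t_start chunk start time, seconds.
#' @return `list(p_pain, label, no_decision, state)`.
#' @export
classify_chunk <- function(decoder, chunk, state = NULL, t_start = 0) {
  if (is.vector(chunk)) chunk <- matrix(chunk, nrow = 1)
  if (inherits(decoder, "oracle_decoder")) {
    mid <- t_start + ncol(chunk) / 2 / (if (decoder$modality == "EEG") 500 else 5)
    p <- as.numeric(in_p_epoch(mid, decoder$events))
    return(list(p_pain = p, label = if (p > 0.5) "P" else "R",
                no_decision = FALSE, state = state %||% list(oracle = TRUE)))
  }
  if (is.null(state)) state <- new_chunk_state(decoder)
  expected <- round(decoder$window_spec$length_s * decoder$fs)
  if (ncol(chunk) != expected)
    abort_painbci(sprintf("chunk has %d samples, decoder expects %d",
                          ncol(chunk), expected),
                  "painbci_validation_error")
  flt <- stream_filter(state$filter, chunk)
  state$filter <- flt$state
  ptp <- max(apply(flt$out, 1, function(x) max(x) - min(x)))
  if (ptp > decoder$window_spec$ptp_reject_threshold) {
    p <- state$last_p
    return(list(p_pain = p, label = if (p > 0.5) "P" else "R",
                no_decision = TRUE, state = state))
  }
  fv <- if (decoder$modality == "EEG")
    eeg_feature_vector(flt$out, decoder$fs,
                       channel_names = state$channel_names)
  else sc_feature_vector(flt$out, decoder$fs)
  x <- matrix(fv, nrow = 1, dimnames = list(NULL, names(fv)))
  colnames(x) <- decoder$scaler$feature_names   # positional contract
  xs <- zscore_apply(decoder$scaler, x)
  model <- decoder$svm
  class(model) <- "rbf_svm"
  pr <- predict(model, xs, type = "prob")
  p <- if ("P" %in% colnames(pr)) pr[1, "P"] else 0
  lab <- predict(model, xs, type = "class")
  state$last_p <- p
  list(p_pain = unname(p), label = lab, no_decision = FALSE, state = state)
}

#' Fuse the most recent per-modality classifications
#'
#' At decision time `t`, takes the most recent (up to 2 per modality)
#' classifications with timestamps in `(t - decision_period, t]`, averages
#' pain posteriors within each modality, and combines the modality means
#' with the configured weights; if one modality has no classification in
#' the window, the weights renormalize over those present. The trigger
#' condition is strict (`fused > threshold`), so an exact tie at the
#' threshold does not trigger.
#'
#' @param classifications data frame with columns `id`, `t`, `modality`,
#'   `p_pain` (e.g. `log$classifications`).
#' @param t decision time, seconds.
#' @param cfg an [engine_config()].
#' @return `list(t, p_pain, trigger, used)` or `NULL` when no
#'   classification is available.
#' @export
fuse_recent <- function(classifications, t, cfg = engine_config()) {
  win <- classifications[classifications$t > t - cfg$decision_period_s &
                           classifications$t <= t, , drop = FALSE]
  if (nrow(win) == 0) return(NULL)
  per_mod <- cfg$fusion_window_n %/% 2
  used <- integer(0); means <- c(); w <- c()
  for (mod in names(cfg$weights)) {
    rows <- win[win$modality == toupper(mod), , drop = FALSE]
    if (nrow(rows) == 0) next
    rows <- rows[order(rows$t, decreasing = TRUE), , drop = FALSE]
    rows <- utils::head(rows, per_mod)
    used <- c(used, rows$id)
    means <- c(means, mean(rows$p_pain))
    w <- c(w, cfg$weights[[mod]])
  }
  if (!length(means) || sum(w) == 0) return(NULL)
  p <- sum(w / sum(w) * means)
  list(t = t, p_pain = p, trigger = p > cfg$trigger_threshold,
       used = used)
}

new_decision_log <- function(classifications, decisions, triggers,
                             cfg, extra = list()) {
  structure(c(list(classifications = classifications,
                   decisions = decisions, triggers = triggers,
                   config = unclass(cfg)), extra),
            class = "bci_decision_log")
}

#' @export
print.bci_decision_log <- function(x, ...) {
  cat(sprintf("<bci_decision_log> %d classification(s), %d decision(s), %d trigger(s)\n",
              nrow(x$classifications), nrow(x$decisions),
              length(x$triggers)))
  invisible(x)
}

#' Run the healthy-subject closed-loop engine on a recorded session
#'
#' Replays the EEG recording in 0.5-s chunks and the SC recording in 1-s
#' hops feeding a sliding 2-s window, classifies each with its decoder
#' (causal stateful filtering), fuses every second with [fuse_recent()],
#' and releases the intervention on a strict-threshold crossing with a
#' refractory period of `cfg$intervention_s`.
#'
#' @param eeg,sc `bci_recording`s of the session.
#' @param decoders `list(eeg =, sc =)` of `bci_decoder` /
#'   [oracle_decoder()] objects.
#' @param events optional true schedule (only consumed by oracle decoders
#'   at construction; kept for signature symmetry).
#' @param cfg an [engine_config()].
#' @return A `bci_decision_log`.
#' @export
run_healthy_engine <- function(eeg, sc, decoders, events = NULL,
                               cfg = engine_config()) {
  stopifnot(is.list(decoders), !is.null(decoders$eeg), !is.null(decoders$sc))
  cls <- list()
  id <- 0L
  # EEG chunk classifications
  st_eeg <- if (inherits(decoders$eeg, "oracle_decoder")) NULL
            else new_chunk_state(decoders$eeg, eeg$channel_names)
  for (ch in playback_stream(eeg, cfg$eeg_chunk_s)) {
    r <- classify_chunk(decoders$eeg, ch$data, st_eeg, ch$start_s)
    st_eeg <- r$state
    id <- id + 1L
    cls[[id]] <- data.frame(id = id, t = ch$start_s + cfg$eeg_chunk_s,
                            modality = "EEG", p_pain = r$p_pain,
                            label = r$label, no_decision = r$no_decision)
  }
  # SC sliding-window classifications: causal filter per hop, classify the
  # filtered buffer once it spans a full window
  hop_n <- round(cfg$sc_hop_s * sc$fs)
  win_n <- round(cfg$sc_chunk_s * sc$fs)
  oracle_sc <- inherits(decoders$sc, "oracle_decoder")
  st_sc <- if (oracle_sc) NULL else new_chunk_state(decoders$sc, "SC")
  buf <- numeric(0)
  for (hp in playback_stream(sc, cfg$sc_hop_s)) {
    t_end <- hp$start_s + cfg$sc_hop_s
    if (oracle_sc) {
      if (t_end < cfg$sc_chunk_s) next
      r <- classify_chunk(decoders$sc, matrix(0, 1, win_n), NULL,
                          t_end - cfg$sc_chunk_s)
    } else {
      flt <- stream_filter(st_sc$filter, hp$data)
      st_sc$filter <- flt$state
      buf <- c(buf, flt$out[1, ])
      if (length(buf) > win_n) buf <- utils::tail(buf, win_n)
      if (length(buf) < win_n) next
      r <- classify_sc_window(decoders$sc, buf, st_sc)
      st_sc <- r$state
    }
    id <- id + 1L
    cls[[id]] <- data.frame(id = id, t = t_end, modality = "SC",
                            p_pain = r$p_pain, label = r$label,
                            no_decision = r$no_decision)
  }
  classifications <- do.call(rbind, cls)
  classifications <- classifications[order(classifications$t,
                                           classifications$id), ]
  # fused decisions on the 1-s grid
  t_max <- floor(min(recording_duration(eeg), recording_duration(sc)))
  decisions <- list(); triggers <- numeric(0)
  refractory_until <- -Inf
  used_list <- list()
  for (t in seq_len(t_max) * cfg$decision_period_s) {
    d <- fuse_recent(classifications, t, cfg)
    if (is.null(d)) next
    fire <- d$trigger && t > refractory_until
    if (fire) {
      triggers <- c(triggers, t)
      refractory_until <- t + cfg$intervention_s
    }
    decisions[[length(decisions) + 1L]] <-
      data.frame(t = t, p_pain = d$p_pain, trigger = fire)
    used_list[[length(used_list) + 1L]] <- d$used
  }
  decisions <- do.call(rbind, decisions)
  decisions$used <- I(used_list)
  new_decision_log(classifications, decisions, triggers, cfg)
}

# SC classification on an already-filtered window (the engine filters the
# stream once; offline-trained scaler/SVM apply unchanged).
classify_sc_window <- function(decoder, xwin, state) {
  ptp <- max(xwin) - min(xwin)
  if (ptp > decoder$window_spec$ptp_reject_threshold) {
    p <- state$last_p
    return(list(p_pain = p, label = if (p > 0.5) "P" else "R",
                no_decision = TRUE, state = state))
  }
  fv <- sc_feature_vector(xwin, decoder$fs)
  x <- matrix(fv, nrow = 1, dimnames = list(NULL, names(fv)))
  colnames(x) <- decoder$scaler$feature_names
  xs <- zscore_apply(decoder$scaler, x)
  model <- decoder$svm
  class(model) <- "rbf_svm"
  pr <- predict(model, xs, type = "prob")
  p <- if ("P" %in% colnames(pr)) pr[1, "P"] else 0
  state$last_p <- p
  list(p_pain = unname(p), label = predict(model, xs, type = "class"),
       no_decision = FALSE, state = state)
}

#' Run the patient closed-loop engine
#'
#' Classifies non-overlapping 1-s EEG windows each second, forms the final
#' label each second as the majority of the last `vote_n` (3) labels (no
#' final label during the warm-up), and splits each 30-s block into 6-s
#' chunks aligned to the block start; a chunk is released iff any final
#' label inside it is pain.
#'
#' @param eeg the patient EEG `bci_recording`.
#' @param decoder a `bci_decoder` or [oracle_decoder()].
#' @param blocks the block schedule (`bci_events`, alternating R/P).
#' @param cfg an [engine_config()].
#' @return A `bci_decision_log` with an extra `$chunks` table
#'   (`block_id`, `start_s`, `truth`, `released`).
#' @export
run_patient_engine <- function(eeg, decoder, blocks,
                               cfg = engine_config()) {
  st <- if (inherits(decoder, "oracle_decoder")) NULL
        else new_chunk_state(decoder, eeg$channel_names)
  cls <- list()
  id <- 0L
  for (ch in playback_stream(eeg, cfg$patient_row_s)) {
    r <- classify_chunk(decoder, ch$data, st, ch$start_s)
    st <- r$state
    id <- id + 1L
    cls[[id]] <- data.frame(id = id, t = ch$start_s + cfg$patient_row_s,
                            modality = "EEG", p_pain = r$p_pain,
                            label = r$label, no_decision = r$no_decision)
  }
  classifications <- do.call(rbind, cls)
  labs <- classifications$label
  n <- length(labs)
  final <- data.frame(t = numeric(0), label = character(0))
  if (n >= cfg$vote_n) {
    idx <- cfg$vote_n:n
    maj <- vapply(idx, function(i) {
      recent <- labs[(i - cfg$vote_n + 1):i]
      names(which.max(table(recent)))
    }, "")
    final <- data.frame(t = classifications$t[idx], label = maj)
  }
  chunks <- list()
  for (b in seq_len(nrow(blocks))) {
    n_chunks <- floor(blocks$duration[b] / cfg$patient_chunk_s)
    for (j in seq_len(n_chunks)) {
      cs <- blocks$onset[b] + (j - 1) * cfg$patient_chunk_s
      ce <- cs + cfg$patient_chunk_s
      in_chunk <- final$t > cs & final$t <= ce
      chunks[[length(chunks) + 1L]] <-
        data.frame(block_id = blocks$event_id[b], start_s = cs,
                   truth = blocks$trial_type[b],
                   released = any(final$label[in_chunk] == "P"))
    }
  }
  chunks <- do.call(rbind, chunks)
  triggers <- chunks$start_s[chunks$released]
  decisions <- data.frame(t = final$t,
                          p_pain = as.numeric(final$label == "P"),
                          trigger = final$label == "P")
  new_decision_log(classifications, decisions, triggers, cfg,
                   extra = list(final = final, chunks = chunks))
}

#' Evaluate intervention triggers against the true schedule
#'
#' Healthy mode: an event's response window is `(onset, end + grace_s]`;
#' a P event is correct iff at least one trigger falls inside it, an NP or
#' R event iff none does. Returns per-class correctness rates, the
#' per-event table, and pain recall (the P rate). Patient mode: chunk-level
#' truth (block label) versus release, reported as a
#' [classification_metrics()] confusion with pain precision/recall.
#'
#' @param log a `bci_decision_log`.
#' @param events the true schedule (healthy mode).
#' @param cfg an [engine_config()].
#' @param mode `"healthy"` or `"patient"`.
#' @return A list (healthy) or `bci_metrics` (patient).
#' @export
evaluate_triggers <- function(log, events = NULL, cfg = engine_config(),
                              mode = c("healthy", "patient")) {
  mode <- match.arg(mode)
  if (mode == "patient") {
    ch <- log$chunks
    pred <- ifelse(ch$released, "P", "R")
    m <- classification_metrics(ch$truth, pred, c("P", "R"))
    return(m)
  }
  validate_events(events)
  correct <- logical(nrow(events))
  hit <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    w0 <- events$onset[i]
    w1 <- events$onset[i] + events$duration[i] + cfg$grace_s
    hit[i] <- any(log$triggers > w0 & log$triggers <= w1)
    correct[i] <- if (events$trial_type[i] == "P") hit[i] else !hit[i]
  }
  rates <- tapply(correct, events$trial_type, mean)
  per_event <- cbind(as.data.frame(events), triggered = hit,
                     correct = correct)
  list(rates = rates, pain_recall = unname(rates["P"]),
       per_event = per_event)
}

#' Per-modality contribution to correct pain triggers
#'
#' Over fused decisions that fired inside some P event's response window,
#' a modality's contribution is its weighted mean pain posterior (the same
#' quantity the fusion rule combines) divided by the fused total, averaged
#' across those decisions. Defining the contribution on modality means
#' rather than raw member sums keeps it invariant to how many
#' classifications each modality happens to emit per decision period
#' (EEG emits two per second, SC one), so equal posteriors give exactly
#' (0.5, 0.5). The two fractions sum to 1.
#'
#' @param log a healthy-engine `bci_decision_log`.
#' @param events the true schedule.
#' @param cfg an [engine_config()].
#' @return `c(eeg =, sc =)`.
#' @export
modality_contribution <- function(log, events, cfg = engine_config()) {
  dec <- log$decisions
  fr <- c()
  for (i in seq_len(nrow(dec))) {
    if (!dec$trigger[i]) next
    t <- dec$t[i]
    in_p <- any(events$trial_type == "P" & t > events$onset &
                  t <= events$onset + events$duration + cfg$grace_s)
    if (!in_p) next
    mem <- log$classifications[log$classifications$id %in% dec$used[[i]], ]
    parts <- c(eeg = 0, sc = 0)
    w <- c(eeg = 0, sc = 0)
    for (mod in c("eeg", "sc")) {
      rows <- mem[mem$modality == toupper(mod), , drop = FALSE]
      if (nrow(rows) == 0) next
      parts[mod] <- mean(rows$p_pain)
      w[mod] <- cfg$weights[[mod]]
    }
    tot <- sum(w * parts)
    if (tot <= 0) next
    fr <- c(fr, w[["eeg"]] * parts[["eeg"]] / tot)
  }
  if (!length(fr)) return(c(eeg = NA_real_, sc = NA_real_))
  c(eeg = mean(fr), sc = 1 - mean(fr))
}

#' Gaussian pulse-width envelope following a wave trajectory
#'
#' Within each interval where the virtual wave touches the feet, the TENS
#' pulse width follows a Gaussian course peaking (at `pw_max`) when the
#' wave height is maximal, with spread `sigma_frac` times the contact
#' interval length; outside contact the pulse width is 0. The stimulation
#' frequency is fixed at 50 Hz (attribute `freq_hz`).
#'
#' @param t time grid, seconds.
#' @param height wave height samples (>= 0) on `t`.
#' @param contacts data frame `start`/`end` of contact intervals; derived
#'   from `height > 0` runs when omitted.
#' @param pw_max peak pulse width, microseconds.
#' @param sigma_frac Gaussian SD as a fraction of the interval length.
#' @return Pulse width versus time (same length as `t`).
#' @export
pulse_width_envelope <- function(t, height, contacts = NULL, pw_max = 500,
                                 sigma_frac = 1 / 6) {
  if (any(height < 0))
    abort_painbci("wave height must be >= 0", "painbci_validation_error")
  if (is.null(contacts)) {
    on <- height > 0
    edges <- diff(c(FALSE, on, FALSE))
    starts <- t[which(edges == 1)]
    ends_i <- which(edges == -1) - 1
    contacts <- data.frame(start = starts, end = t[ends_i])
  }
  pw <- numeric(length(t))
  for (r in seq_len(nrow(contacts))) {
    sel <- t >= contacts$start[r] & t <= contacts$end[r]
    if (!any(sel)) next
    t_peak <- t[sel][which.max(height[sel])]
    sigma <- sigma_frac * (contacts$end[r] - contacts$start[r])
    pw[sel] <- pw_max * exp(-(t[sel] - t_peak)^2 / (2 * sigma^2))
  }
  structure(pw, freq_hz = 50)
}
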