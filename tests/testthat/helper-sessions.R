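# Lazily built, memoised synthetic sessions shared across test files, so
# the expensive EEG feature extraction runs once per process.

.session_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.session_cache[[key]]))
    assign(key, builder(), envir = .session_cache)
  .session_cache[[key]]
}

# One healthy subject: events + recordings + both feature tables.
healthy_subject <- function(seed = 1) {
  cached(paste0("healthy_", seed), function() {
    ev <- make_event_schedule(protocol_spec("healthy"), seed = seed)
    eeg <- synth_eeg(ev, synth_config(), seed = seed + 1)
    sc <- synth_sc(ev, synth_config(), seed = seed + 2)
    list(events = ev, eeg = eeg, sc = sc,
         ft_eeg = offline_features(eeg, ev),
         ft_sc = offline_features(sc, ev))
  })
}

# SC-only subject (cheap) for decode-level properties.
sc_subject <- function(seed = 1) {
  cached(paste0("sc_", seed), function() {
    ev <- make_event_schedule(protocol_spec("healthy"), seed = seed)
    sc <- synth_sc(ev, synth_config(), seed = seed + 2)
    list(events = ev, ft = offline_features(sc, ev))
  })
}

# The 13-subject healthy dataset used by the acceptance criteria; features
# are attached per subject on first use.
acceptance_dataset <- function(seed = 0) {
  cached(paste0("dataset_", seed), function() {
    ds <- make_dataset(13, protocol_spec("healthy"), synth_config(),
                       seed = seed)
    lapply(ds, function(s) {
      s$ft_eeg <- offline_features(s$eeg, s$events)
      s$ft_sc <- offline_features(s$sc, s$events)
      s
    })
  })
}
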