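# Shared small fixtures, built once per test run.

# a compact synthetic-study slice: high-regularity stream, observer trace,
# 72-parcel atlas, and one subject's epochs at reduced trial count
fixture_epochs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      atlas <- make_atlas(seed = 1)
      seq_hr <- generate_sequence("high", 240, seed = 2)
      trace <- run_observer(seq_hr)
      cfg <- sim_config(n_trials = 720, seed = 5)
      cache <<- list(
        atlas = atlas, seq = seq_hr, trace = trace, cfg = cfg,
        epochs = generate_epochs(seq_hr, trace, atlas, cfg)
      )
    }
    cache
  }
})

# tiny 3-tone alphabet spanning less than one octave
toneset3 <- function() {
  tibble::tibble(tone = 0:2, label = c("C4", "E4", "G4"),
                 freq_hz = c(261.63, 329.63, 392.00))
}
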