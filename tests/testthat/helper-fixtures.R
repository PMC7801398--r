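# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# One subject of 300-s alpha-band-limited noise, segmented into 20-s
# epochs on the 75%-overlap grid.
fixture_noise_epochs <- function() {
  fixture("noise_epochs", function() {
    sig <- generate_bandlimited_noise(300, 250, c(8, 13), seed = 42)
    segment_epochs(sig, 250, subject_id = "noise1")
  })
}

# A modulated-oscillation subject with strong envelope LRTC (H = 0.85).
fixture_lrtc_epochs <- function() {
  fixture("lrtc_epochs", function() {
    sim <- generate_modulated_oscillation(
      signal_spec(envelope_exponent = 0.85, seed = 77))
    segment_epochs(sim$signal, 250, subject_id = "lrtc1")
  })
}
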