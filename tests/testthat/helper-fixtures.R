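# Shared fixtures: small cohorts are generated once per test run and
# cached, keyed by their configuration.

.fixture_env <- new.env(parent = emptyenv())

# Generate (or fetch) a cohort in a session-persistent temp dir.
fixture_cohort <- function(key, config, components = "posteriors") {
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  dir <- file.path(tempdir(), paste0("cohort-", key))
  res <- generate_cohort(config, dir, components = components)
  res$dir <- dir
  .fixture_env[[key]] <- res
  res
}

# A small effect-bearing cohort with posterior streams only.
small_pac_cohort <- function() {
  fixture_cohort("pac-small",
                 cohort_config(n_patients = 5,
                               protocols = c("pataka", "vowels", "digits"),
                               seed = 301L))
}

# A small cohort with audio, strong spectral contrast between states.
small_audio_cohort <- function() {
  fixture_cohort("audio-small",
                 cohort_config(n_patients = 4,
                               protocols = c("pataka", "vowels"),
                               gain_db_off = 12, aspiration_off = 0.1,
                               seed = 302L),
                 components = c("posteriors", "audio"))
}

# Cached 16-kHz waveforms for the audio fixture cohort.
fixture_waves <- function(res) {
  if (is.null(.fixture_env$waves16))
    .fixture_env$waves16 <- load_cohort_audio(res$manifest)
  .fixture_env$waves16
}

# Random binary codes as bit-strings.
random_codes <- function(n, bits = 21) {
  vapply(seq_len(n), function(i)
    paste(sample(0:1, bits, replace = TRUE), collapse = ""), "")
}

# A valid random posterior stream.
random_stream <- function(frames = 50, seed = 1) {
  set.seed(seed)
  posterior_stream(matrix(runif(frames * 21), frames, 21))
}

# Small CRNN configuration used across network tests.
tiny_crnn_config <- function(epochs = 3, ...) {
  crnn_config(conv_filters = 24, recurrent_units = 12, dropout_rate = 0.2,
              epochs = epochs, batch_size = 16, ...)
}
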