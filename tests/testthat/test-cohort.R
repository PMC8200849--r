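# Synthetic cohort generator: contracts, determinism, and the statistical
# structure the classifiers rely on.

test_that("attribute inventory has 21 unique names including the core set", {
  attrs <- pd_attributes()
  expect_length(attrs, 21)
  expect_false(anyDuplicated(attrs) > 0)
  core <- c("silence", "continuant", "tense", "voiced", "fricative",
            "retroflex", "velar", "high", "coronal", "mid", "back",
            "vocalic", "anterior", "labial")
  expect_true(all(core %in% attrs))
})

test_that("phone map vectors are 21-bit and silence is silence-only", {
  m <- phone_attribute_map()
  expect_true(all(vapply(m$phones, length, 1L) == 21))
  expect_true(all(unlist(m$phones) %in% 0:1))
  sil <- m$phones$sil
  expect_equal(sum(sil), 1)
  expect_equal(m$attributes[sil == 1], "silence")
  # every template phone is in the map
  tpl_phones <- unique(unlist(protocol_templates()))
  expect_true(all(tpl_phones %in% names(m$phones)))
})

test_that("manifest enumerates patient x protocol x state and is reproducible", {
  cfg <- cohort_config(n_patients = 3, protocols = c("pataka", "vowels"),
                       seed = 11L)
  d1 <- withr::local_tempdir()
  r1 <- generate_cohort(cfg, d1, components = "posteriors")
  expect_equal(nrow(r1$manifest), 3 * 2 * 2)
  expect_true(all(file.exists(r1$manifest$posteriors)))
  d2 <- withr::local_tempdir()
  r2 <- generate_cohort(cfg, d2, components = "posteriors")
  for (i in seq_len(nrow(r1$manifest)))
    expect_identical(readLines(r1$manifest$posteriors[i]),
                     readLines(r2$manifest$posteriors[i]))
  expect_error(cohort_config(protocols = "humming"), "unknown protocol")
  expect_error(cohort_config(n_patients = 1), "n_patients")
})

test_that("zero-noise ON streams are exactly the canonical phone vectors", {
  cfg <- cohort_config(noise_scale = 0, slip_delete = 0)
  s <- synthesize_posteriors("pataka", "ON", 1, cfg, seed = 3)
  m <- phone_attribute_map()
  expect_true(all(s$posteriors %in% c(0, 1)))
  canonical <- vapply(m$phones, paste, "", collapse = "")
  frame_codes <- apply(s$posteriors, 1, paste, collapse = "")
  expect_true(all(frame_codes %in% canonical))
})

test_that("full weakening suppresses all canonically active attributes", {
  cfg <- cohort_config(dropout_prob_off = 1, silence_boost_off = 0,
                       noise_scale = 0, slip_delete = 0,
                       substitution_frac = 0)
  on <- synthesize_posteriors("pataka", "ON", 1, cfg, seed = 9)
  off <- synthesize_posteriors("pataka", "OFF", 1, cfg, seed = 9)
  m <- phone_attribute_map()
  non_sil <- m$attributes != "silence"
  expect_true(all(off$posteriors[, non_sil] < 0.5))
  bits <- function(s) mean(rowSums(s$posteriors >= 0.5))
  expect_lt(bits(off), bits(on))
})

test_that("OFF streams are sparser than ON whenever weakening is active", {
  cfg <- cohort_config()
  for (seed in 1:3) {
    on <- synthesize_posteriors("months", "ON", 1, cfg, seed = seed)
    off <- synthesize_posteriors("months", "OFF", 1, cfg, seed = seed + 100)
    bits <- function(s) mean(rowSums(s$posteriors >= 0.5))
    expect_lt(bits(off), bits(on))
  }
})

test_that("pataka streams vary in silence, continuant, tense and voiced", {
  s <- synthesize_posteriors("pataka", "ON", 1, cohort_config(), seed = 5)
  for (a in c("silence", "continuant", "tense", "voiced"))
    expect_gt(stats::sd(s$posteriors[, a]), 0.05)
})

test_that("posterior values stay in [0, 1] across states and effects", {
  cfg <- cohort_config()
  for (st in c("ON", "OFF")) {
    s <- synthesize_posteriors("twisters", st, 1.5, cfg, seed = 7)
    expect_gte(min(s$posteriors), 0)
    expect_lte(max(s$posteriors), 1)
  }
})

test_that("synthesized audio meets the acquisition contract", {
  w <- synthesize_audio("vowels", "ON", 1, cohort_config(), seed = 2)
  expect_equal(w$rate, 44100)
  expect_gte(length(w$samples) / w$rate, 10)
  expect_true(all(abs(w$samples) <= 1))
})

test_that("a 6 dB OFF gain reduction halves the RMS", {
  cfg <- cohort_config(gain_db_off = 6, aspiration_off = 0, jitter_off = 0,
                       rate_factor_off = 1)
  rms <- function(w) sqrt(mean(w$samples^2))
  ratios <- vapply(1:4, function(s) {
    on <- synthesize_audio("vowels", "ON", 1, cfg, seed = s)
    off <- synthesize_audio("vowels", "OFF", 1, cfg, seed = s)
    rms(off) / rms(on)
  }, 1)
  expect_true(all(abs(ratios - 10^(-6 / 20)) < 0.05))
})

test_that("zero patient effect makes ON and OFF audio indistinguishable in level", {
  cfg <- cohort_config()
  rms <- function(w) sqrt(mean(w$samples^2))
  on <- vapply(1:5, function(s) rms(synthesize_audio("pataka", "ON", 0, cfg, seed = s)), 1)
  off <- vapply(1:5, function(s) rms(synthesize_audio("pataka", "OFF", 0, cfg, seed = s + 50)), 1)
  expect_lt(abs(mean(on) - mean(off)) / mean(on), 0.05)
})

test_that("clinical-style scores increase with the injected effect multiplier", {
  res <- small_pac_cohort()
  delta <- res$scores[["III Total OFF"]] - res$scores[["III Total ON"]]
  expect_true(all(delta > 0))
  expect_gt(stats::cor(delta, rowMeans(res$effects)), 0)
})

test_that("posterior CSV round-trips and rejects malformed files", {
  s <- random_stream(40, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_posteriors(s, path)
  s2 <- read_posteriors(path)
  expect_equal(s2$posteriors, s$posteriors, tolerance = 1e-6,
               ignore_attr = TRUE)
  # drop one column -> error naming the missing attribute
  df <- utils::read.csv(path, check.names = FALSE)
  p20 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df[, -3], p20, row.names = FALSE)
  expect_error(read_posteriors(p20), colnames(df)[3])
  # out-of-range value -> error citing the row
  df2 <- df; df2[7, 2] <- 1.2
  pbad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df2, pbad, row.names = FALSE)
  expect_error(read_posteriors(pbad), "row 7")
})
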