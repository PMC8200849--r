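# Synthetic Parkinsonian speech cohort generator.
#
# Emulates the statistical structure the ON/OFF classifiers assume: for each
# patient x speech protocol x motor state the generator produces (a) a
# phonological posterior stream and (b) a mono 44.1-kHz waveform, plus a
# cohort manifest and a clinical-style severity score table.  The OFF state
# degrades speech the way hypokinetic dysarthria does: articulation becomes
# consistently imprecise (per patient x protocol, a random subset of
# attributes is weakened throughout, often substituting a confusable
# attribute — slurring), attributes additionally drop out frame-wise,
# silence intrudes (hesitation), speech is time-compressed (festination),
# the signal is softer (hypophonia) and noisier (hoarseness).  Per-patient
# x protocol effect multipliers make protocols differ in how informative
# they are for a given patient.  The consistency of the weakening is what
# gives each state class-exclusive quantized codes (the premise of the
# codebook classifier); purely frame-independent corruption would let every
# near-canonical code eventually appear in both classes of a large
# training pool.

#' Cohort generator configuration
#'
#' All OFF-state corruption magnitudes are scaled per patient x protocol by
#' an effect multiplier (see `patient_heterogeneity`, `heterogeneity_mode`);
#' setting every effect to zero yields a null cohort in which ON and OFF are
#' draws from the same distribution.
#'
#' @param n_patients number of patients (>= 2).
#' @param protocols subset of [pd_protocols()].
#' @param effect_sizes named numeric vector of ON-minus-OFF posterior
#'   offsets in \[-1, 1\] (names among [pd_attributes()]); attributes not
#'   named get offset 0.
#' @param dropout_prob_off probability (per patient x protocol x attribute,
#'   scaled by the effect multiplier) that a canonically active attribute
#'   is consistently suppressed in OFF speech.
#' @param frame_dropout_off additional per-frame probability that an
#'   active attribute drops out in an OFF frame (frame-wise imprecision).
#' @param substitution_frac probability that a weakened attribute's frames
#'   activate its confusion partner instead (slurred substitution).
#' @param slip_delete state-independent per-frame probability that an
#'   active attribute is momentarily under-articulated (both states; this
#'   is the articulatory variability that keeps a null cohort's codebooks
#'   non-degenerate).
#' @param silence_boost_off per-frame probability that an OFF frame is
#'   replaced by a silence frame.
#' @param rate_factor_off duration multiplier for OFF speech (< 1 models
#'   the hastened, festinating speech typical of the OFF state).
#' @param patient_heterogeneity sdlog of the per-patient x protocol
#'   log-normal effect multipliers.
#' @param heterogeneity_mode `"lognormal"` (default) or `"single-protocol"`
#'   (exactly one informative protocol per patient, the rest null).
#' @param noise_scale amplitude of the logistic-squashed Gaussian posterior
#'   perturbation (0 = noise-free canonical vectors).
#' @param noise_sd,noise_ar standard deviation and AR(1) coefficient of the
#'   underlying Gaussian noise process.
#' @param frame_period posterior frame period in seconds.
#' @param protocol_weights named informativeness weights per protocol
#'   (weakly informative read/monologue analogs by default).
#' @param durations named target recording durations in seconds (each
#'   >= 10 s after rate scaling).
#' @param gain_db_off OFF loudness reduction in dB (hypophonia).
#' @param aspiration_off amplitude of added OFF aspiration noise.
#' @param jitter_off extra OFF pitch jitter (relative f0 sd).
#' @param f0 base fundamental frequency in Hz.
#' @param sample_rate audio sampling rate in Hz.
#' @param seed integer seed; generation is a pure function of (config, seed).
#' @return A validated `cohort_config` object.
#' @export
cohort_config <- function(n_patients = 14,
                          protocols = pd_protocols(),
                          effect_sizes = c(fricative = 0.12, continuant = 0.10,
                                           tense = 0.08, voiced = 0.08),
                          dropout_prob_off = 0.5,
                          frame_dropout_off = 0.08,
                          substitution_frac = 0.6,
                          slip_delete = 0.03,
                          silence_boost_off = 0.12,
                          rate_factor_off = 0.9,
                          patient_heterogeneity = 0.5,
                          heterogeneity_mode = c("lognormal", "single-protocol"),
                          noise_scale = 0.15,
                          noise_sd = 1.0,
                          noise_ar = 0.9,
                          frame_period = 0.01,
                          protocol_weights = c(digits = 1, months = 1,
                                               vowels = 1.2, pataka = 1.3,
                                               twisters = 1.1, read = 0.45,
                                               monologue = 0.35),
                          durations = c(digits = 12, months = 14,
                                        vowels = 10.5, pataka = 10.5,
                                        twisters = 12, read = 16,
                                        monologue = 20),
                          gain_db_off = 6,
                          aspiration_off = 0.05,
                          jitter_off = 0.02,
                          f0 = 120,
                          sample_rate = 44100,
                          seed = 1L) {
  heterogeneity_mode <- match.arg(heterogeneity_mode)
  if (!is_count(n_patients) || n_patients < 2) stopf("n_patients must be >= 2")
  bad <- setdiff(protocols, pd_protocols())
  if (length(bad)) stopf("unknown protocol(s): %s", paste(bad, collapse = ", "))
  attrs <- pd_attributes()
  es <- stats::setNames(numeric(length(attrs)), attrs)
  if (length(effect_sizes)) {
    bad <- setdiff(names(effect_sizes), attrs)
    if (length(bad)) stopf("effect_sizes name(s) not attributes: %s",
                           paste(bad, collapse = ", "))
    es[names(effect_sizes)] <- effect_sizes
  }
  if (any(abs(es) > 1)) stopf("effect_sizes must lie in [-1, 1]")
  for (p in c(dropout_prob_off, frame_dropout_off, substitution_frac,
              slip_delete, silence_boost_off))
    if (p < 0 || p > 1) stopf("probabilities must lie in [0, 1]")
  if (rate_factor_off <= 0) stopf("rate_factor_off must be > 0")
  cfg <- list(n_patients = as.integer(n_patients), protocols = protocols,
              effect_sizes = es, dropout_prob_off = dropout_prob_off,
              frame_dropout_off = frame_dropout_off,
              substitution_frac = substitution_frac,
              slip_delete = slip_delete,
              silence_boost_off = silence_boost_off,
              rate_factor_off = rate_factor_off,
              patient_heterogeneity = patient_heterogeneity,
              heterogeneity_mode = heterogeneity_mode,
              noise_scale = noise_scale, noise_sd = noise_sd,
              noise_ar = noise_ar, frame_period = frame_period,
              protocol_weights = protocol_weights, durations = durations,
              gain_db_off = gain_db_off, aspiration_off = aspiration_off,
              jitter_off = jitter_off, f0 = f0, sample_rate = sample_rate,
              seed = as.integer(seed))
  structure(cfg, class = "cohort_config")
}

#' Null cohort configuration (all state effects zeroed)
#'
#' Convenience wrapper for chance-level controls: ON and OFF become draws
#' from the same distribution.
#'
#' @param ... overrides passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
null_cohort_config <- function(...) {
  cohort_config(effect_sizes = numeric(0), dropout_prob_off = 0,
                frame_dropout_off = 0, silence_boost_off = 0,
                rate_factor_off = 1, gain_db_off = 0, aspiration_off = 0,
                jitter_off = 0, patient_heterogeneity = 0, ...)
}

# Frame-wise phone sequence for one recording: template repeated until the
# (rate-scaled) duration reaches the protocol target.
phone_frame_sequence <- function(protocol, rate, config) {
  tpl <- protocol_templates()[[protocol]]
  if (is.null(tpl)) stopf("unknown protocol: %s", protocol)
  target_frames <- ceiling(max(10, config$durations[[protocol]]) /
                           config$frame_period)
  durs <- pmax(2L, as.integer(round(vapply(tpl, phone_base_frames, 1L) * rate)))
  reps <- ceiling(target_frames / sum(durs))
  phones <- rep(rep(tpl, durs), reps)
  phones[seq_len(max(target_frames, sum(durs)))]
}

# Effective time-stretch: OFF-state rate deviation scaled by the patient
# effect so a zero-effect patient is indistinguishable from ON.
effective_rate <- function(state, patient_effect, config) {
  if (identical(state, "OFF")) 1 + (config$rate_factor_off - 1) * patient_effect
  else 1
}

#' Synthesize a phonological posterior stream
#'
#' Each frame is the canonical binary attribute vector of the current phone
#' plus a smooth logistic-squashed Gaussian perturbation; both states carry
#' a small state-independent articulation-slip rate.  OFF streams
#' additionally (i) weaken a consistent per-stream random subset of
#' attributes (probability `dropout_prob_off * patient_effect` each),
#' frequently substituting the attribute's confusion partner (slurring),
#' (ii) drop active attributes frame-wise with probability
#' `frame_dropout_off * patient_effect`, (iii) replace frames with silence
#' with probability `silence_boost_off * patient_effect`, (iv) subtract the
#' configured ON-OFF attribute offsets, and (v) are time-compressed by the
#' effective rate factor.
#'
#' @param protocol protocol name.
#' @param state `"ON"` or `"OFF"`.
#' @param patient_effect non-negative effect multiplier for this
#'   patient x protocol.
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @param map a [phone_attribute_map()].
#' @return A [posterior_stream()].
#' @export
synthesize_posteriors <- function(protocol, state = c("ON", "OFF"),
                                  patient_effect = 1,
                                  config = cohort_config(),
                                  seed = config$seed,
                                  map = phone_attribute_map()) {
  state <- match.arg(state)
  rate <- effective_rate(state, patient_effect, config)
  phones <- phone_frame_sequence(protocol, rate, config)
  unknown <- setdiff(unique(phones), names(map$phones))
  if (length(unknown)) stopf("phone(s) not in attribute map: %s",
                             paste(unknown, collapse = ", "))
  n <- length(phones)
  k <- length(map$attributes)
  confusion <- attribute_confusion_map()
  with_seed(seed, {
    B <- do.call(rbind, map$phones[phones])
    storage.mode(B) <- "double"
    P <- B
    sil_col <- map$attributes == "silence"
    if (state == "OFF" && patient_effect > 0) {
      p_sil <- min(1, config$silence_boost_off * patient_effect)
      if (p_sil > 0) {
        sil_rows <- stats::runif(n) < p_sil
        P[sil_rows, ] <- rep(as.numeric(map$phones$sil), each = sum(sil_rows))
      }
      # consistent weakening: a per-stream random attribute subset is
      # misarticulated throughout, often activating its confusion partner
      q <- min(1, config$dropout_prob_off * patient_effect)
      weakened <- !sil_col & stats::runif(k) < q
      for (j in which(weakened)) {
        act <- B[, j] == 1 & P[, j] > 0.5        # skip silence-replaced rows
        if (!any(act)) next
        P[act, j] <- 0.2
        partner <- confusion[[map$attributes[j]]]
        if (!is.null(partner) && !is.na(partner)) {
          pj <- which(map$attributes == partner)
          sub <- act & stats::runif(n) < config$substitution_frac
          P[sub, pj] <- pmax(P[sub, pj], 0.9)
        }
      }
      # frame-wise dropout on the remaining active attributes
      p_drop <- min(1, config$frame_dropout_off * patient_effect)
      if (p_drop > 0) {
        active <- P > 0.5 & B == 1
        active[, sil_col] <- FALSE
        drop <- active & matrix(stats::runif(n * k) < p_drop, n, k)
        P[drop] <- 0
      }
    }
    # state-independent articulation slips (momentary under-articulation)
    if (config$slip_delete > 0) {
      active <- P > 0.5 & B == 1
      active[, sil_col] <- FALSE
      slip <- active & matrix(stats::runif(n * k) < config$slip_delete, n, k)
      P[slip] <- 0.1
    }
    if (config$noise_scale > 0) {
      eps <- matrix(stats::rnorm(n * k), n, k)
      if (config$noise_ar > 0 && n > 1) {
        phi <- config$noise_ar
        for (t in 2:n) eps[t, ] <- phi * eps[t - 1, ] +
            sqrt(1 - phi^2) * eps[t, ]
      }
      squash <- 2 * stats::plogis(config$noise_sd * eps) - 1
      P <- P + config$noise_scale * squash
    }
    if (state == "OFF" && patient_effect > 0)
      P <- sweep(P, 2, config$effect_sizes * patient_effect, "-")
    posterior_stream(clamp01(P), map$attributes,
                     frame_period = config$frame_period,
                     provenance = "synthetic")
  })
}

# -- audio synthesis -------------------------------------------------------

vowel_formants <- list(
  a = c(730, 1090, 2440), e = c(530, 1840, 2480), i = c(270, 2290, 3010),
  o = c(570, 840, 2410), u = c(300, 870, 2240))

phone_sound_class <- function(phone) {
  if (phone == "sil") "sil"
  else if (phone %in% names(vowel_formants)) "vowel"
  else if (phone %in% c("s", "z", "S", "f", "v", "h")) "fricative"
  else if (phone %in% c("m", "n", "l", "r", "w", "j")) "sonorant"
  else "stop"
}

# Resonance magnitude of a harmonic at frequency f given formants (simple
# sum of Lorentzian peaks with a -6 dB/oct source tilt).
formant_gain <- function(f, formants, bw = c(90, 110, 170)) {
  g <- 0
  for (j in seq_along(formants))
    g <- g + 1 / sqrt(1 + ((f - formants[j]) / bw[j])^2)
  g * (200 / (f + 200))
}

#' Synthesize a speech-like waveform for one recording
#'
#' Vowels and sonorants are a jittered harmonic source shaped by formant
#' resonances; fricatives are spectrally shaped noise; stops are a closure
#' gap plus a burst.  The OFF state applies gain reduction (hypophonia),
#' added aspiration noise (hoarseness), extra pitch jitter, and time
#' compression, each scaled by `patient_effect`.
#'
#' @inheritParams synthesize_posteriors
#' @return A [waveform()] at `config$sample_rate` (>= 10 s, samples in
#'   \[-1, 1\]).
#' @export
synthesize_audio <- function(protocol, state = c("ON", "OFF"),
                             patient_effect = 1, config = cohort_config(),
                             seed = config$seed) {
  state <- match.arg(state)
  rate <- effective_rate(state, patient_effect, config)
  phones <- phone_frame_sequence(protocol, rate, config)
  fs <- config$sample_rate
  spf <- round(config$frame_period * fs)       # samples per frame
  runs <- rle(phones)
  seg_len <- runs$lengths * spf
  n <- sum(seg_len)
  t_all <- seq_len(n) / fs
  with_seed(seed, {
    off <- state == "OFF"
    jit_sd <- 0.004 + if (off) config$jitter_off * patient_effect else 0
    jit <- stats::rnorm(length(runs$values))            # per-segment jitter
    f0_seg <- config$f0 * (1 + jit_sd * jit)
    f0_track <- rep(f0_seg, seg_len) * (1 + 0.01 * sin(2 * pi * 5 * t_all))
    phase <- cumsum(2 * pi * f0_track / fs)
    classes <- vapply(runs$values, phone_sound_class, "")
    x <- numeric(n)
    # harmonic (voiced) part: per-harmonic amplitude looked up from a
    # phone x harmonic table evaluated at the nominal f0
    n_harm <- 14L
    voiced_phones <- unique(runs$values[classes %in% c("vowel", "sonorant")])
    if (length(voiced_phones)) {
      amp_tab <- vapply(voiced_phones, function(ph) {
        fm <- if (!is.null(vowel_formants[[ph]])) vowel_formants[[ph]]
              else c(280, 1250, 2200)
        gain <- if (!is.null(vowel_formants[[ph]])) 1 else 0.45
        vapply(seq_len(n_harm) * config$f0, formant_gain, 1, formants = fm) * gain
      }, numeric(n_harm))                       # n_harm x phones
      seg_col <- match(runs$values, voiced_phones)  # NA for unvoiced
      for (kh in seq_len(n_harm)) {
        amp_seg <- ifelse(is.na(seg_col), 0, amp_tab[kh, seg_col])
        if (all(amp_seg == 0)) next
        x <- x + rep(amp_seg, seg_len) * sin(kh * phase)
      }
    }
    # noise part
    noise <- stats::rnorm(n)
    hp <- c(0, diff(noise))                              # high-pass shaped
    namp <- numeric(length(runs$values))
    namp[classes == "fricative"] <- 0.5
    namp[classes == "sil"] <- 0.002
    x <- x + rep(namp, seg_len) *
      ifelse(rep(runs$values %in% c("s", "z", "S"), seg_len), hp, noise) * 0.5
    # stops: closure (silence) then a short burst
    for (si in which(classes == "stop")) {
      i0 <- sum(seg_len[seq_len(si - 1)])
      len <- seg_len[si]
      closure <- floor(len * 0.6)
      x[i0 + seq_len(closure)] <- 0
      burst <- len - closure
      x[i0 + closure + seq_len(burst)] <-
        stats::rnorm(burst) * 0.4 * exp(-seq_len(burst) / (burst / 3))
    }
    peak <- max(abs(x))
    if (peak > 0) x <- x / peak * 0.35
    if (off && patient_effect > 0) {
      x <- x * 10^(-(config$gain_db_off * patient_effect) / 20)
      if (config$aspiration_off > 0)
        x <- x + stats::rnorm(n) * config$aspiration_off * patient_effect * 0.1
    }
    waveform(pmax(-1, pmin(1, x)), fs, "float32")
  })
}

# Per-patient x protocol effect multipliers.
effect_multipliers <- function(config) {
  np <- config$n_patients
  prot <- config$protocols
  with_seed(mix_seed(config$seed, 777L), {
    sev <- exp(stats::rnorm(np, 0, 0.3))                  # patient severity
    if (config$heterogeneity_mode == "single-protocol") {
      m <- matrix(0, np, length(prot), dimnames = list(NULL, prot))
      pick <- sample(seq_along(prot), np, replace = TRUE)
      for (i in seq_len(np)) m[i, pick[i]] <- 1.4 * sev[i]
    } else {
      z <- matrix(stats::rnorm(np * length(prot)), np, length(prot))
      w <- config$protocol_weights[prot]
      m <- sev * exp(config$patient_heterogeneity * z -
                     config$patient_heterogeneity^2 / 2)
      m <- sweep(m, 2, as.numeric(w), "*")
      dimnames(m) <- list(NULL, prot)
    }
    list(multipliers = m, severity = sev)
  })
}

# Clinical-style severity table: OFF-ON motor score difference increases
# monotonically with the patient's mean injected effect multiplier.
clinical_score_table <- function(config, eff) {
  np <- config$n_patients
  with_seed(mix_seed(config$seed, 778L), {
    mbar <- rowMeans(eff$multipliers)
    rel <- if (max(mbar) > 0) mbar / max(mbar) else rep(0, np)
    age <- pmin(85, pmax(45, round(stats::rnorm(np, 66, 7))))
    gender <- sample(c("F", "M"), np, replace = TRUE, prob = c(0.6, 0.4))
    on_total <- pmax(2, round(stats::rnorm(np, 21, 11)))
    delta <- pmax(1, round(5 + 14 * rel))
    off_total <- on_total + delta
    speech_on <- pmin(4, pmax(0, round(on_total / 14)))
    speech_off <- pmin(4, pmax(0, round(off_total / 13)))
    df <- data.frame(ID = seq_len(np), Gender = gender, Age = age,
                     check.names = FALSE)
    df[["III Total ON"]] <- on_total
    df[["III Total OFF"]] <- off_total
    df[["III.I ON"]] <- speech_on
    df[["III.I OFF"]] <- speech_off
    df
  })
}

#' Generate a synthetic patient cohort on disk
#'
#' For each patient x protocol x state writes one posterior-stream CSV and
#' (optionally) one WAV file, plus `manifest.csv` and a clinical-style
#' `clinical_scores.csv`.  Generation is bit-reproducible given the config
#' seed.
#'
#' @param config a [cohort_config()].
#' @param dir output directory (created if needed).
#' @param components subset of `c("posteriors", "audio")`; generating audio
#'   for large cohorts is the expensive part and may be skipped when only
#'   the codebook pipeline is exercised.
#' @return Invisibly, a list with `manifest` (data frame: patient_id, state,
#'   protocol, session, path, posteriors), `scores`, and the injected
#'   `effects` multiplier matrix.
#' @export
generate_cohort <- function(config, dir,
                            components = c("posteriors", "audio")) {
  stopifnot(inherits(config, "cohort_config"))
  components <- match.arg(components, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stopf("cannot create output directory %s", dir)
  eff <- effect_multipliers(config)
  map <- phone_attribute_map()
  rows <- list()
  for (i in seq_len(config$n_patients)) {
    for (pi in seq_along(config$protocols)) {
      prot <- config$protocols[pi]
      pe <- eff$multipliers[i, prot]
      for (st in c("ON", "OFF")) {
        stem <- sprintf("p%02d_%s_%s", i, prot, st)
        csv <- file.path(dir, paste0(stem, ".csv"))
        wav <- file.path(dir, paste0(stem, ".wav"))
        si <- if (st == "ON") 1L else 2L
        if ("posteriors" %in% components) {
          ps <- synthesize_posteriors(prot, st, pe, config,
                                      seed = mix_seed(config$seed, i, pi, si, 1L),
                                      map = map)
          write_posteriors(ps, csv)
        }
        if ("audio" %in% components) {
          wv <- synthesize_audio(prot, st, pe, config,
                                 seed = mix_seed(config$seed, i, pi, si, 2L))
          write_wav(wv$samples, wav, wv$rate, "float32")
        }
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = i, state = st, protocol = prot, session = 1L,
          path = if ("audio" %in% components) wav else NA_character_,
          posteriors = if ("posteriors" %in% components) csv else NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  scores <- clinical_score_table(config, eff)
  utils::write.csv(scores, file.path(dir, "clinical_scores.csv"),
                   row.names = FALSE)
  invisible(list(manifest = manifest, scores = scores,
                 effects = eff$multipliers))
}

#' Read a cohort manifest
#'
#' @param path path to a `manifest.csv` written by [generate_cohort()].
#' @return The manifest data frame.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "state", "protocol", "session")
  missing <- setdiff(need, names(df))
  if (length(missing)) stopf("manifest missing column(s): %s",
                             paste(missing, collapse = ", "))
  df
}
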