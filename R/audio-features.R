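# Audio ingestion and time-frequency feature extraction.
#
# Analysis convention: recordings are downsampled to 16 kHz / 16-bit, cut
# into 10-s segments, and transformed with a complex STFT using a 25-ms
# window and 7.5-ms overlap (hop 17.5 ms) over 201 one-sided frequency
# bins, so a 10-s segment yields a 201 x 571 magnitude matrix.  Frame count
# follows the no-padding convention floor((N - win) / hop) + 1, which is
# the only reading that reproduces 571 frames.

#' Spectrogram analysis parameters
#'
#' @param window_ms analysis window length in ms.
#' @param overlap_ms overlap between adjacent windows in ms (hop =
#'   window - overlap).
#' @param rate analysis sampling rate in Hz.
#' @param window window function, `"hamming"` (default) or `"rect"`.
#' @return List of STFT parameters.
#' @export
stft_params <- function(window_ms = 25, overlap_ms = 7.5, rate = 16000,
                        window = c("hamming", "rect")) {
  window <- match.arg(window)
  win <- round(window_ms * rate / 1000)
  hop <- round((window_ms - overlap_ms) * rate / 1000)
  list(window_ms = window_ms, overlap_ms = overlap_ms, rate = rate,
       win = win, hop = hop, n_bins = win %/% 2 + 1, window = window)
}

#' Downsample to 16 kHz and quantize to 16 bits
#'
#' FFT-domain sinc resampling: the spectrum is truncated at the target
#' Nyquist frequency before reconstruction at the new rate, which applies
#' ideal anti-aliasing.  Samples are then round-tripped through 16-bit
#' integer quantization.
#'
#' @param w a [waveform()] with rate >= 16 kHz.
#' @param rate target rate (default 16000 Hz).
#' @return A [waveform()] at `rate` with `bit_depth = "pcm16"`.
#' @export
resample_and_quantize <- function(w, rate = 16000) {
  stopifnot(inherits(w, "waveform"))
  if (w$rate < rate)
    stopf("input rate %g Hz below target %g Hz: upsampling unsupported",
          w$rate, rate)
  x <- w$samples
  n <- length(x)
  if (w$rate == rate) {
    y <- x
  } else {
    m <- floor(n * rate / w$rate)
    X <- stats::fft(x)
    # keep only bins below the target Nyquist; rebuild a Hermitian spectrum
    keep <- m %/% 2                       # positive-frequency bins retained
    Y <- complex(m)
    Y[1] <- X[1]
    if (keep >= 1) {
      Y[2:(keep + 1)] <- X[2:(keep + 1)]
      Y[m - (1:keep) + 1] <- Conj(X[2:(keep + 1)])
    }
    if (m %% 2 == 0) Y[keep + 1] <- Re(X[keep + 1])  # real Nyquist bin
    y <- Re(stats::fft(Y, inverse = TRUE)) / n
  }
  q <- pmax(-32768, pmin(32767, round(y * 32767))) / 32767
  waveform(q, rate, "pcm16")
}

#' Concatenate same-state recordings and cut into 10-s training segments
#'
#' All recordings with the same motor state are concatenated in manifest
#' order and cut into non-overlapping 10-s segments; a final remainder
#' shorter than 10 s is dropped.  Testing recordings are never combined
#' this way (utterance-level evaluation).
#'
#' @param waves list of [waveform()]s at 16 kHz, all of one state.
#' @param state the common state label, attached to each segment.
#' @param segment_s segment length in seconds.
#' @return List of `waveform` segments, each with attribute `"state"`.
#' @export
chunk_training_audio <- function(waves, state, segment_s = 10) {
  if (!length(waves)) return(list())
  rates <- vapply(waves, function(w) w$rate, 1)
  if (length(unique(rates)) != 1L)
    stopf("all recordings must share one rate (got %s)",
          paste(unique(rates), collapse = ", "))
  fs <- rates[1]
  x <- unlist(lapply(waves, function(w) w$samples), use.names = FALSE)
  seg_n <- round(segment_s * fs)
  k <- length(x) %/% seg_n
  lapply(seq_len(k), function(i) {
    s <- waveform(x[((i - 1) * seg_n + 1):(i * seg_n)], fs, waves[[1]]$bit_depth)
    attr(s, "state") <- state
    s
  })
}

#' Split a 10-s segment into validation and test halves
#'
#' The first 5 s serve as validation material, the last 5 s as test
#' material.
#'
#' @param segment a [waveform()] of exactly 10 s.
#' @return List with `validation` and `test` waveforms (5 s each).
#' @export
split_test_segment <- function(segment) {
  stopifnot(inherits(segment, "waveform"))
  n <- length(segment$samples)
  if (n != round(10 * segment$rate))
    stopf("segment must be exactly 10 s (got %.3f s)", n / segment$rate)
  h <- n %/% 2
  list(validation = waveform(segment$samples[1:h], segment$rate,
                             segment$bit_depth),
       test = waveform(segment$samples[(h + 1):n], segment$rate,
                       segment$bit_depth))
}

#' Extend a short segment to a target length by repetition
#'
#' Model inputs are fixed at 10 s; shorter segments (e.g. the 5-s halves)
#' are tiled until they reach the required length.
#'
#' @param w a [waveform()].
#' @param target_s target duration in seconds.
#' @return A [waveform()] of exactly `target_s` seconds.
#' @export
extend_by_repetition <- function(w, target_s = 10) {
  n_target <- round(target_s * w$rate)
  x <- rep(w$samples, length.out = n_target)
  waveform(x, w$rate, w$bit_depth)
}

#' Compute the STFT magnitude spectrogram
#'
#' @param segment a [waveform()] at the analysis rate.
#' @param params [stft_params()].
#' @return A `spectrogram` object: list with `magnitude`
#'   (n_bins x n_frames), `params`, and `normalized = FALSE`. For a 10-s
#'   16-kHz segment under default parameters the magnitude is 201 x 571.
#' @export
compute_spectrogram <- function(segment, params = stft_params()) {
  stopifnot(inherits(segment, "waveform"))
  if (segment$rate != params$rate)
    stopf("segment rate %g differs from analysis rate %g",
          segment$rate, params$rate)
  x <- segment$samples
  win <- params$win; hop <- params$hop
  if (length(x) < win) stopf("segment shorter than one analysis window")
  n_frames <- (length(x) - win) %/% hop + 1L
  idx <- outer(seq_len(win), (seq_len(n_frames) - 1L) * hop, "+")
  frames <- matrix(x[idx], nrow = win)
  wfun <- if (params$window == "hamming")
    0.54 - 0.46 * cos(2 * pi * (seq_len(win) - 1) / (win - 1)) else rep(1, win)
  S <- stats::mvfft(frames * wfun)
  mag <- Mod(S[seq_len(params$n_bins), , drop = FALSE])
  structure(list(magnitude = mag, params = params, normalized = FALSE),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d bins x %d frames%s\n", nrow(x$magnitude),
              ncol(x$magnitude), if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Fit per-frequency-channel normalization statistics
#'
#' Mean and standard deviation of each frequency channel estimated over the
#' pooled frames of the training spectrograms only (cross-validation
#' hygiene: never fit on held-out patients).  Zero-variance channels are
#' floored at `1e-8` with a warning.
#'
#' @param spectrograms list of training `spectrogram`s.
#' @param provenance free-form tag recording which fold/patients the stats
#'   were fitted on.
#' @return A `norm_stats` object with `mean`, `sd`, `provenance`.
#' @export
fit_normalizer <- function(spectrograms, provenance = "training") {
  if (!length(spectrograms)) stopf("need at least one training spectrogram")
  M <- do.call(cbind, lapply(spectrograms, function(s) s$magnitude))
  mu <- rowMeans(M)
  sd <- sqrt(rowMeans((M - mu)^2) * ncol(M) / max(1, ncol(M) - 1))
  if (any(sd < 1e-8)) {
    warning("zero-variance frequency channel(s); sd floored at 1e-8")
    sd <- pmax(sd, 1e-8)
  }
  structure(list(mean = mu, sd = sd, provenance = provenance),
            class = "norm_stats")
}

#' Apply channel normalization to a spectrogram
#'
#' @param s a `spectrogram`.
#' @param stats a `norm_stats` from [fit_normalizer()].
#' @return The z-scored `spectrogram` (`normalized = TRUE`).
#' @export
apply_normalizer <- function(s, stats) {
  stopifnot(inherits(s, "spectrogram"), inherits(stats, "norm_stats"))
  s$magnitude <- (s$magnitude - stats$mean) / stats$sd
  s$normalized <- TRUE
  s
}
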