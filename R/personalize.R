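# Personalized protocol selection (p-CRNN).
#
# The classifier stays speaker-independent; personalization only chooses,
# per patient, which speech protocols are used at test time.  Each 10-s
# test segment is split into a 5-s validation half and a 5-s test half;
# a protocol is selected iff its validation predictions are correct for
# both the ON and the OFF state.

#' Split a patient's recordings into validation and test portions
#'
#' Applies the deterministic 5 s / 5 s rule to every 10-s segment of every
#' protocol x state recording.  Protocols missing one state are excluded
#' with a warning.
#'
#' @param manifest_rows manifest rows of one patient.
#' @param waves list of 16-kHz [waveform()]s parallel to `manifest_rows`.
#' @return Named list per protocol: for each state, lists of `validation`
#'   and `test` 5-s halves.
#' @export
split_patient_recordings <- function(manifest_rows, waves) {
  stopifnot(nrow(manifest_rows) == length(waves))
  out <- list()
  for (prot in unique(manifest_rows$protocol)) {
    idx <- which(manifest_rows$protocol == prot)
    states <- manifest_rows$state[idx]
    if (!all(c("ON", "OFF") %in% states)) {
      warning(sprintf("protocol %s lacks one state; excluded", prot))
      next
    }
    per_state <- list()
    for (st in c("ON", "OFF")) {
      halves <- list(validation = list(), test = list())
      for (i in idx[states == st]) {
        segs <- chunk_utterance(waves[[i]])
        for (s in segs) {
          sp <- split_test_segment(s)
          halves$validation <- c(halves$validation, list(sp$validation))
          halves$test <- c(halves$test, list(sp$test))
        }
      }
      per_state[[st]] <- halves
    }
    out[[prot]] <- per_state
  }
  out
}

# Cut one test recording into 10-s segments (utterance-level: recordings
# are never concatenated across utterances).  A recording shorter than
# 10 s is extended by repetition into a single segment.
chunk_utterance <- function(w, segment_s = 10) {
  seg_n <- round(segment_s * w$rate)
  k <- length(w$samples) %/% seg_n
  if (k == 0) return(list(extend_by_repetition(w, segment_s)))
  lapply(seq_len(k), function(i)
    waveform(w$samples[((i - 1) * seg_n + 1):(i * seg_n)], w$rate,
             w$bit_depth))
}

#' Select a patient's informative speech protocols
#'
#' A protocol is selected iff its validation predictions are correct for
#' both motor states (`rule = "all"` requires every validation segment
#' correct; `rule = "majority"` requires a per-state majority).  If no
#' protocol qualifies, the selection falls back to all protocols and the
#' `fallback` flag is raised, so the patient still receives a call.
#'
#' @param validation data frame with columns `protocol`, `truth`
#'   (`"ON"`/`"OFF"`), `call` (predicted label), one row per validation
#'   segment.
#' @param rule `"all"` (default) or `"majority"`.
#' @return A `protocol_selection`: list with `selected`, `evidence`,
#'   `fallback`.
#' @export
select_protocols <- function(validation, rule = c("all", "majority")) {
  rule <- match.arg(rule)
  stopifnot(all(c("protocol", "truth", "call") %in% names(validation)))
  protocols <- unique(validation$protocol)
  ok <- vapply(protocols, function(p) {
    rows <- validation[validation$protocol == p, ]
    state_ok <- vapply(c("ON", "OFF"), function(st) {
      r <- rows[rows$truth == st, ]
      if (!nrow(r)) return(FALSE)
      if (rule == "all") all(r$call == st) else mean(r$call == st) > 0.5
    }, TRUE)
    all(state_ok)
  }, TRUE)
  fallback <- !any(ok)
  structure(list(selected = if (fallback) protocols else protocols[ok],
                 evidence = validation, fallback = fallback),
            class = "protocol_selection")
}

#' @export
print.protocol_selection <- function(x, ...) {
  cat(sprintf("<protocol_selection> %s%s\n",
              paste(x$selected, collapse = ", "),
              if (x$fallback) " (fallback: none qualified)" else ""))
  invisible(x)
}
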