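# Phone-Attribute Codebook (PAC) classification.
#
# Instance-based ON/OFF classification: posterior streams are 1-bit
# quantized into 21-bit frame codes; the unique codes of each class form a
# codebook; shared codes are removed so the two codebooks are disjoint; a
# test sample is assigned the state whose codebook it matches more often,
# with Jaccard similarity as the fallback when exact matching ties (in
# particular when no direct match exists).  Codes are represented as
# 21-character bit-strings so set operations are plain string matching.

code_to_string <- function(bits) paste(bits, collapse = "")

#' 1-bit quantization of a posterior stream
#'
#' A bit is 1 iff the posterior probability is `>= threshold` (the boundary
#' value 0.5 maps to 1 by convention, for determinism).
#'
#' @param stream a [posterior_stream()].
#' @param threshold quantization threshold.
#' @return Character vector of 21-character bit-strings, one per frame.
#' @export
quantize_posteriors <- function(stream, threshold = 0.5) {
  stopifnot(inherits(stream, "posterior_stream"))
  B <- (stream$posteriors >= threshold) + 0L
  apply(B, 1, code_to_string)
}

#' Build per-class codebooks from training streams
#'
#' Accumulates the quantized frame codes of every training stream of one
#' class into a codebook of unique codes, retaining frame-occurrence
#' counts.
#'
#' @param streams list of [posterior_stream()]s of one class.
#' @param class_label `"ON"` or `"OFF"`.
#' @param protocol protocol name the codebook is scoped to.
#' @return A `codebook` object: `codes` (character), `counts` (integer),
#'   `class_label`, `protocol`.
#' @export
build_codebook <- function(streams, class_label, protocol) {
  if (!length(streams))
    stopf("no training streams for class %s, protocol %s", class_label, protocol)
  codes <- unlist(lapply(streams, quantize_posteriors), use.names = FALSE)
  codebook_from_codes(codes, class_label, protocol)
}

# Codebook from pre-quantized frame codes (lets cross-validation quantize
# each stream once instead of once per fold).
codebook_from_codes <- function(codes, class_label, protocol) {
  tab <- table(codes)
  structure(list(codes = names(tab), counts = as.integer(tab),
                 class_label = class_label, protocol = protocol),
            class = "codebook")
}

#' Build the ON and OFF codebooks for one protocol
#'
#' @param on_streams,off_streams lists of training [posterior_stream()]s.
#' @param protocol protocol name.
#' @return List with `on` and `off` [build_codebook()] results.
#' @export
build_codebooks <- function(on_streams, off_streams, protocol) {
  list(on = build_codebook(on_streams, "ON", protocol),
       off = build_codebook(off_streams, "OFF", protocol))
}

#' Remove shared codes so the two codebooks are disjoint
#'
#' Codes occurring in both classes are removed from both, leaving unique
#' ON and OFF codebooks whose intersection is empty.
#'
#' @param on,off `codebook`s from the same protocol.
#' @return List with the pruned `on` and `off` codebooks (class
#'   `unique_codebook_pair`).
#' @export
make_unique <- function(on, off) {
  stopifnot(inherits(on, "codebook"), inherits(off, "codebook"))
  if (!identical(on$protocol, off$protocol))
    stopf("codebooks come from different protocols (%s vs %s)",
          on$protocol, off$protocol)
  shared <- intersect(on$codes, off$codes)
  keep_on <- !(on$codes %in% shared)
  keep_off <- !(off$codes %in% shared)
  on$codes <- on$codes[keep_on]; on$counts <- on$counts[keep_on]
  off$codes <- off$codes[keep_off]; off$counts <- off$counts[keep_off]
  if (!length(on$codes) && !length(off$codes))
    stopf("degenerate training for protocol %s: no unique codes in either class",
          on$protocol)
  structure(list(on = on, off = off), class = "unique_codebook_pair")
}

#' Jaccard similarity between two binary codes
#'
#' `a / (a + b + c)` where `a` counts positions active in both codes, `b`
#' positions active only in the first, and `c` positions active only in the
#' second; joint absences are ignored.  Two all-zero codes are identical
#' and score 1.
#'
#' @param x,y equal-length 0/1 vectors or bit-strings.
#' @return Similarity in \[0, 1\].
#' @export
jaccard_similarity <- function(x, y) {
  if (is.character(x)) x <- as.integer(strsplit(x, "")[[1]])
  if (is.character(y)) y <- as.integer(strsplit(y, "")[[1]])
  if (length(x) != length(y)) stopf("codes must have equal length")
  a <- sum(x == 1 & y == 1)
  b <- sum(x == 1 & y == 0)
  cc <- sum(x == 0 & y == 1)
  if (a + b + cc == 0) return(1)
  a / (a + b + cc)
}

# Bit matrix (codes x 21) from bit-strings, cached-friendly.
codes_to_matrix <- function(codes) {
  if (!length(codes)) return(matrix(0L, 0, 0))
  t(vapply(strsplit(codes, ""), as.integer, integer(nchar(codes[1]))))
}

# Max Jaccard similarity of each query code against a codebook, vectorized:
# for binary rows, a = Q %*% t(C), |x|+|y| known, J = a / (|x| + |y| - a).
max_jaccard_scores <- function(query_codes, book_codes) {
  if (!length(book_codes)) return(rep(0, length(query_codes)))
  Q <- codes_to_matrix(query_codes)
  C <- codes_to_matrix(book_codes)
  A <- Q %*% t(C)
  qs <- rowSums(Q); cs <- rowSums(C)
  denom <- outer(qs, cs, "+") - A
  J <- ifelse(denom == 0, 1, A / pmax(denom, 1e-12))
  apply(J, 1, max)
}

#' Classify a test sample against a unique codebook pair
#'
#' Stage 1 (exact matching): count test frames whose code occurs in each
#' unique codebook (per-frame weighting by default; per-unique-code
#' weighting by `weighting = "unique"`); the class with more matches wins.
#' Stage 2 (Jaccard fallback, on exact ties, including the no-match 0=0
#' case, or always when `matching = "jaccard"`): each test code scores its
#' maximum Jaccard similarity against each codebook, scores are summed
#' over test codes.  A persistent tie yields `"ABSTAIN"`.
#'
#' @param test_codes character vector of quantized test frame codes (from
#'   [quantize_posteriors()]).
#' @param pair a `unique_codebook_pair` from [make_unique()].
#' @param weighting `"frame"` (default) or `"unique"`.
#' @param matching `"exact-then-jaccard"` (default) or `"jaccard"`.
#' @return A `match_decision`: list with `label` (`"ON"|"OFF"|"ABSTAIN"`),
#'   `on_score`, `off_score`, `margin`, `mechanism`.
#' @export
classify_sample <- function(test_codes, pair,
                            weighting = c("frame", "unique"),
                            matching = c("exact-then-jaccard", "jaccard")) {
  stopifnot(inherits(pair, "unique_codebook_pair"))
  weighting <- match.arg(weighting)
  matching <- match.arg(matching)
  if (!length(pair$on$codes) && !length(pair$off$codes))
    stopf("degenerate codebook pair")
  codes <- if (weighting == "unique") unique(test_codes) else test_codes
  decision <- NULL
  if (matching == "exact-then-jaccard") {
    on_score <- sum(codes %in% pair$on$codes)
    off_score <- sum(codes %in% pair$off$codes)
    if (on_score != off_score) {
      decision <- list(label = if (on_score > off_score) "ON" else "OFF",
                       on_score = on_score, off_score = off_score,
                       margin = on_score - off_score, mechanism = "exact")
    }
  }
  if (is.null(decision)) {
    on_score <- sum(max_jaccard_scores(codes, pair$on$codes))
    off_score <- sum(max_jaccard_scores(codes, pair$off$codes))
    label <- if (on_score > off_score) "ON"
             else if (off_score > on_score) "OFF" else "ABSTAIN"
    decision <- list(label = label, on_score = on_score,
                     off_score = off_score, margin = on_score - off_score,
                     mechanism = "jaccard")
  }
  structure(decision, class = "match_decision")
}

#' Majority vote over per-protocol decisions
#'
#' Abstaining protocols are excluded; label ties are broken by the summed
#' `on_score - off_score` margin (positive margin means ON); if every
#' protocol abstains the patient is undecidable.
#'
#' @param decisions list of `match_decision`s (one per protocol).
#' @return `"ON"` or `"OFF"`.
#' @export
vote_protocols <- function(decisions) {
  labels <- vapply(decisions, function(d) d$label, "")
  margins <- vapply(decisions, function(d) d$margin, 1)
  active <- labels != "ABSTAIN"
  if (!any(active)) stopf("all protocols abstained: patient undecidable")
  n_on <- sum(labels[active] == "ON")
  n_off <- sum(labels[active] == "OFF")
  if (n_on > n_off) "ON"
  else if (n_off > n_on) "OFF"
  else if (sum(margins[active]) >= 0) "ON" else "OFF"
}

#' Serialize a unique codebook pair to JSON
#'
#' @param pair a `unique_codebook_pair`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_codebooks <- function(pair, path) {
  doc <- list(protocol = pair$on$protocol,
              on = list(codes = pair$on$codes, counts = pair$on$counts),
              off = list(codes = pair$off$codes, counts = pair$off$counts))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a serialized codebook pair
#'
#' @param path JSON path written by [write_codebooks()].
#' @return A `unique_codebook_pair`.
#' @export
read_codebooks <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(side, label)
    structure(list(codes = as.character(side$codes),
                   counts = as.integer(side$counts),
                   class_label = label, protocol = doc$protocol),
              class = "codebook")
  structure(list(on = mk(doc$on, "ON"), off = mk(doc$off, "OFF")),
            class = "unique_codebook_pair")
}
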