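# Phone-attribute codebook classifier: quantization, codebooks, matching.

make_stream <- function(rows) {
  posterior_stream(do.call(rbind, rows))
}

bitvec <- function(s) as.integer(strsplit(s, "")[[1]])

test_that("1-bit quantization thresholds at 0.5 with the boundary on 1", {
  row <- rep(0, 21)
  row[1] <- 0.9; row[2] <- 0.3; row[3] <- 0.7; row[4] <- 0.5
  codes <- quantize_posteriors(make_stream(list(row, rep(0, 21))))
  expect_equal(substr(codes[1], 1, 4), "1011")  # 0.5 maps to 1
  expect_equal(codes[2], paste(rep("0", 21), collapse = ""))
  expect_true(all(nchar(codes) == 21))
})

test_that("codebooks deduplicate codes and retain frame counts", {
  a <- c(rep(1, 3), rep(0, 18)); b <- c(rep(0, 18), rep(1, 3))
  book <- build_codebook(list(make_stream(list(a, a, b))), "ON", "pataka")
  expect_length(book$codes, 2)
  counts <- stats::setNames(book$counts, book$codes)
  expect_equal(unname(counts[paste(a, collapse = "")]), 2L)
  expect_equal(unname(counts[paste(b, collapse = "")]), 1L)
  expect_error(build_codebook(list(), "ON", "pataka"), "no training streams")
})

test_that("unique codebooks are disjoint and degenerate pairs error", {
  mk <- function(codes, label) structure(
    list(codes = codes, counts = rep(1L, length(codes)),
         class_label = label, protocol = "pataka"), class = "codebook")
  on <- mk(c("A", "B", "C"), "ON"); off <- mk(c("B", "D"), "OFF")
  pair <- make_unique(on, off)
  expect_setequal(pair$on$codes, c("A", "C"))
  expect_setequal(pair$off$codes, "D")
  expect_length(intersect(pair$on$codes, pair$off$codes), 0)
  expect_error(make_unique(mk(c("A", "B"), "ON"), mk(c("A", "B"), "OFF")),
               "degenerate")
  # disjoint books pass through unchanged
  p2 <- make_unique(mk(c("A", "B"), "ON"), mk(c("C"), "OFF"))
  expect_setequal(p2$on$codes, c("A", "B"))
  # property: intersection always empty on random instances
  set.seed(42)
  for (i in 1:20) {
    onb <- mk(unique(random_codes(15)), "ON")
    offb <- mk(unique(random_codes(15)), "OFF")
    p <- tryCatch(make_unique(onb, offb), error = function(e) NULL)
    if (!is.null(p))
      expect_length(intersect(p$on$codes, p$off$codes), 0)
  }
})

test_that("Jaccard similarity equals the a/(a+b+c) count ratio", {
  expect_equal(jaccard_similarity(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(jaccard_similarity(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(jaccard_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(jaccard_similarity(c(0, 0), c(0, 0)), 1)  # identical all-zero
  expect_error(jaccard_similarity(c(1, 0), c(1, 0, 1)), "equal length")
  # brute-force oracle over random pairs, plus symmetry
  set.seed(7)
  for (i in 1:50) {
    x <- sample(0:1, 21, replace = TRUE); y <- sample(0:1, 21, replace = TRUE)
    a <- 0; b <- 0; cc <- 0
    for (j in 1:21) {
      if (x[j] == 1 && y[j] == 1) a <- a + 1
      if (x[j] == 1 && y[j] == 0) b <- b + 1
      if (x[j] == 0 && y[j] == 1) cc <- cc + 1
    }
    expected <- if (a + b + cc == 0) 1 else a / (a + b + cc)
    expect_equal(jaccard_similarity(x, y), expected)
    expect_equal(jaccard_similarity(y, x), jaccard_similarity(x, y))
  }
})

toy_pair <- function(on_codes, off_codes) {
  mk <- function(codes, label) structure(
    list(codes = codes, counts = rep(1L, length(codes)),
         class_label = label, protocol = "pataka"), class = "codebook")
  structure(list(on = mk(on_codes, "ON"), off = mk(off_codes, "OFF")),
            class = "unique_codebook_pair")
}

test_that("exact matching counts frames and the majority class wins", {
  A <- paste(c(1, 1, rep(0, 19)), collapse = "")
  E <- paste(c(0, 0, 1, 1, rep(0, 17)), collapse = "")
  d <- classify_sample(c(A, A, E), toy_pair(A, E))
  expect_equal(d$label, "ON")
  expect_equal(d$on_score, 2)
  expect_equal(d$off_score, 1)
  expect_equal(d$mechanism, "exact")
})

test_that("Jaccard fallback decides when no exact match exists", {
  on_code <- paste(c(1, 1, 1, 1, rep(0, 17)), collapse = "")
  off_code <- paste(c(rep(0, 17), 1, 1, 1, 1), collapse = "")
  # test code shares 3 of 4 bits with the OFF code, none with ON
  test_code <- paste(c(rep(0, 17), 1, 1, 1, 0), collapse = "")
  d <- classify_sample(test_code, toy_pair(on_code, off_code))
  expect_equal(d$mechanism, "jaccard")
  expect_equal(d$label, "OFF")
  expect_equal(d$off_score, 3 / 4)
  expect_equal(d$on_score, 0)
})

test_that("classification is label-symmetric under codebook swap", {
  set.seed(13)
  for (i in 1:15) {
    on <- unique(random_codes(8)); off <- setdiff(unique(random_codes(8)), on)
    if (!length(off)) next
    test <- random_codes(10)
    d1 <- classify_sample(test, toy_pair(on, off))
    d2 <- classify_sample(test, toy_pair(off, on))
    flip <- c(ON = "OFF", OFF = "ON", ABSTAIN = "ABSTAIN")
    expect_equal(d2$label, unname(flip[d1$label]))
    expect_equal(d2$on_score, d1$off_score)
  }
})

test_that("optimized exact scores equal the all-pairs brute-force oracle", {
  set.seed(99)
  for (i in 1:20) {
    on <- unique(random_codes(sample(5:50, 1)))
    off <- setdiff(unique(random_codes(sample(5:50, 1))), on)
    if (!length(off)) next
    test <- random_codes(sample(10:50, 1))
    d <- classify_sample(test, toy_pair(on, off))
    brute_on <- sum(vapply(test, function(tc)
      any(vapply(on, identical, TRUE, x = tc)), TRUE))
    brute_off <- sum(vapply(test, function(tc)
      any(vapply(off, identical, TRUE, x = tc)), TRUE))
    if (d$mechanism == "exact") {
      expect_equal(d$on_score, brute_on)
      expect_equal(d$off_score, brute_off)
    } else {
      expect_equal(brute_on, brute_off)  # fallback only fires on ties
    }
  }
})

test_that("unique-code weighting counts each distinct code once", {
  A <- paste(c(1, rep(0, 20)), collapse = "")
  B <- paste(c(0, 1, rep(0, 19)), collapse = "")
  pair <- toy_pair(A, B)
  d <- classify_sample(c(A, A, A, B), pair, weighting = "unique")
  expect_equal(d$on_score, 1)
  expect_equal(d$off_score, 1)   # tie -> falls through to Jaccard
  expect_equal(d$mechanism, "jaccard")
})

test_that("protocol voting takes the majority with margin tie-breaks", {
  mk <- function(label, margin) structure(
    list(label = label, on_score = 0, off_score = 0, margin = margin,
         mechanism = "exact"), class = "match_decision")
  expect_equal(vote_protocols(list(mk("ON", 1), mk("ON", 1), mk("OFF", -4))),
               "ON")
  expect_equal(vote_protocols(list(mk("ON", 5), mk("OFF", -1))), "ON")
  expect_equal(vote_protocols(list(mk("ON", 1), mk("OFF", -7))), "OFF")
  expect_equal(vote_protocols(list(mk("ABSTAIN", 0), mk("OFF", -1))), "OFF")
  expect_error(vote_protocols(list(mk("ABSTAIN", 0))), "undecidable")
})

test_that("codebook pairs serialize to JSON and back", {
  res <- small_pac_cohort()
  manifest <- res$manifest
  streams <- load_cohort_posteriors(manifest[manifest$protocol == "pataka", ])
  states <- manifest$state[manifest$protocol == "pataka"]
  books <- build_codebooks(streams[states == "ON"], streams[states == "OFF"],
                           "pataka")
  pair <- make_unique(books$on, books$off)
  path <- withr::local_tempfile(fileext = ".json")
  write_codebooks(pair, path)
  pair2 <- read_codebooks(path)
  expect_setequal(pair2$on$codes, pair$on$codes)
  expect_setequal(pair2$off$codes, pair$off$codes)
  expect_equal(pair2$on$protocol, "pataka")
})
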