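# Feature-level statistics: paired t-tests, attribute correlations,
# 2-D embeddings.

test_that("paired t equals the textbook formula and stats::t.test", {
  set.seed(4)
  on <- matrix(rnorm(20 * 21, 0.5, 0.1), 20, 21,
               dimnames = list(NULL, pd_attributes()))
  off <- on + matrix(rnorm(20 * 21, 0, 0.05), 20, 21)
  res <- attribute_ttest(on, off)
  for (a in sample(pd_attributes(), 6)) {
    d <- on[, a] - off[, a]
    t_manual <- mean(d) / (stats::sd(d) / sqrt(length(d)))
    oracle <- stats::t.test(on[, a], off[, a], paired = TRUE)
    row <- res[res$attribute == a, ]
    expect_lt(abs(row$t - t_manual), 1e-10)
    expect_lt(abs(row$t - unname(oracle$statistic)), 1e-10)
    expect_lt(abs(row$p - oracle$p.value), 1e-12)
  }
  expect_true(all(diff(abs(res$t)) <= 1e-12))  # sorted by |t|
  expect_true(all(res$p_adjusted >= res$p))
})

test_that("degenerate pairings follow the documented conventions", {
  on <- matrix(0.5, 4, 21, dimnames = list(NULL, pd_attributes()))
  res <- attribute_ttest(on, on)
  expect_true(all(res$t == 0))
  expect_true(all(res$p == 1))
  off <- on; off[, 1] <- on[, 1] - 0.1   # constant nonzero difference
  res2 <- attribute_ttest(on, off)
  r <- res2[res2$attribute == pd_attributes()[1], ]
  expect_equal(r$t, Inf)
  expect_equal(r$p, 0)
  expect_error(attribute_ttest(on[1, , drop = FALSE], on[1, , drop = FALSE]),
               "at least 2")
})

test_that("designed ON-OFF offsets surface as the top-|t| attributes", {
  # clean design: no weakening/silence effects, only posterior offsets
  cfg <- cohort_config(n_patients = 8,
                       protocols = c("digits", "months", "twisters"),
                       effect_sizes = c(fricative = 0.25, vocalic = -0.25),
                       dropout_prob_off = 0, frame_dropout_off = 0,
                       silence_boost_off = 0, rate_factor_off = 1,
                       patient_heterogeneity = 0, seed = 404L)
  map <- phone_attribute_map()
  feats <- function(st) t(vapply(seq_len(cfg$n_patients), function(i) {
    rowsum <- sapply(cfg$protocols, function(pr) {
      s <- synthesize_posteriors(pr, st, 1, cfg,
                                 seed = 404 + i * 7 +
                                   match(pr, cfg$protocols) +
                                   (st == "OFF") * 1000)
      colMeans(s$posteriors)
    })
    rowMeans(rowsum)
  }, numeric(21)))
  res <- attribute_ttest(feats("ON"), feats("OFF"))
  top2 <- res$attribute[1:2]
  expect_setequal(top2, c("fricative", "vocalic"))
  expect_gt(res$t[res$attribute == "fricative"], 0)  # ON higher
  expect_lt(res$t[res$attribute == "vocalic"], 0)    # ON lower
})

test_that("default OFF effects push silence and fricative in opposite directions", {
  res <- small_pac_cohort()
  streams <- load_cohort_posteriors(res$manifest)
  agg <- function(st) t(sapply(which(res$manifest$state == st),
                               function(i) colMeans(streams[[i]]$posteriors)))
  tt <- attribute_ttest(agg("ON"), agg("OFF"))
  t_sil <- tt$t[tt$attribute == "silence"]
  t_fric <- tt$t[tt$attribute == "fricative"]
  expect_lt(t_sil, 0)    # more silence in OFF
  expect_gt(t_fric, 0)   # fricative suppressed in OFF
})

test_that("trajectory correlations behave at the fixed points", {
  s <- random_stream(200, seed = 21)
  expect_equal(attribute_correlation(s, "tense", "tense")$r, 1)
  anti <- s
  anti$posteriors[, "mid"] <- 1 - anti$posteriors[, "high"]
  expect_equal(attribute_correlation(anti, "high", "mid")$r, -1)
  flat <- s
  flat$posteriors[, "velar"] <- 0.5
  out <- attribute_correlation(flat, "velar", "high")
  expect_true(out$degenerate)
  expect_true(is.na(out$r))
})

test_that("structurally co-active attributes correlate strongly in ON pataka", {
  streams <- lapply(1:3, function(i)
    synthesize_posteriors("pataka", "ON", 1, cohort_config(), seed = 500 + i))
  out <- attribute_correlation(streams, "high", "coronal")
  expect_gt(out$r, 0.9)
})

test_that("embedding separates separable clouds and is seed-stable", {
  set.seed(6)
  X <- rbind(matrix(rnorm(30 * 5, 0), 30, 5), matrix(rnorm(30 * 5, 4), 30, 5))
  states <- rep(c("ON", "OFF"), each = 30)
  e1 <- embed_protocol(X, states, seed = 3)
  expect_gt(e1$separability, 0.9)
  e2 <- embed_protocol(X, states, seed = 3)
  expect_identical(e1$coords, e2$coords)
  # identical class distributions: separability near chance
  X0 <- matrix(rnorm(60 * 5), 60, 5)
  e0 <- embed_protocol(X0, states, seed = 4)
  expect_lt(e0$separability, 0.8)
  expect_warning(out <- embed_protocol(X[1:8, ], states[c(1:4, 31:34)]),
                 "too few")
  expect_null(out)
})

test_that("informative protocols embed more separably than weak ones", {
  res <- fixture_cohort("stats-sep",
                        cohort_config(n_patients = 5,
                                      protocols = c("pataka", "monologue"),
                                      seed = 303L))
  streams <- load_cohort_posteriors(res$manifest)
  # embeddings are stochastic: compare mean separability over a few seeds
  sep <- sapply(c("pataka", "monologue"), function(prot) {
    idx <- which(res$manifest$protocol == prot)
    feats <- segment_mean_posteriors(streams[idx])
    states <- rep(res$manifest$state[idx],
                  vapply(idx, function(i)
                    nrow(streams[[i]]$posteriors) %/% 200, numeric(1)))
    mean(vapply(1:3, function(sd)
      embed_protocol(feats, states, seed = sd)$separability, numeric(1)))
  })
  expect_gte(sep[["pataka"]], sep[["monologue"]])
})
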