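# Convolutional-recurrent classifier: architecture contracts, gradient
# correctness, training behavior, and decision rules.

test_that("output step count follows the convolution length formula", {
  cfg <- tiny_crnn_config(seed = 1)
  model <- build_crnn(cfg, n = 571, f = 201)
  expect_equal(model$m, (571 - 15) %/% 4 + 1)   # = 140
  expect_equal(model$m, 140)
  X <- lapply(1:2, function(i) matrix(rnorm(571 * model$d0), 571, model$d0))
  out <- pdvoice:::crnn_forward(model, X)
  expect_equal(dim(out$probs), c(2, 140))
  expect_true(all(out$probs > 0 & out$probs < 1))
})

test_that("GRU and LSTM variants produce the same output shape", {
  for (kind in c("GRU", "LSTM")) {
    cfg <- tiny_crnn_config(recurrent_kind = kind, seed = 2)
    model <- build_crnn(cfg, n = 120, f = 201)
    X <- list(matrix(rnorm(120 * model$d0), 120, model$d0))
    out <- pdvoice:::crnn_forward(model, X)
    expect_equal(dim(out$probs), c(1, model$m))
  }
})

test_that("analytic gradients match finite differences for every layer", {
  for (kind in c("GRU", "LSTM")) {
    cfg <- crnn_config(conv_filters = 3, kernel_size = 5, stride_time = 2,
                       stride_freq = 2, recurrent_units = 2,
                       dropout_rate = 0, recurrent_kind = kind, seed = 11)
    model <- build_crnn(cfg, n = 20, f = 6)
    set.seed(31)
    X <- lapply(1:3, function(i) matrix(rnorm(20 * model$d0), 20, model$d0))
    y <- c(1, 0, 1)
    g <- pdvoice:::crnn_loss_grads(model, X, y)$grads
    loss_at <- function(m) pdvoice:::crnn_loss_grads(m, X, y)$loss
    check <- function(analytic, mutate) {
      h <- 1e-6
      ng <- (loss_at(mutate(model, h)) - loss_at(mutate(model, -h))) / (2 * h)
      expect_lt(abs(analytic - ng) / max(1e-8, abs(ng)), 1e-4)
    }
    check(g$conv_W[5], function(m, h) { m$params$conv_W[5] <- m$params$conv_W[5] + h; m })
    check(g$conv_b[1], function(m, h) { m$params$conv_b[1] <- m$params$conv_b[1] + h; m })
    check(g$rnn1_f$dWx[3], function(m, h) { m$params$rnn1_f$Wx[3] <- m$params$rnn1_f$Wx[3] + h; m })
    check(g$rnn1_f$dWh[2], function(m, h) { m$params$rnn1_f$Wh[2] <- m$params$rnn1_f$Wh[2] + h; m })
    check(g$rnn1_b$db[1], function(m, h) { m$params$rnn1_b$b[1] <- m$params$rnn1_b$b[1] + h; m })
    check(g$bn1_gamma[2], function(m, h) { m$params$bn1_gamma[2] <- m$params$bn1_gamma[2] + h; m })
    check(g$rnn2_f$dWh[4], function(m, h) { m$params$rnn2_f$Wh[4] <- m$params$rnn2_f$Wh[4] + h; m })
    check(g$rnn2_b$dWx[2], function(m, h) { m$params$rnn2_b$Wx[2] <- m$params$rnn2_b$Wx[2] + h; m })
    check(g$bn2_beta[3], function(m, h) { m$params$bn2_beta[3] <- m$params$bn2_beta[3] + h; m })
    check(g$dense_W[1], function(m, h) { m$params$dense_W[1] <- m$params$dense_W[1] + h; m })
    check(g$dense_b, function(m, h) { m$params$dense_b <- m$params$dense_b + h; m })
  }
})

test_that("training set assembly guards against patient leakage", {
  res <- small_audio_cohort()
  waves <- fixture_waves(res)
  prep <- prepare_training_set(res$manifest, waves, 1)
  expect_true(all(prep$labels %in% 0:1))
  expect_true(all(vapply(prep$segments,
                         function(s) length(s$samples), 1) == 160000))
  expect_setequal(unique(prep$labels), 0:1)
  # fold with a single class present must error
  m1 <- res$manifest[res$manifest$state == "ON", ]
  expect_error(prepare_training_set(m1, waves[res$manifest$state == "ON"], 1),
               "lacks one motor state")
  expect_error(prepare_training_set(res$manifest[0, ], list(), 1),
               "empty training fold")
})

test_that("training is deterministic and its loss decreases when separable", {
  res <- small_audio_cohort()
  waves <- fixture_waves(res)
  prep <- prepare_training_set(res$manifest, waves, 1)
  specs <- lapply(prep$segments, compute_spectrogram)
  norm <- fit_normalizer(specs)
  specs <- lapply(specs, apply_normalizer, stats = norm)
  cfg <- tiny_crnn_config(epochs = 4, seed = 77)
  m1 <- train_crnn(build_crnn(cfg), specs, prep$labels)
  m2 <- train_crnn(build_crnn(cfg), specs, prep$labels)
  expect_identical(tail(m1$training_log$loss, 1), tail(m2$training_log$loss, 1))
  expect_lt(tail(m1$training_log$loss, 1), m1$training_log$loss[1])
  expect_error(train_crnn(build_crnn(cfg), specs[prep$labels == 1],
                          prep$labels[prep$labels == 1]),
               "both classes")
  .fixture_env$trained_model <- m1
  .fixture_env$trained_norm <- norm
})

test_that("a trained model separates held-out segments of a contrasting cohort", {
  res <- small_audio_cohort()
  waves <- .fixture_env$waves16
  model <- .fixture_env$trained_model
  norm <- .fixture_env$trained_norm
  # held-out patient 1, utterance-level segments
  rows <- which(res$manifest$patient_id == 1)
  calls <- character(0); truths <- character(0)
  for (i in rows) {
    segs <- pdvoice:::chunk_utterance(waves[[i]])
    for (s in segs) {
      spec <- apply_normalizer(compute_spectrogram(s), norm)
      p <- as.numeric(predict_crnn(model, list(spec)))
      calls <- c(calls, decide_state(p, 0.5))
      truths <- c(truths, res$manifest$state[i])
    }
  }
  expect_gte(mean(calls == truths), 0.9)
})

test_that("threshold-and-vote decision follows the strict majority rule", {
  expect_equal(decide_state(c(0.9, 0.9, 0.1, 0.9), 0.44), "ON")
  expect_equal(decide_state(rep(0.44, 4), 0.44), "ON")  # boundary bits are ON
  expect_equal(decide_state(c(0.9, 0.9, 0.1, 0.1), 0.44), "OFF")  # exact m/2
  # permutation invariance
  p <- runif(15)
  expect_equal(decide_state(p, 0.44), decide_state(sample(p), 0.44))
})

test_that("threshold selection scans the grid and averages across folds", {
  fold <- list(probs = list(rep(0.2, 10), rep(0.8, 10), rep(0.15, 10)),
               truth = c("OFF", "ON", "OFF"))
  expect_equal(select_threshold(list(fold)), 0.21)
  expect_equal(select_threshold(list(fold, fold)), 0.21)  # mean of equal folds
  expect_equal(select_threshold(list(), mode = "replication"), 0.44)
  expect_error(select_threshold(list()), "no validation data")
})
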