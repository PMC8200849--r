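# CRNN configuration, training-set assembly, and decision rules.

#' CRNN configuration
#'
#' Defaults follow the reference architecture: 196 conv filters, kernel 15,
#' strides of 4 in time and frequency, two stacked bidirectional recurrent
#' layers of 128 units with dropout 0.8 and batch normalization, and a
#' decision threshold of 0.44.  The frequency stride is realized as a 4x
#' average-pooling decimation of the frequency axis before the temporal
#' convolution (`freq_mode = "pool"`); `freq_mode = "channels"` keeps all
#' bins as convolution input channels.
#'
#' @param conv_filters,kernel_size,stride_time,stride_freq convolution
#'   stage hyper-parameters.
#' @param recurrent_units units per direction in each recurrent layer.
#' @param recurrent_kind `"GRU"` or `"LSTM"`.
#' @param dropout_rate fraction of units dropped after each recurrent
#'   layer, in \[0, 1).
#' @param threshold per-timestep decision threshold in (0, 1).
#' @param epochs,batch_size,learning_rate training hyper-parameters.
#' @param freq_mode `"pool"` or `"channels"` (see above).
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return A `crnn_config` object.
#' @export
crnn_config <- function(conv_filters = 196, kernel_size = 15,
                        stride_time = 4, stride_freq = 4,
                        recurrent_units = 128,
                        recurrent_kind = c("GRU", "LSTM"),
                        dropout_rate = 0.8, threshold = 0.44,
                        epochs = 20, batch_size = 16, learning_rate = 1e-3,
                        freq_mode = c("pool", "channels"), seed = 1L) {
  recurrent_kind <- match.arg(recurrent_kind)
  freq_mode <- match.arg(freq_mode)
  stopifnot(conv_filters >= 1, kernel_size >= 1, stride_time >= 1,
            stride_freq >= 1, recurrent_units >= 1, epochs >= 1,
            batch_size >= 1, learning_rate > 0)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stopf("dropout_rate must lie in [0, 1)")
  if (threshold <= 0 || threshold >= 1)
    stopf("threshold must lie in (0, 1)")
  structure(list(conv_filters = as.integer(conv_filters),
                 kernel_size = as.integer(kernel_size),
                 stride_time = as.integer(stride_time),
                 stride_freq = as.integer(stride_freq),
                 recurrent_units = as.integer(recurrent_units),
                 recurrent_kind = recurrent_kind,
                 dropout_rate = dropout_rate, threshold = threshold,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, freq_mode = freq_mode,
                 seed = as.integer(seed)),
            class = "crnn_config")
}

#' Assemble the labeled training segments for one cross-validation fold
#'
#' Concatenates the training-fold recordings per motor state (manifest
#' order) and cuts them into 10-s segments with per-segment state labels.
#' A leakage guard asserts that no recording of the held-out patient
#' enters the pool.
#'
#' @param manifest cohort manifest data frame.
#' @param waves list of 16-kHz [waveform()]s parallel to the manifest rows.
#' @param holdout_patient patient id excluded from training.
#' @return List with `segments` (list of 10-s waveforms) and `labels`
#'   (0 = OFF, 1 = ON).
#' @export
prepare_training_set <- function(manifest, waves, holdout_patient) {
  stopifnot(nrow(manifest) == length(waves))
  train_idx <- which(manifest$patient_id != holdout_patient)
  if (!length(train_idx)) stopf("empty training fold")
  if (any(manifest$patient_id[train_idx] == holdout_patient))
    stopf("leakage: held-out patient present in training pool")
  states <- manifest$state[train_idx]
  if (length(unique(states)) < 2)
    stopf("training fold lacks one motor state")
  segs <- list(); labels <- integer(0)
  for (st in c("OFF", "ON")) {
    idx <- train_idx[states == st]
    chunks <- chunk_training_audio(waves[idx], st)
    segs <- c(segs, chunks)
    labels <- c(labels, rep(if (st == "ON") 1L else 0L, length(chunks)))
  }
  list(segments = segs, labels = labels)
}

#' Threshold-and-vote decision for one audio sample
#'
#' Each of the m per-timestep probabilities is binarized at `threshold`
#' (probability >= threshold counts as ON); the sample is called ON iff
#' strictly more than m/2 steps are ON, otherwise OFF.
#'
#' @param probs numeric vector of per-timestep probabilities.
#' @param threshold decision threshold.
#' @return `"ON"` or `"OFF"`.
#' @export
decide_state <- function(probs, threshold = 0.44) {
  bits <- probs >= threshold
  if (sum(bits) > length(bits) / 2) "ON" else "OFF"
}

#' Select the decision threshold from validation predictions
#'
#' In `"fit"` mode, each fold's threshold maximizes validation accuracy
#' over a 0.01-step grid (smallest maximizer on ties) and the returned
#' value is the across-fold mean.  `"replication"` mode returns the fixed
#' published constant 0.44 regardless of data.
#'
#' @param folds list of folds, each a list with `probs` (list of
#'   per-timestep probability vectors) and `truth` (character vector of
#'   `"ON"`/`"OFF"` labels).
#' @param mode `"fit"` or `"replication"`.
#' @param grid candidate thresholds.
#' @return Scalar threshold.
#' @export
select_threshold <- function(folds, mode = c("fit", "replication"),
                             grid = seq(0.01, 0.99, by = 0.01)) {
  mode <- match.arg(mode)
  if (mode == "replication") return(0.44)
  if (!length(folds)) stopf("no validation data")
  per_fold <- vapply(folds, function(f) {
    if (!length(f$probs)) stopf("fold without validation predictions")
    acc <- vapply(grid, function(th) {
      calls <- vapply(f$probs, decide_state, "", threshold = th)
      mean(calls == f$truth)
    }, 1)
    grid[which.max(acc)]           # which.max returns the first (smallest)
  }, 1)
  mean(per_fold)
}
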