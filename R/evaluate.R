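# Leave-one-patient-out evaluation, confusion-matrix metrics, and the
# clinical score-table summary.

#' Confusion-matrix metrics (ON is the positive class)
#'
#' @param predictions,truths character vectors of `"ON"`/`"OFF"` labels.
#' @return A `metrics_report`: accuracy, sensitivity (recall),
#'   specificity, precision, and the TP/FP/TN/FN counts.  Ratios with a
#'   zero denominator are reported as `NA` with the `undefined` flag
#'   naming them, never as 0.
#' @export
compute_metrics <- function(predictions, truths) {
  if (length(predictions) != length(truths))
    stopf("got %d predictions but %d truths", length(predictions),
          length(truths))
  tp <- sum(predictions == "ON" & truths == "ON")
  fp <- sum(predictions == "ON" & truths == "OFF")
  tn <- sum(predictions == "OFF" & truths == "OFF")
  fn <- sum(predictions == "OFF" & truths == "ON")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  rep <- list(accuracy = ratio(tp + tn, tp + fp + tn + fn),
              sensitivity = ratio(tp, tp + fn),
              specificity = ratio(tn, tn + fp),
              precision = ratio(tp, tp + fp),
              TP = tp, FP = fp, TN = tn, FN = fn)
  rep$undefined <- names(which(vapply(rep[1:4], is.na, TRUE)))
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f | sensitivity %.3f | specificity %.3f | precision %.3f\n",
              x$accuracy, x$sensitivity, x$specificity, x$precision))
  cat(sprintf("TP %d FP %d TN %d FN %d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

# ---- clinical table ------------------------------------------------------

#' Read the packaged clinical rating table
#'
#' Per-patient motor examination scores (total motor score and the speech
#' item) in the ON and OFF medication states, as printed for the study
#' cohort.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return Data frame with columns ID, Gender, Age, `III Total ON`,
#'   `III Total OFF`, `III.I ON`, `III.I OFF`.
#' @export
read_clinical_table <- function(path = system.file("extdata",
                                                   "updrs_table1.csv",
                                                   package = "pdvoice")) {
  utils::read.csv(path, check.names = FALSE)
}

#' Summarize a clinical rating table
#'
#' Means and sample standard deviations of the total motor score in each
#' state and of the per-patient OFF-minus-ON difference (delta), plus the
#' speech-item means.
#'
#' @param table data frame as returned by [read_clinical_table()].
#' @return List of summary statistics; `delta_sd` is `NA` (flagged) for a
#'   single-row table.
#' @export
summarize_clinical_table <- function(table) {
  need <- c("III Total ON", "III Total OFF", "III.I ON", "III.I OFF")
  missing_col <- setdiff(need, names(table))
  if (length(missing_col))
    stopf("clinical table missing column(s): %s",
          paste(missing_col, collapse = ", "))
  for (cn in need) {
    bad <- which(is.na(table[[cn]]))
    if (length(bad))
      stopf("missing %s for patient %s", cn,
            paste(table$ID[bad], collapse = ", "))
  }
  delta <- table[["III Total OFF"]] - table[["III Total ON"]]
  sd1 <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x)
  list(n = nrow(table),
       iii_on_mean = mean(table[["III Total ON"]]),
       iii_on_sd = sd1(table[["III Total ON"]]),
       iii_off_mean = mean(table[["III Total OFF"]]),
       iii_off_sd = sd1(table[["III Total OFF"]]),
       delta_mean = mean(delta), delta_sd = sd1(delta),
       speech_on_mean = mean(table[["III.I ON"]]),
       speech_off_mean = mean(table[["III.I OFF"]]))
}

# ---- cohort loading ------------------------------------------------------

#' Load all posterior streams referenced by a manifest
#'
#' @param manifest cohort manifest with a `posteriors` path column.
#' @return List of [posterior_stream()]s parallel to the manifest rows.
#' @export
load_cohort_posteriors <- function(manifest) {
  lapply(manifest$posteriors, read_posteriors, provenance = "external")
}

#' Load and downsample all recordings referenced by a manifest
#'
#' @param manifest cohort manifest with a `path` WAV column.
#' @return List of 16-kHz [waveform()]s parallel to the manifest rows.
#' @export
load_cohort_audio <- function(manifest) {
  lapply(manifest$path, function(p) resample_and_quantize(read_wav(p)))
}

# ---- LOOCV ---------------------------------------------------------------

#' Leave-one-patient-out cross-validation
#'
#' One fold per patient: the held-out patient's recordings are classified
#' by models/codebooks built from the remaining patients only (a leakage
#' guard aborts otherwise).  Each fold yields one patient-level call per
#' motor state.  Metrics are macro-averaged over folds; pooled-confusion
#' metrics are also reported.
#'
#' @param manifest cohort manifest data frame.
#' @param method `"pac"`, `"crnn"`, or `"pcrnn"`.
#' @param streams posterior streams parallel to the manifest rows (PAC;
#'   loaded from the manifest when `NULL`).
#' @param waves 16-kHz waveforms parallel to the manifest rows (CRNN;
#'   loaded from the manifest when `NULL`).
#' @param config a [crnn_config()] for the CRNN methods.
#' @param threshold_mode `"fit"` (per-fold validation grid search) or
#'   `"replication"` (fixed 0.44).
#' @param weighting,matching PAC scoring options, see [classify_sample()].
#' @param max_segments_per_state cap on training segments per state per
#'   fold (evenly spaced over the concatenated pool, so all training
#'   patients stay represented); `Inf` keeps everything.
#' @return A `loocv_result`: `records` (one row per patient x state),
#'   `metrics` (macro), `metrics_pooled`, `folds`, `method`.
#' @export
loocv <- function(manifest, method = c("pac", "crnn", "pcrnn"),
                  streams = NULL, waves = NULL, config = NULL,
                  threshold_mode = c("fit", "replication"),
                  weighting = "frame", matching = "exact-then-jaccard",
                  max_segments_per_state = Inf) {
  method <- match.arg(method)
  threshold_mode <- match.arg(threshold_mode)
  patients <- sort(unique(manifest$patient_id))
  if (length(patients) < 2) stopf("need at least 2 patients")
  if (!all(c("ON", "OFF") %in% manifest$state))
    stopf("manifest must contain both motor states")
  if (method == "pac") {
    if (is.null(streams)) streams <- load_cohort_posteriors(manifest)
    codes_list <- lapply(streams, quantize_posteriors)
    folds <- lapply(patients, function(p)
      pac_fold(manifest, codes_list, p, weighting, matching))
  } else {
    if (is.null(config)) config <- crnn_config()
    if (is.null(waves)) waves <- load_cohort_audio(manifest)
    folds <- lapply(patients, function(p)
      crnn_fold(manifest, waves, p, config, threshold_mode,
                personalized = identical(method, "pcrnn"),
                max_segments_per_state = max_segments_per_state))
  }
  assemble_loocv(folds, "records", method)
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> %s: %d patient-state calls\n", x$method,
              nrow(x$records)))
  cat(sprintf("macro accuracy %.3f | pooled accuracy %.3f\n",
              x$metrics$accuracy, x$metrics_pooled$accuracy))
  invisible(x)
}

# One PAC fold: per-protocol unique codebooks from training patients,
# exact/Jaccard classification of the held-out patient's streams, protocol
# majority vote per state.
pac_fold <- function(manifest, codes_list, holdout, weighting, matching) {
  train <- manifest$patient_id != holdout
  if (any(manifest$patient_id[train] == holdout))
    stopf("leakage: held-out patient in training pool")
  protocols <- unique(manifest$protocol)
  decisions <- list(ON = list(), OFF = list())
  prot_records <- list()
  for (prot in protocols) {
    sel <- manifest$protocol == prot
    on_tr <- which(train & sel & manifest$state == "ON")
    off_tr <- which(train & sel & manifest$state == "OFF")
    if (!length(on_tr) || !length(off_tr)) next
    books <- list(
      on = codebook_from_codes(unlist(codes_list[on_tr]), "ON", prot),
      off = codebook_from_codes(unlist(codes_list[off_tr]), "OFF", prot))
    pair <- tryCatch(make_unique(books$on, books$off), error = function(e) NULL)
    for (st in c("ON", "OFF")) {
      te <- which(!train & sel & manifest$state == st)
      if (!length(te)) next
      codes <- unlist(codes_list[te])
      d <- if (is.null(pair))
        structure(list(label = "ABSTAIN", on_score = 0, off_score = 0,
                       margin = 0, mechanism = "degenerate"),
                  class = "match_decision")
      else classify_sample(codes, pair, weighting, matching)
      decisions[[st]][[prot]] <- d
      prot_records[[length(prot_records) + 1L]] <- data.frame(
        patient_id = holdout, protocol = prot, truth = st, call = d$label,
        mechanism = d$mechanism, margin = d$margin)
    }
  }
  records <- do.call(rbind, lapply(c("ON", "OFF"), function(st) {
    pred <- tryCatch(vote_protocols(decisions[[st]]), error = function(e) NA)
    data.frame(patient_id = holdout, truth = st,
               prediction = if (is.null(pred)) NA else pred)
  }))
  list(held_out = holdout, records = records,
       protocol_records = do.call(rbind, prot_records))
}

# One CRNN fold: train on the remaining patients' concatenated 10-s
# segments (channel normalization fitted on the training pool), predict
# the held-out patient's utterance-level segments, decide by threshold +
# majority voting; the p-CRNN variant restricts testing to the protocols
# selected from the validation halves.
crnn_fold <- function(manifest, waves, holdout, config, threshold_mode,
                      personalized = FALSE, max_segments_per_state = Inf) {
  prep <- prepare_training_set(manifest, waves, holdout)
  if (is.finite(max_segments_per_state)) {
    keep <- unlist(lapply(split(seq_along(prep$labels), prep$labels),
                          function(idx) {
      if (length(idx) <= max_segments_per_state) idx
      else idx[round(seq(1, length(idx), length.out = max_segments_per_state))]
    }))
    keep <- sort(keep)
    prep$segments <- prep$segments[keep]
    prep$labels <- prep$labels[keep]
  }
  params <- stft_params()
  train_specs <- lapply(prep$segments, compute_spectrogram, params = params)
  norm <- fit_normalizer(train_specs,
                         provenance = sprintf("loocv-train-minus-%s", holdout))
  train_specs <- lapply(train_specs, apply_normalizer, stats = norm)
  n_frames <- ncol(train_specs[[1]]$magnitude)
  cfg <- config
  cfg$seed <- mix_seed(config$seed, match(holdout, unique(manifest$patient_id)))
  model <- build_crnn(cfg, n = n_frames, f = nrow(train_specs[[1]]$magnitude))
  model <- train_crnn(model, train_specs, prep$labels)
  # held-out patient: 5-s validation/test halves per protocol x state
  rows <- which(manifest$patient_id == holdout)
  splits <- split_patient_recordings(manifest[rows, , drop = FALSE],
                                     waves[rows])
  # batch all validation/test halves into one forward pass
  keys <- list(); halves <- list()
  for (prot in names(splits)) {
    for (st in c("ON", "OFF")) {
      h <- splits[[prot]][[st]]
      for (part in c("validation", "test")) {
        for (w in h[[part]]) {
          keys[[length(keys) + 1L]] <- c(prot, st, part)
          halves[[length(halves) + 1L]] <- w
        }
      }
    }
  }
  specs <- lapply(halves, function(w)
    apply_normalizer(compute_spectrogram(extend_by_repetition(w, 10), params),
                     norm))
  probs <- if (length(specs)) predict_crnn(model, specs) else NULL
  val_probs <- list(); test_probs <- list()
  for (i in seq_along(keys)) {
    key <- paste(keys[[i]][1], keys[[i]][2])
    tgt <- if (keys[[i]][3] == "validation") "val" else "test"
    pv <- as.numeric(probs[i, ])
    if (tgt == "val") val_probs[[key]] <- c(val_probs[[key]], list(pv))
    else test_probs[[key]] <- c(test_probs[[key]], list(pv))
  }
  threshold <- if (threshold_mode == "replication") 0.44 else {
    fold_val <- list(probs = unlist(val_probs, recursive = FALSE),
                     truth = rep(sub("^\\S+ ", "", names(val_probs)),
                                 vapply(val_probs, length, 1L)))
    select_threshold(list(fold_val), mode = "fit")
  }
  val_calls <- do.call(rbind, lapply(names(val_probs), function(key) {
    prot <- sub(" \\S+$", "", key); st <- sub("^\\S+ ", "", key)
    if (!length(val_probs[[key]])) return(NULL)
    data.frame(protocol = prot, truth = st,
               call = vapply(val_probs[[key]], decide_state, "",
                             threshold = threshold))
  }))
  selection <- select_protocols(val_calls)
  protocol_decision <- function(prot, st) {
    tp <- test_probs[[paste(prot, st)]]
    if (!length(tp)) return(NULL)
    calls <- vapply(tp, decide_state, "", threshold = threshold)
    frac_on <- mean(vapply(tp, function(p) mean(p >= threshold), 1))
    label <- if (sum(calls == "ON") > length(calls) / 2) "ON"
             else if (sum(calls == "OFF") > length(calls) / 2) "OFF"
             else if (frac_on >= 0.5) "ON" else "OFF"
    list(label = label, margin = frac_on - 0.5)
  }
  records_for <- function(protocol_set) {
    do.call(rbind, lapply(c("ON", "OFF"), function(st) {
      ds <- Filter(Negate(is.null),
                   lapply(protocol_set, protocol_decision, st = st))
      pred <- if (!length(ds)) NA_character_ else {
        labels <- vapply(ds, function(d) d$label, "")
        n_on <- sum(labels == "ON"); n_off <- sum(labels == "OFF")
        if (n_on > n_off) "ON" else if (n_off > n_on) "OFF"
        else if (sum(vapply(ds, function(d) d$margin, 1)) >= 0) "ON" else "OFF"
      }
      data.frame(patient_id = holdout, truth = st, prediction = pred)
    }))
  }
  records_all <- records_for(names(splits))
  records_sel <- records_for(selection$selected)
  list(held_out = holdout,
       records = if (personalized) records_sel else records_all,
       records_all = records_all, records_personalized = records_sel,
       threshold = threshold, selection = selection,
       training_log = model$training_log)
}

# Assemble a loocv_result from a list of fold objects and a field name.
assemble_loocv <- function(folds, field, method) {
  records <- do.call(rbind, lapply(folds, function(f) f[[field]]))
  ok <- !is.na(records$prediction)
  pooled <- compute_metrics(records$prediction[ok], records$truth[ok])
  per_fold <- lapply(folds, function(f) {
    r <- f[[field]][!is.na(f[[field]]$prediction), ]
    if (!nrow(r)) return(NULL)
    compute_metrics(r$prediction, r$truth)
  })
  macro <- function(nm) {
    v <- vapply(per_fold, function(m) if (is.null(m)) NA_real_ else m[[nm]], 1)
    mean(v, na.rm = TRUE)
  }
  structure(list(records = records,
                 metrics = list(accuracy = macro("accuracy"),
                                sensitivity = macro("sensitivity"),
                                specificity = macro("specificity"),
                                precision = macro("precision")),
                 metrics_pooled = pooled, folds = folds, method = method),
            class = "loocv_result")
}

#' Paired CRNN / p-CRNN leave-one-patient-out evaluation
#'
#' Trains one speaker-independent model per fold and evaluates it both on
#' all protocols (CRNN) and on the per-patient selected protocols
#' (p-CRNN), so the two methods are compared on identical models.
#'
#' @inheritParams loocv
#' @return List with `crnn` and `pcrnn` `loocv_result`s.
#' @export
loocv_paired_crnn <- function(manifest, waves = NULL, config = NULL,
                              threshold_mode = c("fit", "replication"),
                              max_segments_per_state = Inf) {
  threshold_mode <- match.arg(threshold_mode)
  if (is.null(config)) config <- crnn_config()
  if (is.null(waves)) waves <- load_cohort_audio(manifest)
  patients <- sort(unique(manifest$patient_id))
  folds <- lapply(patients, function(p)
    crnn_fold(manifest, waves, p, config, threshold_mode,
              max_segments_per_state = max_segments_per_state))
  list(crnn = assemble_loocv(folds, "records_all", "crnn"),
       pcrnn = assemble_loocv(folds, "records_personalized", "pcrnn"))
}
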