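# Convolutional-recurrent network core: layers, backpropagation, Adam.
#
# There is no deep-learning runtime among this package's dependencies, so
# the network is implemented directly on BLAS-backed matrix algebra.  The
# architecture is fixed by crnn_config(): optional 4x frequency decimation,
# a temporal 1-D convolution (frequency bins as input channels), two
# stacked bidirectional GRU/LSTM layers each followed by dropout and batch
# normalization, and a time-distributed single-unit sigmoid head.  Every
# layer's backward pass is verified against finite differences in the test
# suite.
#
# Batch layout: a minibatch of B segments with m output time steps is kept
# as flat matrices with row order (b-1)*m + t ("segment-major"); the
# recurrent loops index time slices with seq(t, B*m, by = m).

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# ---- parameter initialization -------------------------------------------

init_rnn_dir <- function(din, units, kind) {
  g <- if (kind == "GRU") 3L else 4L
  list(Wx = glorot(din, g * units), Wh = glorot(units, g * units),
       b = numeric(g * units))
}

#' Build a CRNN model
#'
#' @param cfg a [crnn_config()].
#' @param n input time steps (571 for a 10-s segment under the default
#'   STFT parameters).
#' @param f input frequency bins (201 by default).
#' @return A `crnn_model`: parameter list, shapes (`m` output steps),
#'   batch-norm running statistics, and the total parameter count.
#' @export
build_crnn <- function(cfg, n = 571, f = 201) {
  stopifnot(inherits(cfg, "crnn_config"))
  d0 <- if (cfg$freq_mode == "pool") f %/% cfg$stride_freq else f
  m <- (n - cfg$kernel_size) %/% cfg$stride_time + 1L
  if (m < 1) stopf("input too short for kernel size %d", cfg$kernel_size)
  u <- cfg$recurrent_units
  with_seed(cfg$seed, {
    params <- list(
      conv_W = glorot(cfg$kernel_size * d0, cfg$conv_filters),
      conv_b = numeric(cfg$conv_filters),
      rnn1_f = init_rnn_dir(cfg$conv_filters, u, cfg$recurrent_kind),
      rnn1_b = init_rnn_dir(cfg$conv_filters, u, cfg$recurrent_kind),
      bn1_gamma = rep(1, 2 * u), bn1_beta = numeric(2 * u),
      rnn2_f = init_rnn_dir(2 * u, u, cfg$recurrent_kind),
      rnn2_b = init_rnn_dir(2 * u, u, cfg$recurrent_kind),
      bn2_gamma = rep(1, 2 * u), bn2_beta = numeric(2 * u),
      dense_W = glorot(2 * u, 1L), dense_b = 0)
    running <- list(bn1_mean = numeric(2 * u), bn1_var = rep(1, 2 * u),
                    bn2_mean = numeric(2 * u), bn2_var = rep(1, 2 * u))
    count_one <- function(p) if (is.list(p)) sum(vapply(p, length, 1L))
                             else length(p)
    n_params <- sum(vapply(params, count_one, 1))
    structure(list(cfg = cfg, n = n, f = f, d0 = d0, m = m,
                   params = params, running = running, n_params = n_params),
              class = "crnn_model")
  })
}

#' @export
print.crnn_model <- function(x, ...) {
  cat(sprintf(
    "<crnn_model> input (%d x %d) -> m = %d steps; %s x %d units x 2 layers; %d parameters\n",
    x$n, x$f, x$m, x$cfg$recurrent_kind, x$cfg$recurrent_units, x$n_params))
  invisible(x)
}

# ---- input preparation ---------------------------------------------------

# Convert spectrograms (bins x frames) to model input matrices
# (time x channels), applying the 4x frequency decimation when configured.
crnn_inputs <- function(model, spectrograms) {
  lapply(spectrograms, function(s) {
    mag <- if (inherits(s, "spectrogram")) s$magnitude else s
    if (nrow(mag) != model$f)
      stopf("spectrogram has %d bins; model expects %d", nrow(mag), model$f)
    if (ncol(mag) != model$n)
      stopf("spectrogram has %d frames; model expects %d", ncol(mag), model$n)
    X <- t(mag)                                     # time x freq
    if (model$cfg$freq_mode == "pool") {
      sf <- model$cfg$stride_freq
      d0 <- model$d0
      idx <- matrix(seq_len(d0 * sf), nrow = sf)    # groups of sf bins
      X <- sapply(seq_len(d0), function(j) rowMeans(X[, idx[, j], drop = FALSE]))
    }
    X
  })
}

# im2col for temporal convolution: rows are output steps, columns the
# kernel_size x channels patch, flattened kernel-position-major.
conv_patch_index <- function(n, d0, kernel, stride) {
  m <- (n - kernel) %/% stride + 1L
  starts <- (seq_len(m) - 1L) * stride              # 0-based step offsets
  # column index into X (n x d0) flattened column-major:
  # entry (t, (c-1)*kernel + k) = X[starts[t] + k, c]
  pos <- outer(starts, seq_len(kernel), "+")        # m x kernel row indices
  idx <- matrix(0L, m, kernel * d0)
  for (c in seq_len(d0))
    idx[, (c - 1L) * kernel + seq_len(kernel)] <- pos + (c - 1L) * n
  idx
}

# ---- recurrent layers ----------------------------------------------------

# One GRU direction over a flat segment-major input (B*m x din).
# Returns hidden states H (B*m x u) and caches for BPTT.
gru_forward <- function(X, p, B, m, reverse = FALSE) {
  u <- ncol(p$Wh)/3L
  Xg <- X %*% p$Wx
  Xg <- sweep(Xg, 2, p$b, "+")
  H <- matrix(0, B * m, u)
  Z <- matrix(0, B * m, u); R <- matrix(0, B * m, u); C <- matrix(0, B * m, u)
  Hprev <- matrix(0, B * m, u)
  h <- matrix(0, B, u)
  order_t <- if (reverse) rev(seq_len(m)) else seq_len(m)
  iz <- seq_len(u); ir <- u + iz; ic <- 2L * u + iz
  for (t in order_t) {
    rows <- seq(t, B * m, by = m)
    g <- Xg[rows, , drop = FALSE]
    hU <- h %*% p$Wh
    z <- sigmoid(g[, iz, drop = FALSE] + hU[, iz, drop = FALSE])
    r <- sigmoid(g[, ir, drop = FALSE] + hU[, ir, drop = FALSE])
    cc <- tanh(g[, ic, drop = FALSE] + (r * h) %*% p$Wh[, ic, drop = FALSE])
    Hprev[rows, ] <- h
    h <- z * h + (1 - z) * cc
    H[rows, ] <- h; Z[rows, ] <- z; R[rows, ] <- r; C[rows, ] <- cc
  }
  list(H = H, cache = list(X = X, Z = Z, R = R, C = C, Hprev = Hprev,
                           B = B, m = m, reverse = reverse))
}

gru_backward <- function(dH, p, cache) {
  u <- ncol(p$Wh)/3L
  B <- cache$B; m <- cache$m
  iz <- seq_len(u); ir <- u + iz; ic <- 2L * u + iz
  dWx <- matrix(0, nrow(p$Wx), ncol(p$Wx))
  dWh <- matrix(0, u, 3L * u)
  db <- numeric(3L * u)
  dG <- matrix(0, B * m, 3L * u)                    # grads wrt pre-activations
  dh_next <- matrix(0, B, u)
  order_t <- if (cache$reverse) seq_len(m) else rev(seq_len(m))
  for (t in order_t) {
    rows <- seq(t, B * m, by = m)
    z <- cache$Z[rows, , drop = FALSE]
    r <- cache$R[rows, , drop = FALSE]
    cc <- cache$C[rows, , drop = FALSE]
    hprev <- cache$Hprev[rows, , drop = FALSE]
    dh <- dH[rows, , drop = FALSE] + dh_next
    dz <- dh * (hprev - cc)
    dcc <- dh * (1 - z)
    dc_pre <- dcc * (1 - cc^2)
    drh <- dc_pre %*% t(p$Wh[, ic, drop = FALSE])
    dr <- drh * hprev
    dz_pre <- dz * z * (1 - z)
    dr_pre <- dr * r * (1 - r)
    dG[rows, iz] <- dz_pre; dG[rows, ir] <- dr_pre; dG[rows, ic] <- dc_pre
    dWh[, iz] <- dWh[, iz] + t(hprev) %*% dz_pre
    dWh[, ir] <- dWh[, ir] + t(hprev) %*% dr_pre
    dWh[, ic] <- dWh[, ic] + t(r * hprev) %*% dc_pre
    dh_next <- dh * z + drh * r +
      dz_pre %*% t(p$Wh[, iz, drop = FALSE]) +
      dr_pre %*% t(p$Wh[, ir, drop = FALSE])
  }
  dWx <- t(cache$X) %*% dG
  db <- colSums(dG)
  dX <- dG %*% t(p$Wx)
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

# One LSTM direction (gate order: input, forget, candidate, output).
lstm_forward <- function(X, p, B, m, reverse = FALSE) {
  u <- ncol(p$Wh)/4L
  Xg <- sweep(X %*% p$Wx, 2, p$b, "+")
  H <- matrix(0, B * m, u)
  Gi <- matrix(0, B * m, u); Gf <- matrix(0, B * m, u)
  Gg <- matrix(0, B * m, u); Go <- matrix(0, B * m, u)
  Cs <- matrix(0, B * m, u); Cprev <- matrix(0, B * m, u)
  Hprev <- matrix(0, B * m, u)
  h <- matrix(0, B, u); cst <- matrix(0, B, u)
  order_t <- if (reverse) rev(seq_len(m)) else seq_len(m)
  ii <- seq_len(u); ifo <- u + ii; ig <- 2L * u + ii; io <- 3L * u + ii
  for (t in order_t) {
    rows <- seq(t, B * m, by = m)
    g <- Xg[rows, , drop = FALSE] + h %*% p$Wh
    i_g <- sigmoid(g[, ii, drop = FALSE])
    f_g <- sigmoid(g[, ifo, drop = FALSE])
    g_g <- tanh(g[, ig, drop = FALSE])
    o_g <- sigmoid(g[, io, drop = FALSE])
    Hprev[rows, ] <- h; Cprev[rows, ] <- cst
    cst <- f_g * cst + i_g * g_g
    h <- o_g * tanh(cst)
    H[rows, ] <- h; Gi[rows, ] <- i_g; Gf[rows, ] <- f_g
    Gg[rows, ] <- g_g; Go[rows, ] <- o_g; Cs[rows, ] <- cst
  }
  list(H = H, cache = list(X = X, Gi = Gi, Gf = Gf, Gg = Gg, Go = Go,
                           Cs = Cs, Cprev = Cprev, Hprev = Hprev,
                           B = B, m = m, reverse = reverse))
}

lstm_backward <- function(dH, p, cache) {
  u <- ncol(p$Wh)/4L
  B <- cache$B; m <- cache$m
  ii <- seq_len(u); ifo <- u + ii; ig <- 2L * u + ii; io <- 3L * u + ii
  dWh <- matrix(0, u, 4L * u)
  dG <- matrix(0, B * m, 4L * u)
  dh_next <- matrix(0, B, u); dc_next <- matrix(0, B, u)
  order_t <- if (cache$reverse) seq_len(m) else rev(seq_len(m))
  for (t in order_t) {
    rows <- seq(t, B * m, by = m)
    i_g <- cache$Gi[rows, , drop = FALSE]; f_g <- cache$Gf[rows, , drop = FALSE]
    g_g <- cache$Gg[rows, , drop = FALSE]; o_g <- cache$Go[rows, , drop = FALSE]
    cst <- cache$Cs[rows, , drop = FALSE]
    cprev <- cache$Cprev[rows, , drop = FALSE]
    hprev <- cache$Hprev[rows, , drop = FALSE]
    dh <- dH[rows, , drop = FALSE] + dh_next
    tc <- tanh(cst)
    do_pre <- dh * tc * o_g * (1 - o_g)
    dc <- dh * o_g * (1 - tc^2) + dc_next
    di_pre <- dc * g_g * i_g * (1 - i_g)
    df_pre <- dc * cprev * f_g * (1 - f_g)
    dg_pre <- dc * i_g * (1 - g_g^2)
    dG[rows, ii] <- di_pre; dG[rows, ifo] <- df_pre
    dG[rows, ig] <- dg_pre; dG[rows, io] <- do_pre
    dgate <- cbind(di_pre, df_pre, dg_pre, do_pre)
    dWh <- dWh + t(hprev) %*% dgate
    dh_next <- dgate %*% t(p$Wh)
    dc_next <- dc * f_g
  }
  list(dWx = t(cache$X) %*% dG, dWh = dWh, db = colSums(dG),
       dX = dG %*% t(p$Wx))
}

rnn_forward <- function(kind, ...) {
  if (kind == "GRU") gru_forward(...) else lstm_forward(...)
}
rnn_backward <- function(kind, ...) {
  if (kind == "GRU") gru_backward(...) else lstm_backward(...)
}

# Bidirectional wrapper: concatenated forward and reverse hidden states.
birnn_forward <- function(kind, X, pf, pb, B, m) {
  fw <- rnn_forward(kind, X, pf, B, m, reverse = FALSE)
  bw <- rnn_forward(kind, X, pb, B, m, reverse = TRUE)
  list(H = cbind(fw$H, bw$H), fw = fw, bw = bw)
}

birnn_backward <- function(kind, dH, pf, pb, fwd) {
  u <- ncol(fwd$fw$H)
  gf <- rnn_backward(kind, dH[, seq_len(u), drop = FALSE], pf, fwd$fw$cache)
  gb <- rnn_backward(kind, dH[, u + seq_len(u), drop = FALSE], pb, fwd$bw$cache)
  list(f = gf, b = gb, dX = gf$dX + gb$dX)
}

# ---- batch normalization -------------------------------------------------

bn_forward <- function(X, gamma, beta, running_mean, running_var,
                       training, momentum = 0.9, eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    v <- colMeans(sweep(X, 2, mu)^2)
    new_mean <- momentum * running_mean + (1 - momentum) * mu
    new_var <- momentum * running_var + (1 - momentum) * v
  } else {
    mu <- running_mean; v <- running_var
    new_mean <- running_mean; new_var <- running_var
  }
  istd <- 1 / sqrt(v + eps)
  Xc <- sweep(X, 2, mu)
  Xhat <- sweep(Xc, 2, istd, "*")
  Y <- sweep(sweep(Xhat, 2, gamma, "*"), 2, beta, "+")
  list(Y = Y, cache = list(Xhat = Xhat, istd = istd, gamma = gamma),
       running_mean = new_mean, running_var = new_var)
}

bn_backward <- function(dY, cache) {
  N <- nrow(dY)
  Xhat <- cache$Xhat
  dgamma <- colSums(dY * Xhat)
  dbeta <- colSums(dY)
  dXhat <- sweep(dY, 2, cache$gamma, "*")
  dX <- sweep(dXhat - matrix(colMeans(dXhat), N, ncol(dY), byrow = TRUE) -
              Xhat * matrix(colMeans(dXhat * Xhat), N, ncol(dY), byrow = TRUE),
              2, cache$istd, "*")
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- full network forward / backward ------------------------------------

# X_list: list of B input matrices (n x d0).  Returns probabilities
# (B x m) plus caches when training.
crnn_forward <- function(model, X_list, training = FALSE,
                         keep_cache = training) {
  cfg <- model$cfg; p <- model$params
  B <- length(X_list); m <- model$m
  idx <- conv_patch_index(model$n, model$d0, cfg$kernel_size, cfg$stride_time)
  Z <- do.call(rbind, lapply(X_list, function(X) {
    matrix(X[idx], nrow = m)
  }))                                               # (B*m) x (k*d0), b-major
  # reorder to segment-major rows (b-1)*m + t: rbind already gives that
  A <- sweep(Z %*% p$conv_W, 2, p$conv_b, "+")
  relu_mask <- A > 0
  C1 <- A * relu_mask
  r1 <- birnn_forward(cfg$recurrent_kind, C1, p$rnn1_f, p$rnn1_b, B, m)
  drop1 <- NULL
  H1 <- r1$H
  if (training && cfg$dropout_rate > 0) {
    drop1 <- matrix(stats::rbinom(length(H1), 1, 1 - cfg$dropout_rate),
                    nrow(H1), ncol(H1)) / (1 - cfg$dropout_rate)
    H1 <- H1 * drop1
  }
  b1 <- bn_forward(H1, p$bn1_gamma, p$bn1_beta, model$running$bn1_mean,
                   model$running$bn1_var, training)
  r2 <- birnn_forward(cfg$recurrent_kind, b1$Y, p$rnn2_f, p$rnn2_b, B, m)
  drop2 <- NULL
  H2 <- r2$H
  if (training && cfg$dropout_rate > 0) {
    drop2 <- matrix(stats::rbinom(length(H2), 1, 1 - cfg$dropout_rate),
                    nrow(H2), ncol(H2)) / (1 - cfg$dropout_rate)
    H2 <- H2 * drop2
  }
  b2 <- bn_forward(H2, p$bn2_gamma, p$bn2_beta, model$running$bn2_mean,
                   model$running$bn2_var, training)
  logits <- sweep(b2$Y %*% p$dense_W, 2, p$dense_b, "+")
  probs <- matrix(sigmoid(logits), B, m, byrow = TRUE)
  out <- list(probs = probs, B = B)
  if (training) {
    model$running$bn1_mean <- b1$running_mean
    model$running$bn1_var <- b1$running_var
    model$running$bn2_mean <- b2$running_mean
    model$running$bn2_var <- b2$running_var
  }
  if (keep_cache)
    out$cache <- list(Z = Z, relu_mask = relu_mask, r1 = r1, drop1 = drop1,
                      b1 = b1, r2 = r2, drop2 = drop2, b2 = b2,
                      bn2_Y = b2$Y, logits = logits)
  out$model <- model
  out
}

# Binary cross-entropy over all timesteps; y is a length-B 0/1 vector
# (targets repeated across the m steps).  Returns loss and parameter grads.
crnn_loss_grads <- function(model, X_list, y) {
  cfg <- model$cfg; p <- model$params
  B <- length(X_list); m <- model$m
  fw <- crnn_forward(model, X_list, training = TRUE)
  model <- fw$model
  cache <- fw$cache
  probs_flat <- sigmoid(cache$logits)               # (B*m) x 1, segment-major
  y_flat <- rep(y, each = m)
  eps <- 1e-12
  loss <- -mean(y_flat * log(probs_flat + eps) +
                (1 - y_flat) * log(1 - probs_flat + eps))
  dlogit <- (probs_flat - y_flat) / (B * m)
  g <- list()
  g$dense_W <- t(cache$bn2_Y) %*% dlogit
  g$dense_b <- sum(dlogit)
  dY2 <- dlogit %*% t(p$dense_W)
  bb2 <- bn_backward(dY2, cache$b2$cache)
  g$bn2_gamma <- bb2$dgamma; g$bn2_beta <- bb2$dbeta
  dH2 <- bb2$dX
  if (!is.null(cache$drop2)) dH2 <- dH2 * cache$drop2
  r2g <- birnn_backward(cfg$recurrent_kind, dH2, p$rnn2_f, p$rnn2_b, cache$r2)
  g$rnn2_f <- r2g$f[c("dWx", "dWh", "db")]
  g$rnn2_b <- r2g$b[c("dWx", "dWh", "db")]
  bb1 <- bn_backward(r2g$dX, cache$b1$cache)
  g$bn1_gamma <- bb1$dgamma; g$bn1_beta <- bb1$dbeta
  dH1 <- bb1$dX
  if (!is.null(cache$drop1)) dH1 <- dH1 * cache$drop1
  r1g <- birnn_backward(cfg$recurrent_kind, dH1, p$rnn1_f, p$rnn1_b, cache$r1)
  g$rnn1_f <- r1g$f[c("dWx", "dWh", "db")]
  g$rnn1_b <- r1g$b[c("dWx", "dWh", "db")]
  dC1 <- r1g$dX * cache$relu_mask
  g$conv_W <- t(cache$Z) %*% dC1
  g$conv_b <- colSums(dC1)
  list(loss = loss, grads = g, model = model, probs = fw$probs)
}

# ---- Adam optimizer ------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0)
}

# Map grads (which use dWx/dWh/db inside rnn sublists) onto param names.
grad_for <- function(gsub) {
  if (is.list(gsub) && !is.null(gsub$dWx))
    list(Wx = gsub$dWx, Wh = gsub$dWh, b = gsub$db)
  else gsub
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  upd <- function(p, gr, mm, vv) {
    if (is.list(p)) {
      out_p <- p; out_m <- mm; out_v <- vv
      for (nm in names(p)) {
        r <- upd(p[[nm]], gr[[nm]], mm[[nm]], vv[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    mm <- beta1 * mm + (1 - beta1) * gr
    vv <- beta2 * vv + (1 - beta2) * gr^2
    mhat <- mm / (1 - beta1^state$t)
    vhat <- vv / (1 - beta2^state$t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = mm, v = vv)
  }
  for (nm in names(params)) {
    gr <- grad_for(grads[[nm]])
    r <- upd(params[[nm]], gr, state$m[[nm]], state$v[[nm]])
    params[[nm]] <- r$p; state$m[[nm]] <- r$m; state$v[[nm]] <- r$v
  }
  list(params = params, state = state)
}

# ---- training loop -------------------------------------------------------

#' Train a CRNN on labeled 10-s segments
#'
#' Minimizes per-timestep binary cross-entropy with Adam.  Training is a
#' pure function of (model, data, config seed); a NaN loss aborts with
#' diagnostics.
#'
#' @param model a [build_crnn()] model.
#' @param spectrograms list of training `spectrogram`s (or magnitude
#'   matrices), each `f x n`.
#' @param labels 0/1 vector (1 = ON), one per segment.
#' @param verbose print per-epoch loss?
#' @return The trained model, with a `training_log` data frame attached.
#' @export
train_crnn <- function(model, spectrograms, labels, verbose = FALSE) {
  cfg <- model$cfg
  if (length(spectrograms) != length(labels))
    stopf("got %d segments but %d labels", length(spectrograms), length(labels))
  if (length(unique(labels)) < 2)
    stopf("training data must contain both classes")
  X_all <- crnn_inputs(model, spectrograms)
  n_seg <- length(X_all)
  opt <- adam_init(model$params)
  log <- data.frame(epoch = integer(0), loss = numeric(0))
  with_seed(mix_seed(cfg$seed, 4242L), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(n_seg)
      losses <- numeric(0)
      for (start in seq(1, n_seg, by = cfg$batch_size)) {
        take <- ord[start:min(start + cfg$batch_size - 1, n_seg)]
        res <- crnn_loss_grads(model, X_all[take], labels[take])
        if (!is.finite(res$loss))
          stopf("training diverged (loss = %s) at epoch %d", res$loss, ep)
        model <- res$model
        stepped <- adam_step(model$params, res$grads, opt, cfg$learning_rate)
        model$params <- stepped$params
        opt <- stepped$state
        losses <- c(losses, res$loss)
      }
      log <- rbind(log, data.frame(epoch = ep, loss = mean(losses)))
      if (verbose) message(sprintf("epoch %d: loss %.4f", ep, mean(losses)))
    }
  })
  model$training_log <- log
  model
}

#' Predict per-timestep ON probabilities
#'
#' @param model a trained `crnn_model`.
#' @param spectrograms list of `spectrogram`s (or magnitude matrices).
#' @return Matrix (segments x m) of probabilities in (0, 1).
#' @export
predict_crnn <- function(model, spectrograms) {
  X <- crnn_inputs(model, spectrograms)
  crnn_forward(model, X, training = FALSE)$probs
}
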