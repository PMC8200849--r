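# Feature-level statistics: paired t-tests per attribute, pairwise
# attribute correlations, and seeded 2-D embeddings per protocol.

#' Paired t-tests per phonological attribute
#'
#' Tests, attribute by attribute, whether the posterior features differ
#' between the ON and OFF states.  Rows of `on` and `off` are paired
#' observations (default pairing unit: mean posterior per
#' patient x protocol).  The t sign convention is mean(ON) - mean(OFF).
#' Zero-variance differences yield `t = +/-Inf` with `p = 0` (documented
#' degenerate convention); Bonferroni-adjusted p-values are reported
#' alongside raw ones.
#'
#' @param on,off numeric matrices (pairs x attributes) with identical
#'   dimensions and column names.
#' @return Data frame (attribute, t, p, p_adjusted, mean_on, mean_off)
#'   sorted by decreasing `|t|`.
#' @export
attribute_ttest <- function(on, off) {
  on <- as.matrix(on); off <- as.matrix(off)
  if (!identical(dim(on), dim(off)))
    stopf("ON and OFF matrices must have identical dimensions")
  n <- nrow(on)
  if (n < 2) stopf("need at least 2 pairs (got %d)", n)
  d <- on - off
  t_stat <- p <- numeric(ncol(d))
  for (j in seq_len(ncol(d))) {
    dj <- d[, j]
    sdj <- stats::sd(dj)
    if (sdj == 0) {
      t_stat[j] <- if (mean(dj) == 0) 0 else sign(mean(dj)) * Inf
      p[j] <- if (mean(dj) == 0) 1 else 0
    } else {
      t_stat[j] <- mean(dj) / (sdj / sqrt(n))
      p[j] <- 2 * stats::pt(-abs(t_stat[j]), df = n - 1)
    }
  }
  res <- data.frame(attribute = colnames(on) %||% paste0("attr", seq_len(ncol(on))),
                    t = t_stat, p = p,
                    p_adjusted = stats::p.adjust(p, method = "bonferroni"),
                    mean_on = colMeans(on), mean_off = colMeans(off),
                    row.names = NULL)
  res[order(-abs(res$t)), ]
}

#' Correlation between two attribute posterior trajectories
#'
#' Pearson correlation between the two attributes' posterior time series,
#' concatenated over the given streams (one state, one protocol).  A
#' zero-variance series yields `NA` with a `degenerate` flag.
#'
#' @param streams list of [posterior_stream()]s.
#' @param attr_i,attr_j attribute names.
#' @return List with `r`, `attributes`, `n_frames`, `degenerate`.
#' @export
attribute_correlation <- function(streams, attr_i, attr_j) {
  if (inherits(streams, "posterior_stream")) streams <- list(streams)
  xs <- unlist(lapply(streams, function(s) s$posteriors[, attr_i]))
  ys <- unlist(lapply(streams, function(s) s$posteriors[, attr_j]))
  if (length(xs) < 2) stopf("need at least 2 frames")
  degenerate <- stats::sd(xs) == 0 || stats::sd(ys) == 0
  r <- if (degenerate) NA_real_ else stats::cor(xs, ys)
  list(r = r, attributes = c(attr_i, attr_j), n_frames = length(xs),
       degenerate = degenerate)
}

# ---- t-SNE (exact, small-n) ---------------------------------------------

# Conditional-probability row for one point at a given precision.
tsne_prob_row <- function(d2row, beta) {
  p <- exp(-d2row * beta)
  s <- sum(p)
  if (s == 0) p else p / s
}

# Binary search for the precision giving the target perplexity.
tsne_calibrate <- function(D2, perplexity) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; bmin <- -Inf; bmax <- Inf
    d2 <- D2[i, -i]
    for (iter in 1:50) {
      p <- tsne_prob_row(d2, beta)
      H <- -sum(ifelse(p > 0, p * log(p), 0))
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { bmin <- beta; beta <- if (is.finite(bmax)) (beta + bmax) / 2 else beta * 2 }
      else { bmax <- beta; beta <- if (is.finite(bmin)) (beta + bmin) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P
}

# Exact t-SNE by momentum gradient descent; n is small (segments per
# protocol), so the O(n^2) formulation is appropriate.
tsne_embed <- function(X, perplexity = 10, n_iter = 400, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  perplexity <- max(perplexity, 2)
  D2 <- as.matrix(stats::dist(X))^2
  P <- tsne_calibrate(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    inc <- matrix(0, n, 2)
    momentum <- 0.5
    ex <- 4                                          # early exaggeration
    for (iter in seq_len(n_iter)) {
      if (iter == 100) ex <- 1
      if (iter == 250) momentum <- 0.8
      D2y <- as.matrix(stats::dist(Y))^2
      Qnum <- 1 / (1 + D2y); diag(Qnum) <- 0
      Q <- pmax(Qnum / sum(Qnum), 1e-12)
      W <- (ex * P - Q) * Qnum
      grad <- 4 * (diag(rowSums(W)) - W) %*% Y
      inc <- momentum * inc - 200 * grad
      Y <- Y + inc
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

#' Embed one protocol's segments in 2-D
#'
#' Embeds per-segment mean posterior vectors with a seeded stochastic
#' neighbor embedding and reports a separability score: the accuracy of
#' nearest-centroid classification in the embedded plane.
#'
#' @param features numeric matrix (segments x attributes) of per-segment
#'   mean posteriors.
#' @param states character vector of `"ON"`/`"OFF"` labels per segment.
#' @param perplexity embedding perplexity.
#' @param seed integer seed (same seed, same coordinates).
#' @param min_segments minimum segments per class; below it the protocol
#'   is skipped with a warning and `NULL` is returned.
#' @return List with `coords` (segments x 2), `states`, `separability`.
#' @export
embed_protocol <- function(features, states, perplexity = 10, seed = 1L,
                           min_segments = 5) {
  counts <- table(states)
  if (length(counts) < 2 || any(counts < min_segments)) {
    warning(sprintf("too few segments per class (%s); embedding skipped",
                    paste(counts, collapse = "/")))
    return(NULL)
  }
  Y <- tsne_embed(features, perplexity = perplexity, seed = seed)
  cen_on <- colMeans(Y[states == "ON", , drop = FALSE])
  cen_off <- colMeans(Y[states == "OFF", , drop = FALSE])
  d_on <- sqrt(rowSums(sweep(Y, 2, cen_on)^2))
  d_off <- sqrt(rowSums(sweep(Y, 2, cen_off)^2))
  calls <- ifelse(d_on < d_off, "ON", "OFF")
  list(coords = Y, states = states, separability = mean(calls == states))
}

#' Plot a 2-D protocol embedding
#'
#' @param embedding result of [embed_protocol()].
#' @param main plot title.
#' @return The embedding, invisibly.
#' @export
plot_embedding <- function(embedding, main = "protocol embedding") {
  if (is.null(embedding)) return(invisible(NULL))
  cols <- ifelse(embedding$states == "ON", "#1b7837", "#762a83")
  graphics::plot(embedding$coords, col = cols, pch = 19,
                 xlab = "dim 1", ylab = "dim 2",
                 main = sprintf("%s (separability %.2f)", main,
                                embedding$separability))
  graphics::legend("topright", legend = c("ON", "OFF"), pch = 19,
                   col = c("#1b7837", "#762a83"), bty = "n")
  invisible(embedding)
}

#' Per-segment mean posterior features for a set of streams
#'
#' Splits each stream into consecutive windows of `frames_per_segment`
#' frames and returns the per-window mean posterior vector.
#'
#' @param streams list of [posterior_stream()]s.
#' @param frames_per_segment window length in frames (default 200 frames
#'   = 2 s at the 10-ms frame period).
#' @return Matrix (segments x attributes).
#' @export
segment_mean_posteriors <- function(streams, frames_per_segment = 200) {
  if (inherits(streams, "posterior_stream")) streams <- list(streams)
  rows <- lapply(streams, function(s) {
    n <- nrow(s$posteriors)
    k <- n %/% frames_per_segment
    if (k == 0) return(NULL)
    t(vapply(seq_len(k), function(i) {
      colMeans(s$posteriors[((i - 1) * frames_per_segment + 1):
                            (i * frames_per_segment), , drop = FALSE])
    }, numeric(ncol(s$posteriors))))
  })
  do.call(rbind, rows)
}
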