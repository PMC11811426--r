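# Independent oracles used to cross-check the implementation. These are
# written from the definitions (naive DFT, explicit triangles, dense matrix
# products) and deliberately share no code with the package internals.

# Naive-DFT MFCC oracle: explicit cos/sin transform matrices, loop-built
# triangular filters, direct DCT-II sum.
oracle_mfcc <- function(x, sr, cfg = mfcc_config()) {
  a <- cfg$pre_emphasis
  y <- numeric(length(x))
  y[1] <- x[1]
  for (n in 2:length(x)) y[n] <- x[n] - a * x[n - 1]
  fl <- round(cfg$frame_length * sr)
  hp <- round(cfg$hop_length * sr)
  nf <- if (is.null(cfg$n_fft)) 2^ceiling(log2(fl)) else cfg$n_fft
  k_ <- 0:(fl - 1)
  win <- if (cfg$window == "hamming") {
    0.54 - 0.46 * cos(2 * pi * k_ / (fl - 1))
  } else {
    0.5 - 0.5 * cos(2 * pi * k_ / (fl - 1))
  }
  n_frames <- (length(y) - fl) %/% hp + 1
  bins <- 0:(nf / 2)
  ang <- -2 * pi * outer(bins, 0:(nf - 1)) / nf
  C <- cos(ang)
  S <- sin(ang)
  m2h <- function(m) 700 * (10^(m / 2595) - 1)
  h2m <- function(f) 2595 * log10(1 + f / 700)
  edges <- m2h(seq(0, h2m(sr / 2), length.out = cfg$n_mels + 2))
  freqs <- bins * sr / nf
  out <- matrix(0, n_frames, cfg$n_mfcc)
  M <- cfg$n_mels
  for (i in seq_len(n_frames)) {
    fr <- c(y[((i - 1) * hp + 1):((i - 1) * hp + fl)] * win, rep(0, nf - fl))
    P <- ((C %*% fr)^2 + (S %*% fr)^2) / nf
    E <- numeric(M)
    for (m in seq_len(M)) {
      w <- numeric(length(freqs))
      for (b in seq_along(freqs)) {
        f <- freqs[b]
        if (f >= edges[m] && f <= edges[m + 1]) {
          w[b] <- (f - edges[m]) / (edges[m + 1] - edges[m])
        } else if (f > edges[m + 1] && f <= edges[m + 2]) {
          w[b] <- (edges[m + 2] - f) / (edges[m + 2] - edges[m + 1])
        }
      }
      E[m] <- log(max(sum(w * P), cfg$log_floor))
    }
    for (k in 0:(cfg$n_mfcc - 1)) {
      ak <- if (k == 0) sqrt(1 / M) else sqrt(2 / M)
      out[i, k + 1] <- ak * sum(E * cos(pi * k * (2 * (0:(M - 1)) + 1) / (2 * M)))
    }
  }
  out
}

# Autocorrelation pitch tracker (independent of the generator's model).
oracle_pitch <- function(x, sr, fmin = 70, fmax = 350) {
  ac <- stats::acf(x, lag.max = floor(sr / fmin), plot = FALSE,
                   demean = TRUE)$acf[-1]
  lo <- ceiling(sr / fmax)
  lag <- which.max(ac[lo:length(ac)]) + lo - 1
  sr / lag
}

# Mean inter-frame absolute difference of a clip (motion-energy statistic).
clip_motion <- function(clip) {
  TT <- dim(clip)[1]
  mean(abs(clip[-1, , , , drop = FALSE] - clip[-TT, , , , drop = FALSE]))
}

# Best accuracy over all thresholds of a scalar statistic (either sign).
oracle_threshold_acc <- function(stat, labels) {
  max(vapply(stat, function(th) {
    a <- mean((stat <= th) == (labels == 1))
    max(a, 1 - a)
  }, numeric(1)))
}

# Brute-force edge enumeration for the frame-similarity graph.
oracle_graph_edges <- function(X, threshold, threshold_on, weight_cap) {
  n <- nrow(X)
  edges <- NULL
  weights <- numeric(0)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        d <- sqrt(sum((X[i, ] - X[j, ])^2))
        keep <- if (threshold_on == "similarity") 1 / (1 + d) >= threshold else d <= threshold
        if (keep) {
          edges <- rbind(edges, c(i, j))
          weights <- c(weights, if (d == 0) weight_cap else min(1 / d, weight_cap))
        }
      }
    }
  }
  list(edges = if (is.null(edges)) matrix(integer(0), 0, 2) else edges,
       weights = weights)
}

# Dense normalised-adjacency GCN oracle, built by loops from the definition.
oracle_gcn <- function(X, g, W) {
  n <- g$n_nodes
  A <- matrix(0, n, n)
  if (nrow(g$edges) > 0) {
    for (e in seq_len(nrow(g$edges))) {
      i <- g$edges[e, 1]; j <- g$edges[e, 2]
      A[i, j] <- g$weights[e]
      A[j, i] <- g$weights[e]
    }
  }
  At <- A + diag(n)
  D <- diag(1 / sqrt(rowSums(At)), n)
  Z <- D %*% At %*% D %*% X %*% W
  Z[Z < 0] <- 0
  Z
}

# Trapezoid AUC from first principles (rank statistic).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
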