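# MFCC extraction and frame-similarity graph construction.
#
# The MFCC pipeline runs in the classical order: pre-emphasis -> framing ->
# windowing -> FFT -> power spectrum -> Mel filterbank -> log -> DCT-II.
# Conventions fixed here (and mirrored by the test oracle): power spectrum
# P_k = |X_k|^2 / n_fft over bins 0..n_fft/2; triangular Mel filters defined
# on exact bin frequencies between mel-spaced edge points; natural log with
# a floor; orthonormal DCT-II.

#' MFCC extraction settings
#'
#' Defaults are standard speech-processing values: 0.97 pre-emphasis, 25 ms
#' frames with a 10 ms hop, Hamming window, 26 Mel filters, 13 kept
#' coefficients.
#'
#' @param pre_emphasis First-order pre-emphasis coefficient in `[0, 1)`.
#' @param frame_length Frame length in seconds.
#' @param hop_length Hop between frame starts in seconds.
#' @param window `"hamming"` or `"hann"`.
#' @param n_fft FFT size; `NULL` picks the next power of two at or above the
#'   frame length in samples.
#' @param n_mels Number of triangular Mel filters.
#' @param n_mfcc Number of cepstral coefficients kept (`<= n_mels`).
#' @param log_floor Floor applied to filter energies before the log.
#' @return An object of class `mfcc_config`.
#' @export
mfcc_config <- function(pre_emphasis = 0.97, frame_length = 0.025,
                        hop_length = 0.010, window = c("hamming", "hann"),
                        n_fft = NULL, n_mels = 26, n_mfcc = 13,
                        log_floor = 1e-10) {
  window <- match.arg(window)
  if (pre_emphasis < 0 || pre_emphasis >= 1) stop("pre_emphasis must be in [0, 1)")
  if (frame_length < hop_length) stop("frame_length must be >= hop_length")
  if (n_mfcc > n_mels) stop("n_mfcc must not exceed n_mels")
  if (log_floor <= 0) stop("log_floor must be positive")
  structure(list(pre_emphasis = pre_emphasis, frame_length = frame_length,
                 hop_length = hop_length, window = window, n_fft = n_fft,
                 n_mels = as.integer(n_mels), n_mfcc = as.integer(n_mfcc),
                 log_floor = log_floor),
            class = "mfcc_config")
}

#' First-order pre-emphasis filter
#'
#' `y[1] = x[1]`, `y[n] = x[n] - a * x[n-1]`; linear in the input.
#'
#' @param x Numeric waveform.
#' @param coef Pre-emphasis coefficient.
#' @return Filtered waveform of the same length.
#' @export
pre_emphasize <- function(x, coef = 0.97) {
  if (length(x) == 0) stop("empty waveform")
  c(x[1], x[-1] - coef * x[-length(x)])
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# n_mels x (n_fft/2 + 1) triangular filterbank on exact bin frequencies.
mel_filterbank <- function(sr, n_fft, n_mels) {
  edges <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(sr / 2), length.out = n_mels + 2))
  freqs <- (0:(n_fft / 2)) * sr / n_fft
  fb <- matrix(0, n_mels, length(freqs))
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; mid <- edges[m + 1]; hi <- edges[m + 2]
    up <- (freqs - lo) / (mid - lo)
    down <- (hi - freqs) / (hi - mid)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II matrix (n_keep x n_in).
dct2_matrix <- function(n_in, n_keep) {
  k <- 0:(n_keep - 1)
  m <- 0:(n_in - 1)
  mat <- sqrt(2 / n_in) * cos(pi * outer(k, 2 * m + 1) / (2 * n_in))
  mat[1, ] <- mat[1, ] / sqrt(2)
  mat
}

#' Compute per-frame MFCC features
#'
#' @param waveform Mono numeric waveform.
#' @param sr Sampling rate in Hz.
#' @param cfg An [mfcc_config()].
#' @return An object of class `mfcc_matrix`: list with `values`
#'   (`n_frames x n_mfcc`) and `frame_times` (frame centres in seconds).
#' @export
compute_mfcc <- function(waveform, sr, cfg = mfcc_config()) {
  stopifnot(inherits(cfg, "mfcc_config"))
  frame_n <- as.integer(round(cfg$frame_length * sr))
  hop_n <- as.integer(round(cfg$hop_length * sr))
  if (length(waveform) < frame_n) {
    stop("waveform shorter than one frame (", length(waveform), " < ", frame_n, ")")
  }
  n_fft <- cfg$n_fft
  if (is.null(n_fft)) n_fft <- 2^ceiling(log2(frame_n))
  if (n_fft < frame_n) stop("n_fft must be at least the frame length in samples")

  y <- pre_emphasize(waveform, cfg$pre_emphasis)
  n_frames <- (length(y) - frame_n) %/% hop_n + 1L
  starts <- (seq_len(n_frames) - 1L) * hop_n + 1L
  frames <- matrix(0, frame_n, n_frames)
  for (i in seq_len(n_frames)) {
    frames[, i] <- y[starts[i]:(starts[i] + frame_n - 1L)]
  }
  win <- switch(cfg$window,
                hamming = signal::hamming(frame_n),
                hann = signal::hanning(frame_n))
  frames <- frames * win
  padded <- rbind(frames, matrix(0, n_fft - frame_n, n_frames))
  spec <- stats::mvfft(padded)[1:(n_fft / 2 + 1), , drop = FALSE]
  power <- (Mod(spec)^2) / n_fft
  fb <- mel_filterbank(sr, n_fft, cfg$n_mels)
  energies <- fb %*% power                       # n_mels x n_frames
  logE <- log(pmax(energies, cfg$log_floor))
  dct <- dct2_matrix(cfg$n_mels, cfg$n_mfcc)
  values <- t(dct %*% logE)                      # n_frames x n_mfcc
  structure(list(values = values,
                 frame_times = (starts - 1L + frame_n / 2) / sr),
            class = "mfcc_matrix")
}

#' Similarity between two MFCC frame vectors
#'
#' `s = 1 / (1 + d)` with `d` the Euclidean distance, so `s` is in `(0, 1]`,
#' strictly decreasing in `d`, and equals 1 exactly for identical frames.
#' `s >= 0.5` is equivalent to `d <= 1`.
#'
#' @param a,b Equal-length numeric vectors.
#' @return Similarity in `(0, 1]`.
#' @export
frame_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("frame vectors have different lengths")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("non-finite frame vector")
  1 / (1 + sqrt(sum((a - b)^2)))
}

#' Build the frame-similarity graph over MFCC frames
#'
#' Nodes are per-frame MFCC vectors in temporal order. With the default
#' `"similarity"` semantics an edge joins frames `i < j` iff
#' `1/(1 + d_ij) >= threshold`; with `"distance"` semantics iff
#' `d_ij <= threshold`. Edge weights are the inverse distance `1/d`, capped
#' at `weight_cap` (identical frames get the cap).
#'
#' @param mfcc An `mfcc_matrix` (or a plain numeric matrix of node features).
#' @param threshold Edge threshold; in `(0, 1]` for similarity semantics.
#' @param weight_cap Upper bound on edge weights.
#' @param threshold_on Interpret `threshold` on the similarity or directly on
#'   the Euclidean distance.
#' @param stride Keep every `stride`-th frame before building the graph.
#' @return An object of class `audio_graph`: `node_features`, `edges`
#'   (`m x 2`, `i < j`), `weights`, `node_order`, `n_nodes`.
#' @export
build_graph <- function(mfcc, threshold = 0.5, weight_cap = 1e6,
                        threshold_on = c("similarity", "distance"),
                        stride = 1L) {
  threshold_on <- match.arg(threshold_on)
  X <- if (inherits(mfcc, "mfcc_matrix")) mfcc$values else as.matrix(mfcc)
  if (nrow(X) < 1) stop("empty MFCC matrix")
  if (threshold_on == "similarity" && (threshold <= 0 || threshold > 1)) {
    stop("similarity threshold must be in (0, 1]")
  }
  if (threshold_on == "distance" && threshold < 0) {
    stop("distance threshold must be nonnegative")
  }
  if (weight_cap <= 0) stop("weight_cap must be positive")
  keep <- seq(1, nrow(X), by = as.integer(stride))
  X <- X[keep, , drop = FALSE]
  n <- nrow(X)
  edges <- matrix(integer(0), 0, 2)
  weights <- numeric(0)
  if (n > 1) {
    d <- as.matrix(stats::dist(X))
    keep_edge <- if (threshold_on == "similarity") {
      1 / (1 + d) >= threshold
    } else {
      d <= threshold
    }
    ij <- which(upper.tri(d) & keep_edge, arr.ind = TRUE)
    if (nrow(ij) > 0) {
      ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
      edges <- unname(ij)
      dv <- d[cbind(edges[, 1], edges[, 2])]
      weights <- ifelse(dv == 0, weight_cap, pmin(1 / dv, weight_cap))
    }
  }
  structure(list(node_features = X, edges = edges, weights = weights,
                 node_order = seq_len(n), n_nodes = n),
            class = "audio_graph")
}

#' Convert an audio graph to an igraph object
#'
#' @param g An `audio_graph`.
#' @return A weighted undirected `igraph` graph with node order as vertex ids.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "audio_graph"))
  ig <- igraph::make_empty_graph(n = g$n_nodes, directed = FALSE)
  if (nrow(g$edges) > 0) {
    ig <- igraph::add_edges(ig, t(g$edges), weight = g$weights)
  }
  ig
}

#' Write an audio graph as portable text files
#'
#' Edges go to `<stem>.edges` as `node_i node_j weight` lines; node features
#' to `<stem>.nodes` as a tab-delimited table in temporal order.
#'
#' @param g An `audio_graph`.
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_audio_graph <- function(g, stem) {
  stopifnot(inherits(g, "audio_graph"))
  edge_df <- data.frame(i = g$edges[, 1], j = g$edges[, 2], w = g$weights)
  utils::write.table(edge_df, paste0(stem, ".edges"), row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  utils::write.table(g$node_features, paste0(stem, ".nodes"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(stem)
}

#' Read an audio graph written by [write_audio_graph()]
#'
#' @param stem Path stem used when writing.
#' @return An `audio_graph`.
#' @export
read_audio_graph <- function(stem) {
  X <- as.matrix(utils::read.table(paste0(stem, ".nodes")))
  dimnames(X) <- NULL
  epath <- paste0(stem, ".edges")
  info <- file.info(epath)
  if (!is.na(info$size) && info$size > 0) {
    e <- utils::read.table(epath)
    edges <- unname(as.matrix(e[, 1:2]))
    weights <- e[, 3]
  } else {
    edges <- matrix(integer(0), 0, 2)
    weights <- numeric(0)
  }
  structure(list(node_features = X, edges = edges, weights = weights,
                 node_order = seq_len(nrow(X)), n_nodes = nrow(X)),
            class = "audio_graph")
}
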