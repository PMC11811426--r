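# GCN-LSTM over the MFCC frame-similarity graph.
#
# Graph convolutions use the symmetric-normalised propagation rule with
# self-loops, A_hat = D^{-1/2} (A_w + I) D^{-1/2}, on the weighted adjacency;
# stacked layers (no bias) with ReLU produce node embeddings, which are read
# in temporal node order (optionally strided) by an LSTM. The final hidden
# state passes through a fully connected projection to the audio feature
# vector F_A, dropout, and the dual head (binary logit + PHQ-8 scalar).

#' Configuration for the audio network
#'
#' @param n_mfcc Dimension of the node features.
#' @param gcn_layers Number of stacked graph convolutions (at least 1).
#' @param gcn_hidden Width of the graph convolutions.
#' @param lstm_hidden Width of the LSTM state.
#' @param feature_dim Length of the exported feature vector `F_A`.
#' @param dropout Dropout before the heads, within `[0.4, 0.6]`.
#' @param subsample Temporal stride applied to the node-embedding sequence
#'   before the LSTM.
#' @param arch `"gcn_lstm"` (default), `"gcn_only"` (mean-pooled graph
#'   embeddings, no recurrence), or `"lstm_only"` (LSTM directly on the MFCC
#'   sequence, no graph convolution).
#' @return An object of class `gcnlstm_config`.
#' @export
gcnlstm_config <- function(n_mfcc = 13, gcn_layers = 2, gcn_hidden = 32,
                           lstm_hidden = 32, feature_dim = 32, dropout = 0.5,
                           subsample = 1,
                           arch = c("gcn_lstm", "gcn_only", "lstm_only")) {
  arch <- match.arg(arch)
  if (gcn_layers < 1) stop("gcn_layers must be at least 1")
  if (dropout < 0.4 || dropout > 0.6) stop("dropout must lie in [0.4, 0.6]")
  structure(list(n_mfcc = as.integer(n_mfcc),
                 gcn_layers = as.integer(gcn_layers),
                 gcn_hidden = as.integer(gcn_hidden),
                 lstm_hidden = as.integer(lstm_hidden),
                 feature_dim = as.integer(feature_dim), dropout = dropout,
                 subsample = as.integer(subsample), arch = arch),
            class = "gcnlstm_config")
}

#' Symmetric-normalised adjacency with self-loops
#'
#' `A_hat = D^{-1/2} (A_w + I) D^{-1/2}` where `A_w` is the weighted
#' adjacency of the graph and `D` the degree matrix of `A_w + I`.
#'
#' @param g An `audio_graph`.
#' @return Dense `n x n` symmetric matrix.
#' @export
normalized_adjacency <- function(g) {
  stopifnot(inherits(g, "audio_graph"))
  n <- g$n_nodes
  A <- matrix(0, n, n)
  if (nrow(g$edges) > 0) {
    A[g$edges] <- g$weights
    A[g$edges[, c(2, 1), drop = FALSE]] <- g$weights
  }
  A <- A + diag(n)
  dinv <- 1 / sqrt(rowSums(A))
  A * outer(dinv, dinv)
}

#' One graph convolution layer
#'
#' `ReLU(A_hat X W)` with the symmetric-normalised self-loop adjacency.
#'
#' @param X Node-feature matrix (`n_nodes x d_in`).
#' @param g An `audio_graph` over the same nodes.
#' @param W Weight matrix (`d_in x d_out`).
#' @return Matrix of node embeddings (`n_nodes x d_out`).
#' @export
gcn_layer <- function(X, g, W) {
  if (nrow(X) != g$n_nodes) stop("row count of X must equal the node count")
  if (ncol(X) != nrow(W)) stop("feature/weight dimension mismatch")
  pmax(normalized_adjacency(g) %*% X %*% W, 0)
}

gcn_fwd <- function(X, Ahat, p, nm, g = NULL) {
  W <- p[[paste0(nm, ".W")]]
  AX <- Ahat %*% X
  pre <- AX %*% W
  out <- pmax(pre, 0)
  list(out = out, bwd = function(dout) {
    dpre <- dout
    dpre[pre <= 0] <- 0
    g_acc(g, paste0(nm, ".W"), crossprod(AX, dpre))
    Ahat %*% (dpre %*% t(W))   # Ahat symmetric
  })
}

# ---- LSTM ----------------------------------------------------------------

lstm_init <- function(p, nm, d_in, h) {
  sc <- sqrt(1 / max(d_in, h))
  p[[paste0(nm, ".Wx")]] <- init_mat(d_in, 4 * h, scale = sc)
  p[[paste0(nm, ".Wh")]] <- init_mat(h, 4 * h, scale = sc)
  b <- rep(0, 4 * h)
  b[(h + 1):(2 * h)] <- 1          # forget-gate bias
  p[[paste0(nm, ".b")]] <- b
  p
}

# x: array (steps, batch, d_in); lengths: per-sample valid lengths.
# Gate order in the 4h block: input, forget, output, candidate.
lstm_fwd <- function(x, lengths, p, nm, g = NULL) {
  d <- dim(x)
  TT <- d[1]; N <- d[2]; D <- d[3]
  Wx <- p[[paste0(nm, ".Wx")]]
  Wh <- p[[paste0(nm, ".Wh")]]
  b <- p[[paste0(nm, ".b")]]
  h <- nrow(Wh)
  H <- matrix(0, N, h)
  Cc <- matrix(0, N, h)
  cache <- vector("list", TT)
  for (t in seq_len(TT)) {
    m <- as.numeric(lengths >= t)
    Xt <- matrix(x[t, , ], N, D)
    Z <- Xt %*% Wx + H %*% Wh
    Z <- sweep(Z, 2, b, `+`)
    i_g <- sigmoid(Z[, 1:h, drop = FALSE])
    f_g <- sigmoid(Z[, (h + 1):(2 * h), drop = FALSE])
    o_g <- sigmoid(Z[, (2 * h + 1):(3 * h), drop = FALSE])
    c_g <- tanh(Z[, (3 * h + 1):(4 * h), drop = FALSE])
    C_new <- f_g * Cc + i_g * c_g
    H_new <- o_g * tanh(C_new)
    cache[[t]] <- list(Xt = Xt, Hprev = H, Cprev = Cc, i = i_g, f = f_g,
                       o = o_g, cg = c_g, Cnew = C_new, m = m)
    H <- m * H_new + (1 - m) * H
    Cc <- m * C_new + (1 - m) * Cc
  }
  list(out = H, bwd = function(dH) {
    dh <- dH
    dc <- matrix(0, N, h)
    dx <- array(0, dim = d)
    for (t in rev(seq_len(TT))) {
      cc <- cache[[t]]
      m <- cc$m
      dh_a <- dh * m
      tc <- tanh(cc$Cnew)
      dc_a <- dc * m + dh_a * cc$o * (1 - tc^2)
      do_ <- dh_a * tc
      di <- dc_a * cc$cg
      df <- dc_a * cc$Cprev
      dcg <- dc_a * cc$i
      dZ <- cbind(di * cc$i * (1 - cc$i),
                  df * cc$f * (1 - cc$f),
                  do_ * cc$o * (1 - cc$o),
                  dcg * (1 - cc$cg^2))
      g_acc(g, paste0(nm, ".Wx"), crossprod(cc$Xt, dZ))
      g_acc(g, paste0(nm, ".Wh"), crossprod(cc$Hprev, dZ))
      g_acc(g, paste0(nm, ".b"), colSums(dZ))
      dx[t, , ] <- dZ %*% t(Wx)
      dh <- dZ %*% t(Wh) + dh * (1 - m)
      dc <- dc_a * cc$f + dc * (1 - m)
    }
    dx
  })
}

# ---- model ---------------------------------------------------------------

#' Initialise an audio network
#'
#' @param cfg A [gcnlstm_config()].
#' @param seed Integer seed for weight initialisation.
#' @return A model object of class `gcnlstm_model`.
#' @export
gcnlstm_init <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "gcnlstm_config"))
  p <- with_local_seed(seed, {
    p <- list()
    d_in <- cfg$n_mfcc
    if (cfg$arch != "lstm_only") {
      for (l in seq_len(cfg$gcn_layers)) {
        p[[sprintf("gcn%d.W", l)]] <- init_mat(d_in, cfg$gcn_hidden,
                                               scale = sqrt(2 / d_in))
        d_in <- cfg$gcn_hidden
      }
    }
    seq_dim <- d_in
    if (cfg$arch != "gcn_only") {
      p <- lstm_init(p, "lstm", seq_dim, cfg$lstm_hidden)
      readout_dim <- cfg$lstm_hidden
    } else {
      readout_dim <- seq_dim
    }
    p[["head.fc.W"]] <- init_mat(readout_dim, cfg$feature_dim,
                                 scale = sqrt(1 / readout_dim))
    p[["head.fc.b"]] <- rep(0, cfg$feature_dim)
    p[["head.cls.W"]] <- init_mat(cfg$feature_dim, 1, scale = sqrt(1 / cfg$feature_dim))
    p[["head.cls.b"]] <- 0
    p[["head.reg.W"]] <- init_mat(cfg$feature_dim, 1, scale = sqrt(1 / cfg$feature_dim))
    p[["head.reg.b"]] <- 12
    p
  })
  structure(list(cfg = cfg, params = p), class = "gcnlstm_model")
}

#' Forward pass of the audio network over a batch of graphs
#'
#' Stacked graph convolutions per graph, temporal-order (optionally strided)
#' node-embedding sequences into a batch LSTM, final hidden state, fully
#' connected projection to `F_A`, dropout, dual head.
#'
#' @param model A `gcnlstm_model`.
#' @param graphs List of `audio_graph` objects (non-empty).
#' @param train Training mode (dropout active).
#' @param grads Optional gradient environment.
#' @return list with `F_A` (`batch x feature_dim`), `logits`, `phq8`, and a
#'   backward closure `bwd(dlogits, dphq8, dF_A)`.
#' @export
gcn_lstm_forward <- function(model, graphs, train = FALSE, grads = NULL) {
  cfg <- model$cfg
  p <- model$params
  g <- grads
  if (length(graphs) == 0) stop("empty graph batch")
  n_nodes <- vapply(graphs, function(gr) gr$n_nodes, integer(1))
  if (any(n_nodes < 1)) stop("empty graph in batch")
  N <- length(graphs)

  gcn_bwds <- vector("list", N)
  seqs <- vector("list", N)
  for (s in seq_len(N)) {
    gr <- graphs[[s]]
    X <- gr$node_features          # graph convolutions act in node space
    if (cfg$arch != "lstm_only") {
      Ahat <- normalized_adjacency(gr)
      bwds <- list()
      for (l in seq_len(cfg$gcn_layers)) {
        lf <- gcn_fwd(X, Ahat, p, sprintf("gcn%d", l), g = g)
        X <- lf$out
        bwds[[l]] <- lf$bwd
      }
      gcn_bwds[[s]] <- bwds
    }
    X <- X[gr$node_order, , drop = FALSE]   # temporal order for the LSTM
    keep <- seq(1, nrow(X), by = cfg$subsample)
    seqs[[s]] <- list(X = X[keep, , drop = FALSE], keep = keep,
                      n_full = nrow(X), order = gr$node_order)
  }
  lens <- vapply(seqs, function(sq) nrow(sq$X), integer(1))
  TT <- max(lens)
  D <- ncol(seqs[[1]]$X)

  if (cfg$arch == "gcn_only") {
    pooled <- t(vapply(seqs, function(sq) colMeans(sq$X), numeric(D)))
    read_bwd <- function(dpool) {
      lapply(seq_len(N), function(s) {
        matrix(rep(dpool[s, ] / lens[s], each = lens[s]), lens[s], D)
      })
    }
  } else {
    xarr <- array(0, dim = c(TT, N, D))
    for (s in seq_len(N)) xarr[seq_len(lens[s]), s, ] <- seqs[[s]]$X
    lf <- lstm_fwd(xarr, lens, p, "lstm", g = g)
    pooled <- lf$out
    read_bwd <- function(dpool) {
      dxarr <- lf$bwd(dpool)
      lapply(seq_len(N), function(s) {
        matrix(dxarr[seq_len(lens[s]), s, ], lens[s], D)
      })
    }
  }

  fc <- lin_fwd(pooled, p, "head.fc", g = g)
  FA <- fc$out
  dp <- dropout_fwd(FA, cfg$dropout, train = train)
  cls <- lin_fwd(dp$out, p, "head.cls", g = g)
  reg <- lin_fwd(dp$out, p, "head.reg", g = g)
  list(F_A = FA, logits = as.vector(cls$out), phq8 = as.vector(reg$out),
       bwd = function(dlogits = NULL, dphq8 = NULL, dF_A = NULL,
                      need_dx = FALSE) {
         dfa <- matrix(0, N, ncol(FA))
         if (!is.null(dlogits)) dfa <- dfa + dp$bwd(cls$bwd(matrix(dlogits, N, 1)))
         if (!is.null(dphq8)) dfa <- dfa + dp$bwd(reg$bwd(matrix(dphq8, N, 1)))
         if (!is.null(dF_A)) dfa <- dfa + dF_A
         dseqs <- read_bwd(fc$bwd(dfa))
         # Backprop through the per-sample GCN stacks down to the node
         # features (returned only on request).
         dxs <- if (need_dx) vector("list", N) else NULL
         for (s in seq_len(N)) {
           dXt <- matrix(0, seqs[[s]]$n_full, D)
           dXt[seqs[[s]]$keep, ] <- dseqs[[s]]
           dX <- matrix(0, seqs[[s]]$n_full, D)
           dX[seqs[[s]]$order, ] <- dXt       # back to node space
           if (cfg$arch != "lstm_only") {
             for (l in rev(seq_along(gcn_bwds[[s]]))) {
               dX <- gcn_bwds[[s]][[l]](dX)
             }
           }
           if (need_dx) dxs[[s]] <- dX
         }
         if (need_dx) dxs else invisible(NULL)
       })
}
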