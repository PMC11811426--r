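# TSNet: a 3-D residual video backbone whose residual blocks carry a
# temporal-spatial attention module (TSAM) after each convolutional
# sub-module. The temporal attention module (TAM) is channel attention: both
# global pools reduce to one descriptor per channel, a shared two-layer
# bottleneck MLP scores them, and the sigmoid weight rescales every channel.
# The spatial attention module (SAM) pools over channels, applies a
# (1 x k x k) convolution and a sigmoid, and rescales every position. TSAM
# output is the elementwise sum of the two gated maps, so with all attention
# parameters at zero it reduces exactly to the identity
# (0.5 * F_v + 0.5 * F_v = F_v) and the network collapses to a plain
# residual network.
#
# The "32"/"64" naming counts TAM and SAM separately: the 18-layer layout
# has 8 blocks x 2 sub-modules = 16 TSAM insertions = 32 attention modules;
# the 34-layer layout has 16 blocks x 2 = 32 insertions = 64 modules.

#' Configuration for the video network
#'
#' @param depth `"tsnet32"` (2,2,2,2 blocks per stage) or `"tsnet64"`
#'   (3,4,6,3).
#' @param in_channels Channels of the input clips.
#' @param base_channels Channel width of the first stage; later stages
#'   double it. Desk-scale experiments use small widths.
#' @param attention_reduction Bottleneck ratio of the TAM MLP; must divide
#'   every stage width.
#' @param sam_kernel Odd spatial kernel size of the SAM convolution.
#' @param feature_dim Length of the exported feature vector `F_V`.
#' @param dropout Dropout rate before the heads, within `[0.4, 0.6]`.
#' @param use_tsam Disable to obtain the attention-free backbone (ablation).
#' @return An object of class `tsnet_config`.
#' @export
tsnet_config <- function(depth = c("tsnet32", "tsnet64"), in_channels = 1,
                         base_channels = 8, attention_reduction = 4,
                         sam_kernel = 7, feature_dim = 32, dropout = 0.5,
                         use_tsam = TRUE) {
  depth <- match.arg(depth)
  if (sam_kernel %% 2 == 0) stop("sam_kernel must be odd")
  if (dropout < 0.4 || dropout > 0.6) stop("dropout must lie in [0.4, 0.6]")
  blocks <- if (depth == "tsnet32") c(2, 2, 2, 2) else c(3, 4, 6, 3)
  widths <- base_channels * c(1, 2, 4, 8)
  if (any(widths %% attention_reduction != 0)) {
    stop("attention_reduction must divide every stage width")
  }
  structure(list(depth = depth, in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 blocks_per_stage = as.integer(blocks),
                 widths = as.integer(widths),
                 attention_reduction = as.integer(attention_reduction),
                 sam_kernel = as.integer(sam_kernel),
                 feature_dim = as.integer(feature_dim),
                 dropout = dropout, use_tsam = isTRUE(use_tsam)),
            class = "tsnet_config")
}

# ---- attention sub-modules ----------------------------------------------

tam_init <- function(p, nm, C, r) {
  if (C %% r != 0) stop("channel count not divisible by attention_reduction")
  p[[paste0(nm, ".W1")]] <- init_mat(C, C %/% r)
  p[[paste0(nm, ".b1")]] <- rep(0, C %/% r)
  p[[paste0(nm, ".W2")]] <- init_mat(C %/% r, C)
  p[[paste0(nm, ".b2")]] <- rep(0, C)
  p
}

tam_fwd <- function(x, p, nm, g = NULL) {
  d <- dim(x)
  N <- d[1]; C <- d[2]; S <- prod(d[3:5])
  ap <- gap_thw_fwd(x)
  mp <- gmp_thw_fwd(x)
  # Shared two-layer MLP, applied to both pooled descriptors.
  mlp_fwd <- function(z) {
    h_pre <- sweep(z %*% p[[paste0(nm, ".W1")]], 2, p[[paste0(nm, ".b1")]], `+`)
    h <- pmax(h_pre, 0)
    l <- sweep(h %*% p[[paste0(nm, ".W2")]], 2, p[[paste0(nm, ".b2")]], `+`)
    list(out = l, bwd = function(dl) {
      g_acc(g, paste0(nm, ".W2"), crossprod(h, dl))
      g_acc(g, paste0(nm, ".b2"), colSums(dl))
      dh <- dl %*% t(p[[paste0(nm, ".W2")]])
      dh[h_pre <= 0] <- 0
      g_acc(g, paste0(nm, ".W1"), crossprod(z, dh))
      g_acc(g, paste0(nm, ".b1"), colSums(dh))
      dh %*% t(p[[paste0(nm, ".W1")]])
    })
  }
  ma <- mlp_fwd(ap$out)
  mm <- mlp_fwd(mp$out)
  logits <- ma$out + mm$out
  Wt <- sigmoid(logits)                       # N x C
  wtv <- as.vector(Wt)
  Ft <- x * rep(wtv, S)
  list(W_t = Wt, out = Ft, bwd = function(dFt) {
    prod_ <- dFt * x
    dim(prod_) <- c(N * C, S)
    dWt <- matrix(rowSums(prod_), N, C)
    dx <- dFt * rep(wtv, S)
    dlog <- dWt * Wt * (1 - Wt)
    dap <- ma$bwd(dlog)
    dmp <- mm$bwd(dlog)
    dx + ap$bwd(dap) + mp$bwd(dmp)
  })
}

sam_init <- function(p, nm, k) {
  fan_in <- 2 * k * k
  p[[paste0(nm, ".W")]] <- array(stats::rnorm(2 * k * k, sd = sqrt(2 / fan_in)),
                                 dim = c(1, 2, 1, k, k))
  p[[paste0(nm, ".b")]] <- 0
  p
}

sam_fwd <- function(x, p, nm, k, g = NULL) {
  if (k %% 2 == 0) stop("sam_kernel must be odd")
  d <- dim(x)
  N <- d[1]; C <- d[2]; TT <- d[3]; H <- d[4]; W <- d[5]
  S <- TT * H * W
  xp <- aperm(x, c(1, 3, 4, 5, 2))
  x2 <- matrix(xp, N * S, C)
  mean_map <- rowMeans(x2)
  idx <- max.col(x2, ties.method = "first")
  max_map <- x2[cbind(seq_len(N * S), idx)]
  two <- array(0, dim = c(N, 2, TT, H, W))
  two[, 1, , , ] <- array(mean_map, dim = c(N, TT, H, W))
  two[, 2, , , ] <- array(max_map, dim = c(N, TT, H, W))
  pd <- c(0L, (k - 1L) %/% 2L, (k - 1L) %/% 2L)
  cv <- conv3d_fwd(two, p, nm, stride = c(1, 1, 1), pad = pd, g = g)
  Ws <- sigmoid(cv$out)                        # N,1,T,H,W
  ws_exp <- Ws[, rep(1L, C), , , , drop = FALSE]
  Fs <- x * ws_exp
  list(W_s = Ws, out = Fs, bwd = function(dFs) {
    tmp <- dFs * x
    m <- matrix(aperm(tmp, c(1, 3, 4, 5, 2)), N * S, C)
    dws <- array(rowSums(m), dim = c(N, 1, TT, H, W))
    dx <- dFs * ws_exp
    dlog <- dws * Ws * (1 - Ws)
    d2 <- cv$bwd(dlog)
    dmean <- as.vector(d2[, 1, , , ])
    dmax <- as.vector(d2[, 2, , , ])
    dx2 <- matrix(dmean / C, N * S, C)
    dx2[cbind(seq_len(N * S), idx)] <- dx2[cbind(seq_len(N * S), idx)] + dmax
    dx + aperm(array(dx2, dim = c(N, TT, H, W, C)), c(1, 5, 2, 3, 4))
  })
}

tsam_fwd <- function(x, p, nm, k, g = NULL) {
  ta <- tam_fwd(x, p, paste0(nm, ".tam"), g = g)
  sa <- sam_fwd(x, p, paste0(nm, ".sam"), k = k, g = g)
  list(out = ta$out + sa$out, W_t = ta$W_t, W_s = sa$W_s,
       bwd = function(dout) ta$bwd(dout) + sa$bwd(dout))
}

#' Temporal (channel) attention over a feature map
#'
#' Both global pools collapse time and space to one descriptor per channel; a
#' shared two-layer bottleneck MLP scores them and the summed scores pass
#' through a sigmoid. The per-channel weight rescales the whole map.
#'
#' @param x Rank-5 array `(batch, channels, time, height, width)`.
#' @param pars list with `W1` (`C x C/r`), `b1`, `W2` (`C/r x C`), `b2`.
#' @return list with `W_t` (`batch x channels` weights in `(0,1)`) and `F_t`
#'   (the gated feature map).
#' @export
temporal_attention <- function(x, pars) {
  C <- dim(x)[2]
  if (nrow(pars$W1) != C) stop("W1 must have one row per channel")
  p <- list()
  p[["a.W1"]] <- pars$W1; p[["a.b1"]] <- pars$b1
  p[["a.W2"]] <- pars$W2; p[["a.b2"]] <- pars$b2
  r <- tam_fwd(x, p, "a")
  list(W_t = r$W_t, F_t = r$out)
}

#' Spatial (position) attention over a feature map
#'
#' Channel-wise mean and max maps are stacked and passed through a
#' `(1 x k x k)` same-padded convolution and a sigmoid; the per-position
#' weight rescales every channel.
#'
#' @param x Rank-5 array `(batch, channels, time, height, width)`.
#' @param pars list with `W` (array `(1, 2, 1, k, k)`) and scalar `b`.
#' @return list with `W_s` (`(batch, 1, time, height, width)` weights in
#'   `(0,1)`) and `F_s` (the gated feature map).
#' @export
spatial_attention <- function(x, pars) {
  k <- dim(pars$W)[4]
  p <- list()
  p[["a.W"]] <- pars$W; p[["a.b"]] <- pars$b
  r <- sam_fwd(x, p, "a", k = k)
  list(W_s = r$W_s, F_s = r$out)
}

#' Combined temporal-spatial attention
#'
#' Elementwise sum of the two gated maps, `F_ts = F_t + F_s`; shape is
#' preserved, and with all parameters zero `F_ts` equals the input exactly.
#'
#' @param x Rank-5 array.
#' @param tam_pars,sam_pars Parameter lists as in [temporal_attention()] and
#'   [spatial_attention()].
#' @return The fused feature map `F_ts`.
#' @export
tsam <- function(x, tam_pars, sam_pars) {
  temporal_attention(x, tam_pars)$F_t + spatial_attention(x, sam_pars)$F_s
}

# ---- building blocks -----------------------------------------------------

conv_bn_init <- function(p, bn, nm, ci, co, k) {
  p[[paste0(nm, ".conv.W")]] <- init_conv_w(co, ci, k[1], k[2], k[3])
  p[[paste0(nm, ".conv.b")]] <- rep(0, co)
  bn_init(p, bn, paste0(nm, ".bn"), co)
}

conv_bn_fwd <- function(x, p, bn, nm, stride, pad, train, g = NULL) {
  cv <- conv3d_fwd(x, p, paste0(nm, ".conv"), stride = stride, pad = pad, g = g)
  b <- bn_fwd(cv$out, p, bn, paste0(nm, ".bn"), train = train, g = g)
  list(out = b$out, bwd = function(dout, need_dx = TRUE) {
    cv$bwd(b$bwd(dout), need_dx = need_dx)
  })
}

block_init <- function(p, bn, nm, ci, co, cfg) {
  p <- conv_bn_init(p, bn, paste0(nm, ".c1"), ci, co, c(3, 3, 3))
  p <- conv_bn_init(p, bn, paste0(nm, ".c2"), co, co, c(3, 3, 3))
  if (ci != co) p <- conv_bn_init(p, bn, paste0(nm, ".down"), ci, co, c(1, 1, 1))
  if (cfg$use_tsam) {
    for (sub in c(".a1", ".a2")) {
      p <- tam_init(p, paste0(nm, sub, ".tam"), co, cfg$attention_reduction)
      p <- sam_init(p, paste0(nm, sub, ".sam"), cfg$sam_kernel)
    }
  }
  p
}

block_fwd <- function(x, p, bn, nm, stride, cfg, train, g = NULL) {
  down <- !is.null(p[[paste0(nm, ".down.conv.W")]])
  c1 <- conv_bn_fwd(x, p, bn, paste0(nm, ".c1"), stride, c(1, 1, 1), train, g)
  h1 <- c1$out
  a1 <- if (cfg$use_tsam) tsam_fwd(h1, p, paste0(nm, ".a1"), cfg$sam_kernel, g) else NULL
  r1 <- relu_fwd(if (is.null(a1)) h1 else a1$out)
  c2 <- conv_bn_fwd(r1$out, p, bn, paste0(nm, ".c2"), c(1, 1, 1), c(1, 1, 1), train, g)
  h2 <- c2$out
  a2 <- if (cfg$use_tsam) tsam_fwd(h2, p, paste0(nm, ".a2"), cfg$sam_kernel, g) else NULL
  main <- if (is.null(a2)) h2 else a2$out
  sc <- if (down) {
    conv_bn_fwd(x, p, bn, paste0(nm, ".down"), stride, c(0, 0, 0), train, g)
  } else NULL
  skip <- if (is.null(sc)) x else sc$out
  s <- main + skip
  out <- relu_fwd(s)
  list(out = out$out, bwd = function(dout) {
    ds <- out$bwd(dout)
    dmain <- ds
    if (!is.null(a2)) dmain <- a2$bwd(dmain)
    dr1 <- c2$bwd(dmain)
    dh1 <- r1$bwd(dr1)
    if (!is.null(a1)) dh1 <- a1$bwd(dh1)
    dx <- c1$bwd(dh1)
    dx + (if (is.null(sc)) ds else sc$bwd(ds))
  })
}

# ---- model ---------------------------------------------------------------

#' Initialise a video network
#'
#' @param cfg A [tsnet_config()].
#' @param seed Integer seed for weight initialisation.
#' @return A model object (class `tsnet_model`) holding the parameter list,
#'   batch-norm state, and config.
#' @export
tsnet_init <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "tsnet_config"))
  bn <- new.env(parent = emptyenv())
  p <- with_local_seed(seed, {
    p <- list()
    p <- conv_bn_init(p, bn, "stem", cfg$in_channels, cfg$widths[1], c(7, 7, 7))
    ci <- cfg$widths[1]
    for (s in 1:4) {
      co <- cfg$widths[s]
      for (b in seq_len(cfg$blocks_per_stage[s])) {
        p <- block_init(p, bn, sprintf("s%d.b%d", s, b),
                        if (b == 1) ci else co, co, cfg)
      }
      ci <- co
    }
    p[["head.fc.W"]] <- init_mat(cfg$widths[4], cfg$feature_dim,
                                 scale = sqrt(1 / cfg$widths[4]))
    p[["head.fc.b"]] <- rep(0, cfg$feature_dim)
    p[["head.cls.W"]] <- init_mat(cfg$feature_dim, 1, scale = sqrt(1 / cfg$feature_dim))
    p[["head.cls.b"]] <- 0
    p[["head.reg.W"]] <- init_mat(cfg$feature_dim, 1, scale = sqrt(1 / cfg$feature_dim))
    p[["head.reg.b"]] <- 12
    p
  })
  structure(list(cfg = cfg, params = p, bn = bn), class = "tsnet_model")
}

check_finite_stage <- function(x, stage) {
  if (anyNA(x) || any(is.infinite(x))) {
    stop("non-finite activations in stage '", stage, "'")
  }
  invisible(NULL)
}

#' Stem of the video network
#'
#' The 7x7x7 stride-(1,2,2) convolution followed by batch normalisation and
#' the 3x3x3 stride-(1,2,2) max pool: time is preserved, space is reduced by
#' a factor of four overall (same-padding convention).
#'
#' @param model A `tsnet_model`.
#' @param clip_batch Rank-5 array `(batch, channels, time, height, width)`
#'   with spatial dims at least 32.
#' @param train Batch-statistics mode for normalisation.
#' @return The feature map `F_v`.
#' @export
tsnet_stem <- function(model, clip_batch, train = FALSE) {
  stem_fwd(clip_batch, model$params, model$bn, train = train)$out
}

stem_fwd <- function(x, p, bn, train, g = NULL) {
  d <- dim(x)
  if (length(d) != 5) stop("clip batch must be a rank-5 array")
  if (d[4] < 32 || d[5] < 32) stop("spatial dims must be at least 32")
  cb <- conv_bn_fwd(x, p, bn, "stem", stride = c(1, 2, 2), pad = c(3, 3, 3),
                    train = train, g = g)
  pl <- maxpool3d_fwd(cb$out, ksize = c(3, 3, 3), stride = c(1, 2, 2),
                      pad = c(1, 1, 1))
  list(out = pl$out, bwd = function(dout, need_dx = TRUE) {
    cb$bwd(pl$bwd(dout), need_dx = need_dx)
  })
}

#' Forward pass of the video network
#'
#' Stem, four stages of residual blocks (each convolutional sub-module
#' followed by a TSAM before the residual addition), global average pooling,
#' a fully connected projection to the feature vector `F_V`, dropout, and
#' the dual head: a binary logit and a scalar PHQ-8 estimate.
#'
#' @param model A `tsnet_model` from [tsnet_init()].
#' @param clip_batch Rank-5 array `(batch, channels, time, height, width)`.
#' @param train Training mode (batch statistics + dropout).
#' @param grads Optional gradient environment from [new_grad_env()].
#' @return list with `F_V` (`batch x feature_dim`), `logits`, `phq8`, and a
#'   backward closure `bwd(dlogits, dphq8, dF_V)` returning the input
#'   gradient.
#' @export
tsnet_forward <- function(model, clip_batch, train = FALSE, grads = NULL) {
  cfg <- model$cfg
  p <- model$params
  bn <- model$bn
  g <- grads
  st <- stem_fwd(clip_batch, p, bn, train = train, g = g)
  check_finite_stage(st$out, "stem")
  h <- st$out
  bwds <- list()
  for (s in 1:4) {
    for (b in seq_len(cfg$blocks_per_stage[s])) {
      stride <- if (s > 1 && b == 1) c(2, 2, 2) else c(1, 1, 1)
      blk <- block_fwd(h, p, bn, sprintf("s%d.b%d", s, b), stride, cfg,
                       train = train, g = g)
      h <- blk$out
      bwds[[length(bwds) + 1L]] <- blk$bwd
    }
    check_finite_stage(h, sprintf("stage%d", s))
  }
  gp <- gap_thw_fwd(h)
  fc <- lin_fwd(gp$out, p, "head.fc", g = g)
  FV <- fc$out
  dp <- dropout_fwd(FV, cfg$dropout, train = train)
  cls <- lin_fwd(dp$out, p, "head.cls", g = g)
  reg <- lin_fwd(dp$out, p, "head.reg", g = g)
  list(F_V = FV, logits = as.vector(cls$out), phq8 = as.vector(reg$out),
       bwd = function(dlogits = NULL, dphq8 = NULL, dF_V = NULL,
                      need_dx = FALSE) {
         n <- nrow(FV)
         dfv <- matrix(0, n, ncol(FV))
         if (!is.null(dlogits)) dfv <- dfv + dp$bwd(cls$bwd(matrix(dlogits, n, 1)))
         if (!is.null(dphq8)) dfv <- dfv + dp$bwd(reg$bwd(matrix(dphq8, n, 1)))
         if (!is.null(dF_V)) dfv <- dfv + dF_V
         dh <- gp$bwd(fc$bwd(dfv))
         for (i in rev(seq_along(bwds))) dh <- bwds[[i]](dh)
         st$bwd(dh, need_dx = need_dx)
       })
}

#' Count attention modules in a video network
#'
#' TAM and SAM are counted separately (two per TSAM insertion), matching the
#' "32"/"64" naming of the two depths.
#'
#' @param model A `tsnet_model`.
#' @return Integer count.
#' @export
count_attention_modules <- function(model) {
  nms <- names(model$params)
  n_tam <- sum(grepl("\\.tam\\.W1$", nms))
  n_sam <- sum(grepl("\\.sam\\.W$", nms))
  n_tam + n_sam
}

#' Names of all attention parameters of a video network
#'
#' @param model A `tsnet_model`.
#' @return Character vector of parameter names.
#' @export
attention_param_names <- function(model) {
  grep("\\.(tam|sam)\\.", names(model$params), value = TRUE)
}

#' Stack clips into a network input batch
#'
#' @param clips List of rank-4 arrays `(frames, height, width, channels)`.
#' @return Rank-5 array `(batch, channels, frames, height, width)`.
#' @export
clips_to_batch <- function(clips) {
  d <- dim(clips[[1]])
  out <- array(0, dim = c(length(clips), d[4], d[1], d[2], d[3]))
  for (i in seq_along(clips)) {
    out[i, , , , ] <- aperm(clips[[i]], c(4, 1, 2, 3))
  }
  out
}
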