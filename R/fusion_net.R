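# Video-audio fusion network (VAFN).
#
# The two modality feature vectors are zero-padded to a common length d,
# stacked row-wise into H_VA (2 x d) and concatenated tail-to-tail into V_VA
# (length 2d). A fully connected layer reduces V_VA to two logits; their
# softmax V_VAF weights the two rows of H_VA, so the fused vector F_VA is a
# convex per-modality combination. F_VA is max-pooled (window k, stride k)
# and classified by the dual head. An elementwise-gate alternative (one
# sigmoid gate per feature position) is kept behind `mode = "elementwise"`.

#' Configuration for the fusion network
#'
#' @param d_v,d_a Dimensions of the incoming video/audio feature vectors.
#' @param pool_k Max-pool window (and stride) over the fused vector.
#' @param mode `"softmax"` (two modality weights summing to 1) or
#'   `"elementwise"` (a sigmoid gate per feature position).
#' @return An object of class `vafn_config`.
#' @export
vafn_config <- function(d_v = 32, d_a = 32, pool_k = 4,
                        mode = c("softmax", "elementwise")) {
  mode <- match.arg(mode)
  d <- max(d_v, d_a)
  if (pool_k > d) stop("pool_k must not exceed the fused dimension")
  structure(list(d_v = as.integer(d_v), d_a = as.integer(d_a),
                 d = as.integer(d), pool_k = as.integer(pool_k),
                 mode = mode),
            class = "vafn_config")
}

#' Zero-pad two feature vectors to a common length
#'
#' Padding is appended at the tail of the shorter vector; entries and their
#' order are preserved.
#'
#' @param F_V,F_A Numeric vectors, or matrices with one sample per row.
#' @return list with `F_VP` and `F_AP`, both of length `max(d_v, d_a)` (or
#'   matrices with that many columns).
#' @export
pad_align <- function(F_V, F_A) {
  vec_in <- is.null(dim(F_V))
  V <- if (vec_in) matrix(F_V, 1) else as.matrix(F_V)
  A <- if (is.null(dim(F_A))) matrix(F_A, 1) else as.matrix(F_A)
  if (ncol(V) == 0 || ncol(A) == 0) stop("empty feature vector")
  d <- max(ncol(V), ncol(A))
  pad <- function(M) {
    if (ncol(M) < d) cbind(M, matrix(0, nrow(M), d - ncol(M))) else M
  }
  V <- pad(V); A <- pad(A)
  if (vec_in) list(F_VP = as.vector(V), F_AP = as.vector(A))
  else list(F_VP = V, F_AP = A)
}

#' Initialise a fusion network
#'
#' @param cfg A [vafn_config()].
#' @param seed Integer seed for weight initialisation.
#' @return A model object of class `vafn_model`.
#' @export
vafn_init <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "vafn_config"))
  d <- cfg$d
  n_out <- if (cfg$mode == "softmax") 2L else d
  n_pool <- ceiling(d / cfg$pool_k)
  p <- with_local_seed(seed, {
    p <- list()
    p[["att.W"]] <- init_mat(2 * d, n_out, scale = sqrt(1 / (2 * d)))
    p[["att.b"]] <- rep(0, n_out)
    p[["head.cls.W"]] <- init_mat(n_pool, 1, scale = sqrt(1 / n_pool))
    p[["head.cls.b"]] <- 0
    p[["head.reg.W"]] <- init_mat(n_pool, 1, scale = sqrt(1 / n_pool))
    p[["head.reg.b"]] <- 12
    p
  })
  structure(list(cfg = cfg, params = p), class = "vafn_model")
}

# Core fusion on matrices (one sample per row), with backward closure.
fuse_fwd <- function(VP, AP, p, cfg, g = NULL) {
  N <- nrow(VP); d <- ncol(VP)
  VVA <- cbind(VP, AP)                       # tail concatenation, N x 2d
  att <- lin_fwd(VVA, p, "att", g = g)
  if (cfg$mode == "softmax") {
    Wf <- softmax_rows(att$out)              # N x 2
    FVA <- Wf[, 1] * VP + Wf[, 2] * AP
    bwd <- function(dFVA) {
      dw1 <- rowSums(dFVA * VP)
      dw2 <- rowSums(dFVA * AP)
      # softmax backward per row
      dlog <- cbind(dw1, dw2)
      s <- rowSums(dlog * Wf)
      dz <- Wf * (dlog - s)
      dVVA <- att$bwd(dz)
      dVP <- dFVA * Wf[, 1] + dVVA[, 1:d, drop = FALSE]
      dAP <- dFVA * Wf[, 2] + dVVA[, (d + 1):(2 * d), drop = FALSE]
      list(dVP = dVP, dAP = dAP)
    }
  } else {
    Wf <- sigmoid(att$out)                   # N x d elementwise gate
    FVA <- Wf * VP + (1 - Wf) * AP
    bwd <- function(dFVA) {
      dgate <- dFVA * (VP - AP) * Wf * (1 - Wf)
      dVVA <- att$bwd(dgate)
      list(dVP = dFVA * Wf + dVVA[, 1:d, drop = FALSE],
           dAP = dFVA * (1 - Wf) + dVVA[, (d + 1):(2 * d), drop = FALSE])
    }
  }
  list(F_VA = FVA, weights = Wf, bwd = bwd)
}

#' Fuse two aligned modality feature vectors
#'
#' Stacks `F_VP`/`F_AP` into `H_VA`, concatenates them into `V_VA`, scores
#' `V_VA` with a fully connected layer, normalises with a softmax into the
#' attention weights `V_VAF`, and returns `F_VA = t(V_VAF) %*% H_VA`.
#'
#' @param F_VP,F_AP Equal-length numeric vectors (or matrices, one sample
#'   per row).
#' @param model A `vafn_model`.
#' @return list with `F_VA` and the attention weights `V_VAF`.
#' @export
vafn_fuse <- function(F_VP, F_AP, model) {
  vec_in <- is.null(dim(F_VP))
  VP <- if (vec_in) matrix(F_VP, 1) else as.matrix(F_VP)
  AP <- if (is.null(dim(F_AP))) matrix(F_AP, 1) else as.matrix(F_AP)
  if (ncol(VP) != ncol(AP)) stop("padded features must have equal length")
  r <- fuse_fwd(VP, AP, model$params, model$cfg)
  if (vec_in) list(F_VA = as.vector(r$F_VA), V_VAF = as.vector(r$weights))
  else list(F_VA = r$F_VA, V_VAF = r$weights)
}

# 1-D max pool (window k, stride k) over rows of a matrix; the last window
# may be shorter.
maxpool1d_fwd <- function(X, k) {
  N <- nrow(X); d <- ncol(X)
  if (k > d) stop("pool window exceeds vector length")
  n_pool <- ceiling(d / k)
  out <- matrix(-Inf, N, n_pool)
  arg <- matrix(1L, N, n_pool)
  for (jj in seq_len(n_pool)) {
    cols <- ((jj - 1) * k + 1):min(jj * k, d)
    sub <- X[, cols, drop = FALSE]
    loc <- max.col(sub, ties.method = "first")
    out[, jj] <- sub[cbind(seq_len(N), loc)]
    arg[, jj] <- cols[loc]
  }
  list(out = out, bwd = function(dout) {
    dX <- matrix(0, N, d)
    for (jj in seq_len(n_pool)) {
      ii <- cbind(seq_len(N), arg[, jj])
      dX[ii] <- dX[ii] + dout[, jj]
    }
    dX
  })
}

#' Max-pool and classify a fused feature vector
#'
#' @param F_VA Fused vector (or matrix, one sample per row).
#' @param model A `vafn_model`.
#' @return list with `logits` and `phq8`.
#' @export
vafn_predict <- function(F_VA, model) {
  vec_in <- is.null(dim(F_VA))
  X <- if (vec_in) matrix(F_VA, 1) else as.matrix(F_VA)
  r <- predict_fwd(X, model$params, model$cfg)
  list(logits = r$logits, phq8 = r$phq8)
}

# The fusion head carries no dropout: regularisation lives in the branch
# backbones, and the pooled fused vector is already low-dimensional.
predict_fwd <- function(X, p, cfg, g = NULL) {
  mp <- maxpool1d_fwd(X, cfg$pool_k)
  cls <- lin_fwd(mp$out, p, "head.cls", g = g)
  reg <- lin_fwd(mp$out, p, "head.reg", g = g)
  N <- nrow(X)
  list(logits = as.vector(cls$out), phq8 = as.vector(reg$out),
       bwd = function(dlogits = NULL, dphq8 = NULL) {
         dpool <- matrix(0, N, ncol(mp$out))
         if (!is.null(dlogits)) dpool <- dpool + cls$bwd(matrix(dlogits, N, 1))
         if (!is.null(dphq8)) dpool <- dpool + reg$bwd(matrix(dphq8, N, 1))
         mp$bwd(dpool)
       })
}

#' Full fusion forward pass from branch features
#'
#' Pads, fuses, pools, and classifies a batch of branch feature vectors.
#'
#' @param model A `vafn_model`.
#' @param F_V,F_A Branch feature matrices (one sample per row).
#' @param train Training mode.
#' @param grads Optional gradient environment.
#' @return list with `F_VA`, `V_VAF`, `logits`, `phq8`, and a backward
#'   closure `bwd(dlogits, dphq8)` returning gradients for both branch
#'   feature matrices.
#' @export
vafn_forward <- function(model, F_V, F_A, train = FALSE, grads = NULL) {
  cfg <- model$cfg
  pa <- pad_align(as.matrix(F_V), as.matrix(F_A))
  fu <- fuse_fwd(pa$F_VP, pa$F_AP, model$params, cfg, g = grads)
  pr <- predict_fwd(fu$F_VA, model$params, cfg, g = grads)
  list(F_VA = fu$F_VA, V_VAF = fu$weights, logits = pr$logits,
       phq8 = pr$phq8,
       bwd = function(dlogits = NULL, dphq8 = NULL) {
         dF <- pr$bwd(dlogits, dphq8)
         dd <- fu$bwd(dF)
         list(dF_V = dd$dVP[, seq_len(ncol(as.matrix(F_V))), drop = FALSE],
              dF_A = dd$dAP[, seq_len(ncol(as.matrix(F_A))), drop = FALSE])
       })
}
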