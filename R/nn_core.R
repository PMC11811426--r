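# Reverse-mode training engine used by all three networks.
#
# Every layer helper takes the input plus a parameter list `p` and returns
# list(out = ..., bwd = function(dout) dx). The backward closure accumulates
# parameter gradients into the environment `g` (keyed by parameter name) and
# returns the gradient with respect to the layer input, so whole networks are
# differentiated by chaining closures. Passing g = NULL skips parameter
# gradients (used for input-attribution passes in evaluation mode).

#' Run code under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the previous global RNG
#' state, so deterministic generators do not disturb callers' random streams.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed below 2^31 from a base seed and an index.
derive_seed <- function(seed, index, salt = 0L) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807 +
                as.double(salt) * 69621) %% 2147483647)
}

# ---- gradient accumulation ----------------------------------------------

new_grad_env <- function() new.env(parent = emptyenv())

g_acc <- function(g, name, value) {
  if (is.null(g)) return(invisible(NULL))
  if (is.null(g[[name]])) g[[name]] <- value else g[[name]] <- g[[name]] + value
  invisible(NULL)
}

grads_as_list <- function(g) as.list(g)

# ---- parameter initialisation -------------------------------------------

init_mat <- function(nr, nc, scale = sqrt(2 / nr)) {
  matrix(stats::rnorm(nr * nc, sd = scale), nr, nc)
}

init_conv_w <- function(co, ci, kt, kh, kw) {
  fan_in <- ci * kt * kh * kw
  array(stats::rnorm(co * fan_in, sd = sqrt(2 / fan_in)), dim = c(co, ci, kt, kh, kw))
}

zeros_like <- function(x) {
  z <- x
  z[] <- 0
  z
}

# ---- elementary layers ---------------------------------------------------

lin_fwd <- function(x, p, nm, g = NULL) {
  W <- p[[paste0(nm, ".W")]]
  b <- p[[paste0(nm, ".b")]]
  out <- x %*% W
  out <- sweep(out, 2, b, `+`)
  list(out = out, bwd = function(dout) {
    g_acc(g, paste0(nm, ".W"), crossprod(x, dout))
    g_acc(g, paste0(nm, ".b"), colSums(dout))
    dout %*% t(W)
  })
}

relu_fwd <- function(x) {
  mask <- x > 0
  out <- x
  out[!mask] <- 0
  list(out = out, bwd = function(dout) {
    dx <- dout
    dx[!mask] <- 0
    dx
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

sigmoid_fwd <- function(x) {
  s <- sigmoid(x)
  list(out = s, bwd = function(dout) dout * s * (1 - s))
}

dropout_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) {
    return(list(out = x, bwd = function(dout) dout))
  }
  mask <- (stats::runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(out = x * mask, bwd = function(dout) dout * mask)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- 3-D convolution / pooling wrappers ----------------------------------

conv3d_fwd <- function(x, p, nm, stride, pad, g = NULL) {
  W <- p[[paste0(nm, ".W")]]
  b <- p[[paste0(nm, ".b")]]
  out <- conv3d_fwd_cpp(x, W, b, as.integer(stride), as.integer(pad))
  list(out = out, bwd = function(dout, need_dx = TRUE) {
    r <- conv3d_bwd_cpp(x, W, dout, as.integer(stride), as.integer(pad), need_dx)
    g_acc(g, paste0(nm, ".W"), r$dw)
    g_acc(g, paste0(nm, ".b"), r$db)
    if (need_dx) r$dx else NULL
  })
}

maxpool3d_fwd <- function(x, ksize, stride, pad) {
  r <- maxpool3d_fwd_cpp(x, as.integer(ksize), as.integer(stride), as.integer(pad))
  xd <- dim(x)
  list(out = r$out, bwd = function(dout) {
    maxpool3d_bwd_cpp(dout, r$argmax, as.integer(xd))
  })
}

# ---- batch normalisation over (N, T, H, W) per channel -------------------

# Running statistics live in the environment `bn` under `<nm>.mean` /
# `<nm>.var`; learned scale/shift in the parameter list as `<nm>.gamma` /
# `<nm>.beta` (length C).
bn_fwd <- function(x, p, bn, nm, train, g = NULL, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  N <- d[1]; C <- d[2]; S <- prod(d[3:5])
  gamma <- p[[paste0(nm, ".gamma")]]
  beta <- p[[paste0(nm, ".beta")]]
  xm <- matrix(x, nrow = N)          # N x (C*S); column j has channel (j-1) %% C + 1
  ch <- rep.int(seq_len(C), S)
  n_per <- N * S
  if (train) {
    mu <- as.vector(rowsum(colSums(xm), ch)) / n_per
    xc <- sweep(xm, 2, mu[ch], `-`)
    v <- as.vector(rowsum(colSums(xc * xc), ch)) / n_per
    istd <- 1 / sqrt(v + eps)
    bn[[paste0(nm, ".mean")]] <- (1 - momentum) * bn[[paste0(nm, ".mean")]] + momentum * mu
    bn[[paste0(nm, ".var")]] <- (1 - momentum) * bn[[paste0(nm, ".var")]] + momentum * v
  } else {
    mu <- bn[[paste0(nm, ".mean")]]
    v <- bn[[paste0(nm, ".var")]]
    istd <- 1 / sqrt(v + eps)
    xc <- sweep(xm, 2, mu[ch], `-`)
  }
  xhat <- sweep(xc, 2, istd[ch], `*`)
  om <- sweep(sweep(xhat, 2, gamma[ch], `*`), 2, beta[ch], `+`)
  out <- array(om, dim = d)
  list(out = out, bwd = function(dout) {
    dm <- matrix(dout, nrow = N)
    g_acc(g, paste0(nm, ".gamma"), as.vector(rowsum(colSums(dm * xhat), ch)))
    g_acc(g, paste0(nm, ".beta"), as.vector(rowsum(colSums(dm), ch)))
    dxhat <- sweep(dm, 2, gamma[ch], `*`)
    if (train) {
      m1 <- as.vector(rowsum(colSums(dxhat), ch)) / n_per
      m2 <- as.vector(rowsum(colSums(dxhat * xhat), ch)) / n_per
      dxm <- sweep(dxhat, 2, m1[ch], `-`) - sweep(xhat, 2, m2[ch], `*`)
      dxm <- sweep(dxm, 2, istd[ch], `*`)
    } else {
      dxm <- sweep(dxhat, 2, istd[ch], `*`)
    }
    array(dxm, dim = d)
  })
}

bn_init <- function(p, bn, nm, C) {
  p[[paste0(nm, ".gamma")]] <- rep(1, C)
  p[[paste0(nm, ".beta")]] <- rep(0, C)
  bn[[paste0(nm, ".mean")]] <- rep(0, C)
  bn[[paste0(nm, ".var")]] <- rep(1, C)
  p
}

# ---- global pools over (T,H,W) -------------------------------------------

# x: (N,C,T,H,W) -> N x C mean / max (with backward closures)
gap_thw_fwd <- function(x) {
  d <- dim(x)
  N <- d[1]; C <- d[2]; S <- prod(d[3:5])
  x2 <- x
  dim(x2) <- c(N * C, S)
  out <- matrix(rowMeans(x2), N, C)
  list(out = out, bwd = function(dout) {
    dx2 <- matrix(as.vector(dout) / S, N * C, S)
    array(dx2, dim = d)
  })
}

gmp_thw_fwd <- function(x) {
  d <- dim(x)
  N <- d[1]; C <- d[2]; S <- prod(d[3:5])
  x2 <- x
  dim(x2) <- c(N * C, S)
  idx <- max.col(x2, ties.method = "first")
  out <- matrix(x2[cbind(seq_len(N * C), idx)], N, C)
  list(out = out, bwd = function(dout) {
    dx2 <- matrix(0, N * C, S)
    dx2[cbind(seq_len(N * C), idx)] <- as.vector(dout)
    array(dx2, dim = d)
  })
}

# ---- losses --------------------------------------------------------------

# Numerically stable binary cross-entropy on logits; returns mean loss and
# the gradient d loss / d logit.
bce_with_logits <- function(z, y) {
  z <- as.vector(z); y <- as.vector(y)
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  grad <- (sigmoid(z) - y) / length(z)
  list(loss = loss, grad = grad)
}

mse_loss <- function(est, target) {
  est <- as.vector(est); target <- as.vector(target)
  list(loss = mean((est - target)^2),
       grad = 2 * (est - target) / length(est))
}

# ---- AdamW ---------------------------------------------------------------

adamw_init <- function(params) {
  list(m = lapply(params, zeros_like), v = lapply(params, zeros_like), t = 0L)
}

#' One AdamW update
#'
#' Decoupled weight decay variant of Adam. Parameters absent from `grads`
#' (e.g. frozen branches) are left untouched.
#'
#' @param params Named list of parameter arrays.
#' @param grads Named list of gradients (same shapes).
#' @param state Optimizer state from [adamw_init()].
#' @param lr Learning rate.
#' @param betas Exponential decay rates for the moment estimates.
#' @param eps Numerical stabiliser.
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param lr_mult Optional named numeric vector of parameter-name regex
#'   patterns to learning-rate multipliers (parameter groups).
#' @return list(params, state) after the update.
#' @keywords internal
adamw_step <- function(params, grads, state, lr, betas = c(0.9, 0.999),
                       eps = 1e-8, weight_decay = 0.01, lr_mult = NULL) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    if (is.null(params[[nm]])) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gr
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gr * gr
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    lr_i <- lr
    if (!is.null(lr_mult)) {
      for (pat in names(lr_mult)) if (grepl(pat, nm)) lr_i <- lr_i * lr_mult[[pat]]
    }
    decay <- if (grepl("\\.(gamma|beta|b)$", nm)) 0 else weight_decay
    params[[nm]] <- params[[nm]] - lr_i * (mhat / (sqrt(vhat) + eps) + decay * params[[nm]])
  }
  list(params = params, state = state)
}

# Linear decay from lr to lr/100 across the run.
lr_schedule_linear <- function(lr, iter, total) {
  frac <- if (total <= 1) 1 else 1 - (iter - 1) / total
  lr * max(frac, 0.01)
}
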