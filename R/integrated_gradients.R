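# Integrated-gradients attribution.

#' Integrated gradients along a straight path
#'
#' Midpoint Riemann approximation of
#' `(x - baseline) * integral_0^1 grad f(baseline + a (x - baseline)) da`.
#' Exact for linear models at any number of steps; satisfies the
#' completeness axiom `sum(attributions) = f(x) - f(baseline)` in the limit.
#'
#' @param f Function of one input returning `list(value = scalar,
#'   grad = array like the input)`.
#' @param x Input array.
#' @param baseline Baseline of the same shape; defaults to all zeros.
#' @param steps Number of Riemann steps (at least 1).
#' @return Attribution array of the same shape as `x`, with attributes
#'   `value` (`f(x)`) and `baseline_value` (`f(baseline)`).
#' @export
integrated_gradients <- function(f, x, baseline = NULL, steps = 64) {
  if (steps < 1) stop("steps must be at least 1")
  if (is.null(baseline)) baseline <- zeros_like(x)
  if (!identical(dim(baseline), dim(x)) ||
      length(baseline) != length(x)) {
    stop("baseline must match the input shape")
  }
  diff_ <- x - baseline
  total <- zeros_like(x)
  for (i in seq_len(steps)) {
    a <- (i - 0.5) / steps
    total <- total + f(baseline + a * diff_)$grad
  }
  attr_ <- diff_ * total / steps
  attributes(attr_)$value <- f(x)$value
  attributes(attr_)$baseline_value <- f(baseline)$value
  attr_
}

#' Aggregate per-frame attributions over fixed windows
#'
#' Sums attribution rows over consecutive windows of `every` frames (the
#' last window may be shorter).
#'
#' @param attributions Matrix with one row per frame.
#' @param every Window length in frames.
#' @return Matrix with one row per window.
#' @export
aggregate_attributions <- function(attributions, every = 100) {
  A <- as.matrix(attributions)
  grp <- ceiling(seq_len(nrow(A)) / every)
  rowsum(A, grp)
}

#' Gradient function for a video model's classification logit
#'
#' Wraps a trained `tsnet_model` as the scalar function (single-clip logit)
#' required by [integrated_gradients()].
#'
#' @param model A `tsnet_model`.
#' @return Function mapping a rank-5 single-clip batch to
#'   `list(value, grad)`.
#' @export
tsnet_logit_fn <- function(model) {
  function(x) {
    fw <- tsnet_forward(model, x, train = FALSE)
    grad <- fw$bwd(dlogits = rep(1, length(fw$logits)), need_dx = TRUE)
    list(value = sum(fw$logits), grad = grad)
  }
}

#' Gradient function for an audio model's classification logit
#'
#' Fixes the graph structure and exposes the logit as a function of the
#' node-feature matrix, for [integrated_gradients()].
#'
#' @param model A `gcnlstm_model`.
#' @param graph An `audio_graph` providing the edges and node order.
#' @return Function mapping a node-feature matrix to `list(value, grad)`.
#' @export
gcnlstm_logit_fn <- function(model, graph) {
  function(X) {
    g2 <- graph
    g2$node_features <- X
    fw <- gcn_lstm_forward(model, list(g2), train = FALSE)
    grad <- fw$bwd(dlogits = 1, need_dx = TRUE)[[1]]
    list(value = fw$logits, grad = grad)
  }
}
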