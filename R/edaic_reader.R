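# Reader for per-frame feature tables in the style of clinical-interview
# corpora that distribute extracted features (action units, gaze, pose)
# instead of raw video, plus the attribution workflow over such tables.

#' Read a per-frame facial/behavioural feature table
#'
#' Accepts delimited text with column groups recognised by prefix: `AU*`
#' (facial action units), `gaze*`, and `pose*`. Other columns are kept in
#' the group `other`.
#'
#' @param path CSV/TSV file path (delimiter sniffed from the header line).
#' @return list with `features` (numeric matrix, frames x features) and
#'   `groups` (named character vector mapping column name to group).
#' @export
read_frame_features <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  df <- df[, num, drop = FALSE]
  nm <- colnames(df)
  groups <- rep("other", length(nm))
  groups[grepl("^AU", nm, ignore.case = FALSE)] <- "AU"
  groups[grepl("^gaze", nm, ignore.case = TRUE)] <- "gaze"
  groups[grepl("^pose", nm, ignore.case = TRUE)] <- "pose"
  if (!any(groups %in% c("AU", "gaze", "pose"))) {
    stop("no AU/gaze/pose feature columns found in ", path)
  }
  names(groups) <- nm
  list(features = as.matrix(df), groups = groups)
}

#' Fit a logistic probe on frame features
#'
#' Full-batch gradient descent on the logistic loss with a small L2
#' penalty; a light, differentiable stand-in model for the attribution
#' workflow when a fully trained network is not the object of interest.
#'
#' @param X Feature matrix (frames x features), standardised internally.
#' @param y Binary frame labels.
#' @param iterations Gradient steps.
#' @param lr Learning rate.
#' @param l2 L2 penalty.
#' @return list with `w`, `b`, and the standardisation `center`/`scale`.
#' @export
fit_frame_probe <- function(X, y, iterations = 300, lr = 0.5, l2 = 1e-3) {
  X <- as.matrix(X)
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, `/`)
  w <- rep(0, ncol(X))
  b <- 0
  for (i in seq_len(iterations)) {
    z <- as.vector(Xs %*% w) + b
    r <- sigmoid(z) - y
    gw <- as.vector(crossprod(Xs, r)) / length(y) + l2 * w
    gb <- mean(r)
    w <- w - lr * gw
    b <- b - lr * gb
  }
  list(w = w, b = b, center = center, scale = scale_)
}

#' Attribute frame features with integrated gradients
#'
#' Runs [integrated_gradients()] on a logistic probe over the table and
#' aggregates attributions over frame windows and feature groups.
#'
#' @param table Output of [read_frame_features()].
#' @param y Binary frame labels used to fit the probe (or a pre-fit probe
#'   from [fit_frame_probe()] passed as `probe`).
#' @param probe Optional pre-fit probe.
#' @param every Frame-window length for aggregation.
#' @param steps Integration steps.
#' @return list with `per_frame` (frames x features), `per_window`, and
#'   `per_group` (windows x groups) attribution matrices.
#' @export
attribute_frame_features <- function(table, y = NULL, probe = NULL,
                                     every = 100, steps = 32) {
  X <- table$features
  if (is.null(probe)) {
    if (is.null(y)) stop("either y or a pre-fit probe is required")
    probe <- fit_frame_probe(X, y)
  }
  Xs <- sweep(sweep(X, 2, probe$center), 2, probe$scale, `/`)
  f <- function(m) {
    list(value = sum(m %*% probe$w) + probe$b * nrow(m),
         grad = matrix(probe$w, nrow(m), ncol(m), byrow = TRUE))
  }
  per_frame <- integrated_gradients(f, Xs, baseline = zeros_like(Xs),
                                    steps = steps)
  per_window <- aggregate_attributions(per_frame, every = every)
  grp <- factor(table$groups, levels = unique(table$groups))
  per_group <- t(rowsum(t(per_window), grp))
  colnames(per_group) <- levels(grp)
  list(per_frame = unclass(per_frame), per_window = per_window,
       per_group = per_group)
}
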