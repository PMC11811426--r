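test_that("the joint loss decomposes and vanishes at a perfect fit", {
  r <- joint_loss(logits = c(20, -20), phq8_estimate = c(15, 3),
                  label = c(1, 0), phq8 = c(15, 3))
  expect_lt(r$loss, 1e-6)

  z <- c(0.5, -1.2); y <- c(1, 0)
  r2 <- joint_loss(z, c(0, 0), y, c(5, 5), weights = c(cls = 1, reg = 0))
  bce <- -mean(y * log(plogis(z)) + (1 - y) * log(1 - plogis(z)))
  expect_equal(r2$loss, bce, tolerance = 1e-12)

  # pencil computation on a batch of two
  z <- c(1, -0.5); y <- c(1, 0); est <- c(10, 6); tru <- c(12, 4)
  want <- -mean(log(plogis(c(1, 0.5)))) + mean(c(4, 4))
  expect_equal(joint_loss(z, est, y, tru)$loss, want, tolerance = 1e-12)
  expect_error(joint_loss(NaN, 0, 1, 1), "non-finite")
})

test_that("precision, recall and F1 follow the confusion-matrix arithmetic", {
  # TP = 8, FP = 2, FN = 2
  labels <- c(rep(1, 10), rep(0, 10))
  scores <- c(rep(0.9, 8), rep(0.1, 2), rep(0.9, 2), rep(0.1, 8))
  r <- compute_metrics(scores, labels)
  expect_equal(r$precision, 0.8)
  expect_equal(r$recall, 0.8)
  expect_equal(r$f1, 0.8)

  r2 <- compute_metrics(c(0.9, 0.1, 0.8), c(1, 0, 1),
                        phq8_pred = c(0, 5, 10), phq8_true = c(0, 5, 10))
  expect_equal(r2$rmse, 0)
  expect_equal(r2$mae, 0)
})

test_that("F1 is the harmonic mean of precision and recall on random confusions", {
  set.seed(41)
  for (i in 1:50) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1)
    fn <- sample(0:20, 1); tn <- sample(1:20, 1)
    if (tp + fn == 0 || fp + tn == 0) next
    labels <- c(rep(1, tp + fn), rep(0, fp + tn))
    scores <- c(rep(0.9, tp), rep(0.1, fn), rep(0.9, fp), rep(0.1, tn))
    r <- compute_metrics(scores, labels)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- tp / (tp + fn)
    f1 <- if (p + rec > 0) 2 * p * rec / (p + rec) else 0
    expect_equal(r$f1, f1, tolerance = 1e-12)
    # RMSE dominates MAE on random error vectors
    e <- rnorm(20, sd = 3)
    r3 <- compute_metrics(scores[1:20], labels[1:20], phq8_pred = e,
                          phq8_true = rep(0, 20))
    expect_gte(r3$rmse, r3$mae)
  }
})

test_that("the ROC curve is valid and the AUC matches independent oracles", {
  set.seed(42)
  scores <- runif(60)
  labels <- rbinom(60, 1, 0.45)
  r <- roc_curve(scores, labels)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(utils::tail(r$points$fpr, 1), 1)
  expect_equal(utils::tail(r$points$tpr, 1), 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-12)
  if (requireNamespace("pROC", quietly = TRUE)) {
    pr <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
  }

  # perfect ranking gives AUC 1; a single-class vector gives NA, not 0
  expect_equal(roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_true(is.na(roc_curve(c(0.9, 0.8), c(1, 1))$auc))
})

test_that("grouped evaluation reports each group plus the mixed union", {
  set.seed(43)
  scores <- runif(40)
  labels <- rbinom(40, 1, 0.5)
  sex <- rep(c("male", "female"), 20)
  r <- grouped_eval(scores, labels, sex)
  expect_setequal(names(r), c("male", "female", "mixed"))
  expect_equal(r$mixed$n, 40)

  # single-class group: flagged missing, mixed still present
  labels2 <- labels
  labels2[sex == "male"] <- 1
  r2 <- grouped_eval(scores, labels2, sex)
  expect_true(is.na(r2$male$f1))
  expect_true(is.na(r2$male$auc))
  expect_false(is.na(r2$mixed$f1))

  # absent group level simply does not appear
  r3 <- grouped_eval(scores[1:5], labels[1:5], rep("female", 5))
  expect_setequal(names(r3), c("female", "mixed"))
})

test_that("branch training is reproducible and frozen at zero learning rate", {
  fx <- tiny_corpus()
  idx <- seq_along(fx$data$label)
  cfg <- train_config(iterations = 12, batch_size = 4, lr_branch = 1e-3,
                      seed = 9, log_every = 4)
  m1 <- gcnlstm_init(gcnlstm_config(feature_dim = 8), seed = 1)
  m2 <- gcnlstm_init(gcnlstm_config(feature_dim = 8), seed = 1)
  r1 <- train_branch(m1, fx$data, cfg, idx = idx)
  r2 <- train_branch(m2, fx$data, cfg, idx = idx)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$model$params, r2$model$params)

  cfg0 <- train_config(iterations = 5, batch_size = 4, lr_branch = 0, seed = 9)
  m3 <- gcnlstm_init(gcnlstm_config(feature_dim = 8), seed = 2)
  before <- m3$params
  r3 <- train_branch(m3, fx$data, cfg0, idx = idx)
  expect_equal(r3$model$params, before, tolerance = 1e-15)
})

test_that("training aborts with a diagnostic when the loss diverges", {
  fx <- tiny_corpus()
  m <- gcnlstm_init(gcnlstm_config(feature_dim = 8), seed = 3)
  m$params[["head.reg.b"]] <- 1e6
  cfg <- train_config(iterations = 3, batch_size = 4, seed = 1)
  expect_error(train_branch(m, fx$data, cfg, idx = seq_along(fx$data$label)),
               "diverged")
})

test_that("label-shuffled fusion training stays at chance level", {
  set.seed(44)
  n <- 80
  FV <- matrix(rnorm(n * 8), n, 8)
  FA <- matrix(rnorm(n * 8), n, 8)
  feats <- list(F_V = FV, F_A = FA)
  data <- list(label = rbinom(n, 1, 0.5), phq8 = sample(0:24, n, TRUE),
               split = rep(c("train", "val"), c(50, 30)))
  aucs <- vapply(1:10, function(k) {
    d2 <- data
    d2$label <- sample(d2$label)
    cfg <- train_config(iterations = 120, batch_size = 50, lr_fusion = 2e-3,
                        seed = k)
    tf <- train_fusion(feats, d2, cfg, idx = which(d2$split == "train"))
    evaluate_fusion(tf$model, feats, d2, which(d2$split == "val"))$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("the ablation harness validates variants and shares the split", {
  expect_error(ablate(list(split = "train"), "bogus", train_config()),
               "unknown variant")
  fx <- tiny_corpus()
  cfg <- train_config(iterations = 4, batch_size = 4, seed = 2, log_every = 2)
  tab <- ablate(fx$data, c("audio_only", "gcn_only"), cfg,
                video_cfg = toy_tsnet_cfg(),
                eval_idx = seq_along(fx$data$label))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$model, c("audio_only", "gcn_only"))
  reps <- attr(tab, "reports")
  expect_equal(reps$audio_only$n, reps$gcn_only$n)
})

test_that("checkpoints round-trip and reject mismatched configurations", {
  m <- gcnlstm_init(gcnlstm_config(feature_dim = 8), seed = 5)
  set.seed(45)
  g <- rand_graph(6, 13, threshold = 0.3)
  p <- file.path(tempdir(), "a.ckpt")
  save_checkpoint(m, p)
  m2 <- load_checkpoint(p, expect_hash = mmdepnet:::config_hash(m$cfg))
  expect_identical(gcn_lstm_forward(m, list(g))$logits,
                   gcn_lstm_forward(m2, list(g))$logits)
  expect_error(load_checkpoint(p, expect_hash = "deadbeef"), "hash")

  mv <- tsnet_init(toy_tsnet_cfg(), seed = 6)
  pv <- file.path(tempdir(), "v.ckpt")
  save_checkpoint(mv, pv)
  mv2 <- load_checkpoint(pv)
  x <- rand_clip_batch(1)
  expect_identical(tsnet_forward(mv, x)$logits, tsnet_forward(mv2, x)$logits)
})

test_that("integrated gradients are zero on a null path and exact on linear maps", {
  f_lin <- function(x) list(value = sum(x * c(2, -1, 0.5)), grad = c(2, -1, 0.5))
  x <- c(1, 3, -2)
  expect_equal(integrated_gradients(f_lin, x, baseline = x, steps = 8),
               c(0, 0, 0), ignore_attr = TRUE)
  for (s in c(1, 7)) {
    at <- integrated_gradients(f_lin, x, steps = s)
    expect_equal(as.vector(at), c(2, -1, 0.5) * x, tolerance = 1e-12)
  }
  expect_error(integrated_gradients(f_lin, x, steps = 0), "steps")
  expect_error(integrated_gradients(f_lin, x, baseline = c(1, 2)), "shape")
})

test_that("attribution completeness holds on the audio network", {
  m <- gcnlstm_init(gcnlstm_config(n_mfcc = 4, gcn_hidden = 6,
                                   lstm_hidden = 6, feature_dim = 4), seed = 7)
  set.seed(46)
  g <- rand_graph(6, 4, threshold = 0.3)
  f <- gcnlstm_logit_fn(m, g)
  at <- integrated_gradients(f, g$node_features, steps = 128)
  gap <- f(g$node_features)$value -
    f(mmdepnet:::zeros_like(g$node_features))$value
  expect_lt(abs(sum(at) - gap), max(0.01 * abs(gap), 1e-6))
})

test_that("window aggregation sums attribution rows", {
  A <- matrix(1, 10, 3)
  agg <- aggregate_attributions(A, every = 4)
  expect_equal(dim(agg), c(3, 3))
  expect_equal(agg[, 1], c(4, 4, 2), ignore_attr = TRUE)
})

test_that("frame-feature tables are read, probed and attributed by group", {
  set.seed(47)
  n <- 250
  tbl <- data.frame(AU01 = rnorm(n), AU02 = rnorm(n),
                    gaze_x = rnorm(n), pose_rx = rnorm(n))
  y <- rbinom(n, 1, plogis(2.5 * tbl$AU01))
  p <- file.path(tempdir(), "frames.csv")
  utils::write.csv(tbl, p, row.names = FALSE)
  tab <- read_frame_features(p)
  expect_setequal(unique(tab$groups), c("AU", "gaze", "pose"))

  at <- attribute_frame_features(tab, y = y, every = 100)
  expect_equal(nrow(at$per_window), 3)      # 250 frames in windows of 100
  expect_equal(colnames(at$per_group), c("AU", "gaze", "pose"))
  contrib <- colSums(abs(at$per_group))
  expect_equal(names(which.max(contrib)), "AU")

  bad <- file.path(tempdir(), "bad.csv")
  utils::write.csv(data.frame(a = 1:3, b = 4:6), bad, row.names = FALSE)
  expect_error(read_frame_features(bad), "AU/gaze/pose")
})
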