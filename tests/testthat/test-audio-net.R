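test_that("an edgeless graph reduces the graph convolution to the identity", {
  X <- abs(matrix(rnorm(12), 4, 3))
  g <- build_graph(matrix(c(0, 10, 20, 30), 4, 1), threshold = 0.9)  # no edges
  expect_equal(nrow(g$edges), 0)
  expect_equal(gcn_layer(X, g, diag(3)), X, ignore_attr = TRUE)
})

test_that("a three-node path matches the hand-computed dense propagation", {
  # path 1-2-3 with unit weights; X = identity
  g <- structure(list(node_features = diag(3),
                      edges = matrix(c(1L, 2L, 2L, 3L), 2, 2, byrow = TRUE),
                      weights = c(1, 1), node_order = 1:3, n_nodes = 3L),
                 class = "audio_graph")
  # degrees with self-loops: 2, 3, 2
  d <- c(2, 3, 2)
  Ahat <- (diag(3) + matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)) /
    sqrt(outer(d, d))
  expect_equal(normalized_adjacency(g), Ahat, tolerance = 1e-12)
  expect_equal(gcn_layer(diag(3), g, diag(3)), pmax(Ahat, 0), tolerance = 1e-12)
})

test_that("normalised adjacency rows of a regular unit-weight ring sum to one", {
  n <- 6
  edges <- cbind(1:n, c(2:n, 1))
  edges <- t(apply(edges, 1, sort))
  g <- structure(list(node_features = matrix(0, n, 2),
                      edges = matrix(as.integer(edges), ncol = 2),
                      weights = rep(1, n), node_order = 1:n,
                      n_nodes = as.integer(n)),
                 class = "audio_graph")
  expect_equal(rowSums(normalized_adjacency(g)), rep(1, n), tolerance = 1e-12)
})

test_that("gcn_layer equals the dense loop-built oracle on random graphs", {
  set.seed(21)
  for (trial in 1:20) {
    n <- sample(2:6, 1)
    g <- rand_graph(n, d = 4, threshold = runif(1, 0.2, 0.6))
    X <- g$node_features
    W <- matrix(rnorm(4 * 3), 4, 3)
    expect_lt(max(abs(gcn_layer(X, g, W) - oracle_gcn(X, g, W))), 1e-6)
  }
})

test_that("permuting node labels permutes gcn_layer output rows identically", {
  set.seed(22)
  g <- rand_graph(5, 4, threshold = 0.3)
  W <- matrix(rnorm(12), 4, 3)
  out <- gcn_layer(g$node_features, g, W)
  perm <- sample(5)
  inv <- order(perm)
  g2 <- g
  g2$node_features <- g$node_features[perm, ]
  if (nrow(g$edges) > 0) {
    e2 <- matrix(inv[g$edges], ncol = 2)
    g2$edges <- t(apply(e2, 1, sort))
  }
  out2 <- gcn_layer(g2$node_features, g2, W)
  expect_equal(out2[inv, ], out, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("the forward pass handles degenerate and relabelled graphs", {
  cfg <- gcnlstm_config(n_mfcc = 4, gcn_hidden = 6, lstm_hidden = 5,
                        feature_dim = 4)
  m <- gcnlstm_init(cfg, seed = 2)
  g1 <- build_graph(matrix(rnorm(4), 1, 4))         # single node
  f1 <- gcn_lstm_forward(m, list(g1))
  expect_true(is.finite(f1$logits))
  expect_identical(f1$logits, gcn_lstm_forward(m, list(g1))$logits)
  expect_error(gcn_lstm_forward(m, list()), "empty")

  set.seed(23)
  g <- rand_graph(6, 4, threshold = 0.3)
  perm <- sample(6)
  inv <- order(perm)
  g2 <- g
  g2$node_features <- g$node_features[perm, ]
  if (nrow(g$edges) > 0) {
    e2 <- matrix(inv[g$edges], ncol = 2)
    g2$edges <- t(apply(e2, 1, sort))
  }
  g2$node_order <- perm                     # restores temporal order
  fa <- gcn_lstm_forward(m, list(g))
  fb <- gcn_lstm_forward(m, list(g2))
  expect_equal(fa$logits, fb$logits, tolerance = 1e-10)
  expect_equal(fa$F_A, fb$F_A, tolerance = 1e-10)
})

test_that("zero node features and zero biases give zero logits", {
  cfg <- gcnlstm_config(n_mfcc = 3, gcn_hidden = 4, lstm_hidden = 4,
                        feature_dim = 3)
  m <- gcnlstm_init(cfg, seed = 3)
  g <- build_graph(matrix(0, 5, 3))
  expect_equal(gcn_lstm_forward(m, list(g))$logits, 0, tolerance = 1e-12)
})

test_that("masked padding steps leave the LSTM final state unchanged", {
  set.seed(24)
  p <- mmdepnet:::lstm_init(list(), "l", 3, 4)
  x <- array(rnorm(5 * 2 * 3), c(5, 2, 3))
  lens <- c(5L, 3L)
  out <- mmdepnet:::lstm_fwd(x, lens, p, "l")$out
  x_pad <- array(0, c(8, 2, 3))
  x_pad[1:5, , ] <- x
  out_pad <- mmdepnet:::lstm_fwd(x_pad, lens, p, "l")$out
  expect_equal(out, out_pad, tolerance = 1e-12)
})

test_that("temporal subsampling before the LSTM shortens the sequence", {
  cfg1 <- gcnlstm_config(n_mfcc = 4, subsample = 1)
  cfg2 <- gcnlstm_config(n_mfcc = 4, subsample = 3)
  m1 <- gcnlstm_init(cfg1, seed = 4)
  m2 <- gcnlstm_init(cfg2, seed = 4)
  set.seed(25)
  g <- rand_graph(9, 4, threshold = 0.3)
  f1 <- gcn_lstm_forward(m1, list(g))
  f2 <- gcn_lstm_forward(m2, list(g))
  expect_true(is.finite(f2$logits))
  expect_false(isTRUE(all.equal(f1$logits, f2$logits)))
})

test_that("architecture variants drop the intended component", {
  set.seed(26)
  g <- rand_graph(7, 4, threshold = 0.3)
  for (arch in c("gcn_only", "lstm_only")) {
    m <- gcnlstm_init(gcnlstm_config(n_mfcc = 4, arch = arch), seed = 5)
    has_lstm <- any(grepl("^lstm", names(m$params)))
    has_gcn <- any(grepl("^gcn", names(m$params)))
    expect_equal(has_lstm, arch == "lstm_only")
    expect_equal(has_gcn, arch == "gcn_only")
    expect_true(is.finite(gcn_lstm_forward(m, list(g))$logits))
  }
})
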