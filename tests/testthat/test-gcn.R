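test_that("node labels summarize rows of the scaled impact matrix", {
  # constant row k -> label exactly k
  s <- matrix(3, 5, 5)
  expect_equal(node_labels(s, n_classes = 7), rep(3L, 5))

  # 2-species model: each label is the single off-diagonal value in its row
  s2 <- rbind(c(1, 4), c(2, 1))
  expect_equal(node_labels(s2, n_classes = 7), c(4L, 2L))

  # random model: brute-force mean-row recomputation
  m <- generate_model(generator_config(n_species = 12, seed = 19))
  si <- enhancement_factor(m)$scaled_impact
  lab <- node_labels(m, n_classes = 7)
  oracle <- vapply(1:12, function(i) {
    v <- mean(si[i, setdiff(1:12, i)])
    max(1L, min(7L, as.integer(floor(v + 0.5))))
  }, integer(1))
  expect_identical(lab, oracle)

  # clipping to the class alphabet
  expect_equal(node_labels(matrix(9, 4, 4), n_classes = 5), rep(5L, 4))
})

test_that("node features match closed forms on canonical graphs", {
  # directed out-star: center out-degree n-1, leaves 0
  star <- influence_network(5, data.frame(from = 1, to = 2:5, sign = 1,
                                          weight = 1))
  X <- node_features(star)
  expect_equal(unname(X[1, "out_degree"]), 4)
  expect_equal(unname(X[2:5, "out_degree"]), rep(0, 4))
  expect_equal(unname(X[2:5, "in_degree"]), rep(1, 4))

  # isolated node: degrees and clustering zero
  iso <- influence_network(3, data.frame(from = 1, to = 2, sign = 1,
                                         weight = 1))
  expect_equal(unname(node_features(iso)[3, c("in_degree", "out_degree",
                                              "clustering")]),
               c(0, 0, 0))

  # complete unsigned graph of 4: clustering 1 everywhere
  idx <- expand.grid(from = 1:4, to = 1:4)
  idx <- idx[idx$from != idx$to, ]
  comp <- influence_network(4, data.frame(idx, sign = 1, weight = 1))
  expect_equal(unname(node_features(comp)[, "clustering"]), rep(1, 4))

  # negative incident-edge fraction
  mixed <- influence_network(3, data.frame(from = c(1, 3), to = c(2, 2),
                                           sign = c(-1, 1), weight = 1))
  expect_equal(unname(node_features(mixed)[2, "frac_negative"]), 1 / 2)
})

test_that("the expected-impact feature tracks the true labels closely", {
  models <- generate_ensemble(12, seed = 41, size_range = c(5, 40))
  C <- corpus_n_classes(models)
  agree <- unlist(lapply(models, function(m) {
    net <- build_influence_network(m)
    est <- netpert:::expected_impact_label(net)
    est <- pmin(pmax(as.integer(floor(est + 0.5)), 1L), C)
    est == node_labels(m, n_classes = C)
  }))
  expect_gt(mean(agree), 0.9)
})

test_that("full-graph assembly adds one center node wired to the hubs", {
  nets <- list(chain_network(3), chain_network(4))
  labs <- list(rep(1L, 3), rep(2L, 4))
  b <- assemble_full_graph(nets, labs, split = 0.5, seed = 1, n_classes = 3)
  expect_equal(nrow(b$X), 8)                       # 3 + 4 + center
  center <- 8
  expect_equal(sum(b$A[center, ]), 2)              # one edge per model
  expect_true(is.na(b$y[center]))
  expect_false(b$train_mask[center] || b$test_mask[center])
  # chain hubs: interior nodes have total degree 2; tie broken lowest index
  expect_equal(which(b$A[center, 1:3] == 1), 2)
  # masks split whole models
  mdl <- rep(1:2, c(3, 4))
  expect_true(all(tapply(b$train_mask[1:7], mdl, function(v)
    all(v) || all(!v))))
  # single network: exactly one center edge
  b1 <- assemble_full_graph(nets[1], labs[1], seed = 1, n_classes = 3)
  expect_equal(sum(b1$A[4, ]), 1)
})

test_that("sparse-graph batches are block-diagonal with one-hot pooling", {
  nets <- list(chain_network(3), chain_network(4))
  labs <- list(rep(1L, 3), rep(2L, 4))
  b <- assemble_sparse_graph(nets, labs, split = 0.5, seed = 2, n_classes = 3)
  expect_equal(dim(b$A), c(7, 7))
  expect_true(all(b$A[1:3, 4:7] == 0))
  expect_true(all(b$A[4:7, 1:3] == 0))
  expect_equal(rowSums(b$P), rep(1, 7))
  expect_equal(colSums(b$P), c(3, 4))
  expect_setequal(which(b$train_mask | b$test_mask), 1:7)
  expect_equal(sum(b$train_mask & b$test_mask), 0)
})

test_that("gcn_layer implements the normalized propagation rule", {
  # edgeless graph: Ahat = I, layer reduces to ReLU(HW)
  H <- matrix(c(1, -2, 3, 4), 2, 2)
  W <- diag(2)
  expect_equal(gcn_layer(H, matrix(0, 2, 2), W),
               pmax(H, 0))

  # two-node complete graph, H = I, W = I: operator is 0.5 * ones(2,2)
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(gcn_layer(diag(2), A, diag(2)),
               matrix(0.5, 2, 2))

  # all-negative pre-activation clamps to zero under ReLU
  expect_equal(gcn_layer(matrix(1, 2, 2), A, -diag(2)),
               matrix(0, 2, 2))

  # softmax rows sum to one
  Z <- gcn_layer(matrix(rnorm(6), 2, 3), A, diag(3), activation = "softmax")
  expect_equal(rowSums(Z), c(1, 1))
})

test_that("gcn_layer equals brute-force dense evaluation on random inputs", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(3:8, 1); d <- sample(2:5, 1); f <- sample(2:4, 1)
    A <- matrix(rbinom(n * n, 1, 0.4), n, n)
    A <- pmax(A, t(A)); diag(A) <- 0
    H <- matrix(rnorm(n * d), n, d)
    W <- matrix(rnorm(d * f), d, f)
    Ahat <- A + diag(n)
    Dhat <- diag(rowSums(Ahat))
    brute <- pmax(solve(sqrt(Dhat)) %*% Ahat %*% solve(sqrt(Dhat)) %*% H %*% W, 0)
    expect_equal(gcn_layer(H, A, W), brute, tolerance = 1e-10)
  }
})

test_that("training is deterministic and reduces the loss on separable data", {
  # labels perfectly determined by network size (a feature that survives
  # graph smoothing): small chains labeled 1, larger chains labeled 2
  nets <- c(lapply(rep(3, 6), chain_network), lapply(rep(12, 6), chain_network))
  labs <- c(lapply(rep(3, 6), function(n) rep(1L, n)),
            lapply(rep(12, 6), function(n) rep(2L, n)))
  b <- assemble_sparse_graph(nets, labs, split = 0.5, seed = 4, n_classes = 2)
  fit <- train_gcn(b, gcn_config(n_classes = 2, seed = 1))
  expect_gte(fit$train_accuracy, 0.95)
  expect_lte(fit$loss_history[length(fit$loss_history)], fit$loss_history[1])

  # identical seeds reproduce the loss history bit for bit
  fit2 <- train_gcn(b, gcn_config(n_classes = 2, seed = 1))
  expect_identical(fit$loss_history, fit2$loss_history)
  expect_identical(fit$W1, fit2$W1)

  # a class absent from the training mask warns
  labs_bad <- labs
  labs_bad[[1]][1] <- 2L
  b2 <- assemble_sparse_graph(nets, labs_bad, split = 0.5, seed = 4,
                              n_classes = 3)
  expect_warning(train_gcn(b2, gcn_config(n_classes = 3, max_epochs = 2,
                                          seed = 1)),
                 "absent")
})

test_that("predicted enhancement factors have the ratio structure", {
  nets <- lapply(c(4, 5), chain_network)
  labs <- lapply(c(4, 5), function(n) rep(2L, n))
  b <- assemble_sparse_graph(nets, labs, split = 0.5, seed = 3, n_classes = 4)
  fit <- suppressWarnings(
    train_gcn(b, gcn_config(n_classes = 4, max_epochs = 20, seed = 2)))
  Ehat <- predict_enhancement(fit, b)
  expect_equal(length(Ehat), 2)
  for (E in Ehat) {
    expect_equal(diag(E), rep(1, nrow(E)))
    expect_equal(E * t(E), matrix(1, nrow(E), ncol(E)))   # E_ij * E_ji = 1
  }
  # constant predicted class means no enhancement
  cls <- predict(fit, b)
  if (length(unique(cls[1:4])) == 1) {
    expect_equal(Ehat[[1]], matrix(1, 4, 4))
  }
})

test_that("batch assembly and prediction are permutation-equivariant", {
  models <- generate_ensemble(6, seed = 55, size_range = c(4, 12))
  C <- corpus_n_classes(models)
  nets <- lapply(models, build_influence_network)
  labs <- lapply(models, node_labels, n_classes = C)
  perm <- c(4, 1, 6, 2, 5, 3)

  b <- assemble_sparse_graph(nets, labs, split = 0.5, seed = 9, n_classes = C)
  bp <- assemble_sparse_graph(nets[perm], labs[perm], split = 0.5, seed = 9,
                              n_classes = C)
  fit <- suppressWarnings(
    train_gcn(b, gcn_config(n_classes = C, max_epochs = 30, seed = 7)))
  cls <- predict(fit, b)
  clsp <- predict(fit, bp)
  sizes <- vapply(nets, `[[`, integer(1), "n_nodes")
  ends <- cumsum(sizes); starts <- ends - sizes + 1
  by_model <- lapply(seq_along(nets), function(k) cls[starts[k]:ends[k]])
  expect_identical(unlist(by_model[perm]), unname(clsp))
})
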