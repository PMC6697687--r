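#' Per-node impact labels from the scaled impact matrix
#'
#' The learning target of the enhancement predictor: each node is assigned
#' one small integer class summarizing how strongly it tends to respond
#' across sources. `label(i)` is the mean over columns `j != i` of the
#' node's row of the scaled impact matrix, rounded half-up and clipped to
#' `1..n_classes`. When a node's row is constant `k` the label is exactly
#' `k`. A corpus-wide class count `n_classes = ceiling(log2(N_max)) + 1`
#' covers every scaled rank that can occur on models up to `N_max` species.
#'
#' @param model a [dynamical_model()] (or a precomputed scaled impact
#'   matrix).
#' @param n_classes number of label classes `C`.
#' @param stat `"mean"` (default) or `"median"` row summary.
#' @return integer vector of per-node classes in `1..n_classes`.
#' @export
node_labels <- function(model, n_classes, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  si <- if (inherits(model, "dynamical_model")) {
    enhancement_factor(model)$scaled_impact
  } else as.matrix(model)
  n <- nrow(si)
  if (n == 1) return(1L)
  f <- if (stat == "mean") mean else stats::median
  lab <- vapply(seq_len(n), function(i) f(si[i, -i]), numeric(1))
  lab <- as.integer(floor(lab + 0.5))      # round half up
  pmin(pmax(lab, 1L), as.integer(n_classes))
}

#' Number of label classes for a model corpus
#'
#' @param models list of [dynamical_model()] objects.
#' @return `ceiling(log2(max model size)) + 1`.
#' @export
corpus_n_classes <- function(models) {
  n_max <- max(vapply(models, n_species, integer(1)))
  as.integer(int_bit_length(n_max - 1L) + 1L)
}

#' Topological node features for the GCN
#'
#' The default descriptor set (`D = 7` per node): in-degree, out-degree,
#' `log(1 + N)` (network size, shared by all nodes of a model), local
#' clustering coefficient on the undirected projection, fraction of
#' negative incident edges, mean inverse directed distance to all other
#' nodes (unreachable contributing 0), and the expected impact label.
#'
#' The expected impact label exploits the structure of the learning target:
#' scaled-impact values are ranks of Jacobian magnitudes, and the sparsity
#' pattern pins those ranks down almost completely — all exact zeros of a
#' column tie at the lowest rank, so a zero entry's scaled value is exactly
#' 1 and a nonzero entry's scaled value lies in the narrow band above the
#' zero block, independent of the actual kinetic magnitudes. The feature is
#' the node's expected label under the assumption that each nonzero entry
#' sits at the midpoint of that band (the Jacobian diagonal is taken as
#' nonzero, as any degradation term makes it). It is a pure function of the
#' influence-network topology.
#'
#' Features are raw here; batch assembly standardizes them. With
#' `identity = TRUE` a one-hot identity block is appended (featureless-GCN
#' fallback).
#'
#' @param network an [influence_network()].
#' @param identity append one-hot identity features.
#' @return numeric matrix, one row per node.
#' @export
node_features <- function(network, identity = FALSE) {
  stopifnot(inherits(network, "influence_network"))
  n <- network$n_nodes
  e <- network$edges
  in_deg <- tabulate(e$to, nbins = n)
  out_deg <- tabulate(e$from, nbins = n)
  g <- as_igraph(network, directed = TRUE)
  gu <- as_igraph(network, directed = FALSE)
  clust <- igraph::transitivity(gu, type = "local", isolates = "zero")
  neg_in <- tabulate(e$to[e$sign < 0], nbins = n) +
    tabulate(e$from[e$sign < 0], nbins = n)
  tot_in <- in_deg + out_deg
  frac_neg <- ifelse(tot_in > 0, neg_in / tot_in, 0)
  d <- igraph::distances(g, mode = "out")
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  mean_inv_dist <- if (n > 1) rowSums(inv) / (n - 1) else rep(0, n)
  X <- cbind(in_degree = in_deg, out_degree = out_deg,
             log_size = rep(log1p(n), n), clustering = clust,
             frac_negative = frac_neg, mean_inv_distance = mean_inv_dist,
             expected_impact = expected_impact_label(network))
  if (identity) X <- cbind(X, diag(1, n))
  X
}

# Expected per-node impact label from the sparsity pattern alone: within a
# column, zeros have scaled value 1 and nonzeros sit in the band of ranks
# above the zero block; assume the band midpoint for each nonzero.
expected_impact_label <- function(network) {
  n <- network$n_nodes
  if (n == 1) return(1)
  A <- (abs(adjacency_matrix(network, signed = FALSE)) != 0) * 1
  diag(A) <- 1                         # Jacobian diagonal taken as nonzero
  nnz <- colSums(A)                    # nonzero count of column j
  mid <- pmax(n - nnz + 1 + floor((nnz - 1) / 2), 1)
  s_mid <- int_bit_length(as.integer(mid) - 1L) + 1L
  vapply(seq_len(n), function(i) {
    mean(ifelse(A[i, -i] == 1, s_mid[-i], 1))
  }, numeric(1))
}

# Shared assembly internals -------------------------------------------------

# symmetrized unsigned binary adjacency of one network
sym_adjacency <- function(network) {
  A <- abs(adjacency_matrix(network, signed = FALSE))
  (pmax(A, t(A)) != 0) * 1
}

split_models <- function(n_models, split, seed) {
  k_train <- max(1L, min(n_models - 1L, round(split * n_models)))
  if (n_models == 1) k_train <- 1L
  with_local_seed(seed, sort(sample.int(n_models, k_train)))
}

assemble_common <- function(networks, labels, split, seed, n_classes) {
  stopifnot(length(networks) >= 1, length(labels) == length(networks))
  sizes <- vapply(networks, `[[`, integer(1), "n_nodes")
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  X_raw <- do.call(rbind, lapply(networks, node_features))
  train_models <- split_models(length(networks), split, seed)
  node_model <- rep(seq_along(networks), sizes)
  list(sizes = sizes, starts = starts, ends = ends, X_raw = X_raw,
       y = as.integer(unlist(labels)), node_model = node_model,
       train_models = train_models,
       provenance = data.frame(
         model_id = vapply(networks, `[[`, "", "model_id"),
         start = starts, end = ends))
}

standardize <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  list(X = sweep(sweep(X, 2, center), 2, scale, `/`),
       center = center, scale = scale)
}

new_graph_batch <- function(regime, X, A, P, y, train_mask, test_mask,
                            provenance, center, scale, n_classes) {
  structure(list(regime = regime, X = X, A = A, P = P, y = y,
                 train_mask = train_mask, test_mask = test_mask,
                 provenance = provenance, feat_center = center,
                 feat_scale = scale, n_classes = as.integer(n_classes)),
            class = "graph_batch")
}

#' @export
print.graph_batch <- function(x, ...) {
  cat("<graph_batch> [", x$regime, "] ", nrow(x$X), " nodes, ",
      nrow(x$provenance), " models, D = ", ncol(x$X), ", C = ",
      x$n_classes, "; train/test nodes = ", sum(x$train_mask), "/",
      sum(x$test_mask), "\n", sep = "")
  invisible(x)
}

#' Assemble the full-graph GCN input
#'
#' All influence networks are united into one giant graph together with a
#' single extra center node, connected by undirected weight-1 edges to the
#' hub (highest total-degree node, ties broken by lowest index) of each
#' member network. The center carries the mean feature vector and no label,
#' and is excluded from both masks. Train/test masks split whole models
#' (never nodes of one model).
#'
#' @param networks list of [influence_network()] objects.
#' @param labels list of integer label vectors parallel to `networks`.
#' @param split fraction of models assigned to training (default 0.8).
#' @param seed RNG seed for the model split.
#' @param n_classes label alphabet size `C`.
#' @return a `graph_batch` with `regime = "full"`; the center node is the
#'   last row.
#' @export
assemble_full_graph <- function(networks, labels, split = 0.8, seed = 1,
                                n_classes = max(unlist(labels))) {
  cm <- assemble_common(networks, labels, split, seed, n_classes)
  n_tot <- sum(cm$sizes) + 1
  A <- matrix(0, n_tot, n_tot)
  for (k in seq_along(networks)) {
    idx <- cm$starts[k]:cm$ends[k]
    A[idx, idx] <- sym_adjacency(networks[[k]])
    deg <- tabulate(networks[[k]]$edges$from, nbins = cm$sizes[k]) +
      tabulate(networks[[k]]$edges$to, nbins = cm$sizes[k])
    hub <- which.max(deg)                      # ties -> lowest index
    A[n_tot, cm$starts[k] + hub - 1] <- 1
    A[cm$starts[k] + hub - 1, n_tot] <- 1
  }
  st <- standardize(cm$X_raw)
  X <- rbind(st$X, colMeans(st$X))
  in_train <- cm$node_model %in% cm$train_models
  new_graph_batch("full", X, A, P = NULL,
                  y = c(cm$y, NA_integer_),
                  train_mask = c(in_train, FALSE),
                  test_mask = c(!in_train, FALSE),
                  provenance = cm$provenance,
                  st$center, st$scale, n_classes)
}

#' Assemble the sparse-graph GCN input
#'
#' Block-diagonal batching: the adjacency is a sparse block-diagonal matrix
#' (one block per influence network, in input order, no connections across
#' models) and a pooling matrix `P` assigns each node to exactly one model.
#' The pooling is used to collect per-model mean features, which are
#' appended to each node's feature vector so that every node sees a summary
#' of its own graph. Train/test masks split whole models.
#'
#' @inheritParams assemble_full_graph
#' @return a `graph_batch` with `regime = "sparse"`; `P` is the
#'   `n_nodes x n_models` one-hot assignment.
#' @export
assemble_sparse_graph <- function(networks, labels, split = 0.8, seed = 1,
                                  n_classes = max(unlist(labels))) {
  cm <- assemble_common(networks, labels, split, seed, n_classes)
  n_tot <- sum(cm$sizes)
  A <- matrix(0, n_tot, n_tot)
  for (k in seq_along(networks)) {
    idx <- cm$starts[k]:cm$ends[k]
    A[idx, idx] <- sym_adjacency(networks[[k]])
  }
  P <- matrix(0, n_tot, length(networks))
  P[cbind(seq_len(n_tot), cm$node_model)] <- 1
  st <- standardize(cm$X_raw)
  pooled <- sweep(crossprod(P, st$X), 1, colSums(P), `/`)  # model means
  X <- cbind(st$X, P %*% pooled)
  colnames(X) <- c(colnames(st$X), paste0("graph_", colnames(st$X)))
  in_train <- cm$node_model %in% cm$train_models
  new_graph_batch("sparse", X, A, P = P, y = cm$y,
                  train_mask = in_train, test_mask = !in_train,
                  provenance = cm$provenance,
                  st$center, st$scale, n_classes)
}

#' One graph-convolution layer
#'
#' The layer-wise propagation rule
#' `f(H, A) = activation(Dhat^(-1/2) Ahat Dhat^(-1/2) H W)` with
#' `Ahat = A + I` (self-loops added) and `Dhat` the diagonal degree matrix
#' of `Ahat`. Hidden layers use ReLU; the output layer uses a row-wise
#' softmax over classes.
#'
#' @param H input node representations (`N x D_in`).
#' @param A nonnegative adjacency (`N x N`).
#' @param W weight matrix (`D_in x D_out`).
#' @param activation `"relu"`, `"softmax"` or `"identity"`.
#' @return matrix `N x D_out`.
#' @export
gcn_layer <- function(H, A, W, activation = c("relu", "softmax",
                                              "identity")) {
  activation <- match.arg(activation)
  H <- as.matrix(H); A <- as.matrix(A); W <- as.matrix(W)
  if (any(A < 0)) stop("adjacency must be nonnegative")
  M <- gcn_operator(A)
  Z <- as.matrix(M %*% H) %*% W
  switch(activation,
         relu = pmax(Z, 0),
         softmax = row_softmax(Z),
         identity = Z)
}

# Dhat^{-1/2} (A + I) Dhat^{-1/2}, as a sparse Matrix for batch-size graphs.
gcn_operator <- function(A) {
  n <- nrow(A)
  Ahat <- A + diag(1, n)
  dh <- 1 / sqrt(rowSums(Ahat))
  Matrix::Matrix(Ahat * outer(dh, dh), sparse = TRUE)
}

row_softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' GCN training configuration
#'
#' @param hidden_dim hidden layer width (default 16).
#' @param n_classes output classes `C` (default taken from the batch).
#' @param learning_rate Adam step size (default 0.01).
#' @param dropout dropout probability on the hidden layer (default 0.5).
#' @param max_epochs training epochs (default 200; the final model is used).
#' @param seed RNG seed controlling initialization and dropout.
#' @return a `gcn_config` list.
#' @export
gcn_config <- function(hidden_dim = 16, n_classes = NULL,
                       learning_rate = 0.01, dropout = 0.5,
                       max_epochs = 200, seed = 1) {
  stopifnot(hidden_dim >= 1, max_epochs >= 1,
            learning_rate > 0, learning_rate < 1,
            dropout >= 0, dropout < 1)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 n_classes = n_classes, learning_rate = learning_rate,
                 dropout = dropout, max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "gcn_config")
}

#' Train the two-layer GCN on a graph batch
#'
#' Fits the node-classification stack
#' `softmax(M ReLU(M X W1) W2)` (with `M` the normalized operator of
#' [gcn_layer()], dropout after the ReLU) by minimizing cross-entropy over
#' the training mask with Adam. Training is deterministic given
#' `config$seed`. The returned fit carries the loss history, final train
#' and test accuracies and the majority-class baseline on the test nodes.
#'
#' @param batch a `graph_batch` from [assemble_full_graph()] or
#'   [assemble_sparse_graph()].
#' @param config a [gcn_config()].
#' @return object of class `gcn_fit` with components `W1`, `W2`, `config`,
#'   `loss_history`, `train_accuracy`, `test_accuracy`,
#'   `majority_baseline`, `classes` (per-node argmax predictions on the
#'   training batch), plus the batch's feature scaling and regime.
#' @export
train_gcn <- function(batch, config = gcn_config()) {
  stopifnot(inherits(batch, "graph_batch"))
  C <- if (!is.null(config$n_classes)) config$n_classes else batch$n_classes
  h <- config$hidden_dim
  X <- batch$X
  D <- ncol(X)
  N <- nrow(X)
  tr <- which(batch$train_mask)
  if (!length(tr)) stop("training mask is empty")
  y <- batch$y
  present <- sort(unique(y[tr]))
  missing_cls <- setdiff(seq_len(C), present)
  if (length(missing_cls)) {
    warning("classes absent from training mask (weight 0 in the loss): ",
            paste(missing_cls, collapse = ", "))
  }
  M <- gcn_operator(batch$A)
  MX <- as.matrix(M %*% X)
  Y <- matrix(0, N, C)
  Y[cbind(tr, y[tr])] <- 1
  keep <- 1 - config$dropout
  lr <- config$learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  with_local_seed(config$seed, {
    glorot <- function(fin, fout) {
      s <- sqrt(6 / (fin + fout))
      matrix(stats::runif(fin * fout, -s, s), fin, fout)
    }
    W1 <- glorot(D, h); W2 <- glorot(h, C)
    mom <- list(W1 = W1 * 0, W2 = W2 * 0)
    vel <- list(W1 = W1 * 0, W2 = W2 * 0)
    loss_hist <- numeric(config$max_epochs)
    for (ep in seq_len(config$max_epochs)) {
      Z1 <- MX %*% W1
      H1 <- pmax(Z1, 0)
      Dm <- if (keep < 1) {
        matrix((stats::runif(N * h) < keep) / keep, N, h)
      } else matrix(1, N, h)
      H1d <- H1 * Dm
      Z2 <- as.matrix(M %*% (H1d %*% W2))
      Pm <- row_softmax(Z2)
      loss_hist[ep] <- -mean(log(pmax(Pm[cbind(tr, y[tr])], 1e-12)))
      G2 <- (Pm - Y)
      G2[-tr, ] <- 0
      G2 <- G2 / length(tr)
      MG2 <- as.matrix(M %*% G2)
      dW2 <- crossprod(H1d, MG2)
      dH1 <- (MG2 %*% t(W2)) * Dm * (Z1 > 0)
      dW1 <- crossprod(MX, dH1)
      for (nm in c("W1", "W2")) {
        g <- if (nm == "W1") dW1 else dW2
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g^2
        mhat <- mom[[nm]] / (1 - b1^ep)
        vhat <- vel[[nm]] / (1 - b2^ep)
        upd <- lr * mhat / (sqrt(vhat) + eps)
        if (nm == "W1") W1 <- W1 - upd else W2 <- W2 - upd
      }
    }
    fit <- structure(
      list(W1 = W1, W2 = W2, config = config, n_classes = C,
           loss_history = loss_hist, regime = batch$regime,
           feat_center = batch$feat_center, feat_scale = batch$feat_scale),
      class = "gcn_fit")
    cls <- predict(fit, batch, type = "class")
    te <- which(batch$test_mask)
    fit$classes <- cls
    fit$train_accuracy <- mean(cls[tr] == y[tr])
    maj <- as.integer(names(which.max(table(y[tr]))))
    fit$majority_class <- maj
    fit$test_accuracy <- if (length(te)) mean(cls[te] == y[te]) else NA_real_
    fit$majority_baseline <- if (length(te)) mean(y[te] == maj) else NA_real_
    fit
  })
}

#' @export
print.gcn_fit <- function(x, ...) {
  cat("<gcn_fit> [", x$regime, "] hidden ", ncol(x$W1), ", classes ",
      x$n_classes, ", ", length(x$loss_history), " epochs\n",
      "  final train loss ", signif(x$loss_history[length(x$loss_history)], 4),
      "; train acc ", signif(x$train_accuracy, 3),
      "; test acc ", signif(x$test_accuracy, 3),
      " (majority baseline ", signif(x$majority_baseline, 3), ")\n",
      sep = "")
  invisible(x)
}

#' @export
coef.gcn_fit <- function(object, ...) list(W1 = object$W1, W2 = object$W2)

#' @export
plot.gcn_fit <- function(x, ...) {
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "l",
                 xlab = "epoch", ylab = "training cross-entropy", ...)
  invisible(x)
}

#' Predict node classes (or class probabilities) for a graph batch
#'
#' Deterministic forward pass (no dropout). Argmax ties break toward the
#' lowest class index.
#'
#' @param object a [train_gcn()] fit.
#' @param batch a `graph_batch` whose feature dimension matches the fit.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... unused.
#' @return integer vector of classes, or the `N x C` probability matrix.
#' @export
predict.gcn_fit <- function(object, batch, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(batch, "graph_batch"))
  if (ncol(batch$X) != nrow(object$W1)) {
    stop("feature dimension mismatch: batch has ", ncol(batch$X),
         ", fit expects ", nrow(object$W1))
  }
  M <- gcn_operator(batch$A)
  H1 <- pmax(as.matrix(M %*% batch$X) %*% object$W1, 0)
  Pm <- row_softmax(as.matrix(M %*% (H1 %*% object$W2)))
  if (type == "prob") return(Pm)
  apply(Pm, 1, which.max)          # which.max: first (lowest) class on ties
}

#' Reconstruct predicted enhancement factors from a fitted GCN
#'
#' Per-node predicted classes are turned back into an enhancement matrix
#' per model with the same normalization structure as the true factor:
#' `E_hat[i, j] = class(i) / class(j)`, diagonal 1. When every node of a
#' model gets the same class the factor is all ones (no enhancement), and
#' `E_hat[i, j] * E_hat[j, i] = 1` always.
#'
#' @param fit a [train_gcn()] fit.
#' @param batch the `graph_batch` to predict on (its provenance defines the
#'   per-model blocks; the full-graph center node is ignored).
#' @return named list of enhancement matrices, one per model in the batch.
#' @export
predict_enhancement <- function(fit, batch) {
  cls <- predict(fit, batch, type = "class")
  out <- lapply(seq_len(nrow(batch$provenance)), function(k) {
    idx <- batch$provenance$start[k]:batch$provenance$end[k]
    l <- cls[idx]
    E <- outer(l, l, `/`)
    diag(E) <- 1
    E
  })
  names(out) <- batch$provenance$model_id
  out
}
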