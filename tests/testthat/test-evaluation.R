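test_that("spearman score is 1 for self, -1 for reversal", {
  set.seed(1)
  S <- matrix(rnorm(64), 8, 8)
  expect_equal(as.numeric(spearman_score(S, S)), 1)
  expect_equal(as.numeric(spearman_score(-S, S)), -1)
})

test_that("spearman score matches an independent midrank oracle per column", {
  set.seed(3)
  A <- matrix(rnorm(64), 8, 8)
  B <- matrix(sample(1:4, 64, replace = TRUE), 8, 8)  # heavy ties
  got <- spearman_score(A, B)
  oracle <- mean(vapply(1:8, function(j) {
    spearman_oracle(A[-j, j], B[-j, j])
  }, numeric(1)))
  expect_equal(as.numeric(got), oracle, tolerance = 1e-12)
  # cross-check against the stock implementation too
  stock <- mean(vapply(1:8, function(j) {
    suppressWarnings(cor(A[-j, j], B[-j, j], method = "spearman"))
  }, numeric(1)))
  expect_equal(as.numeric(got), stock, tolerance = 1e-12)
})

test_that("constant or failed columns are skipped, all-constant warns NaN", {
  S_true <- matrix(rnorm(25), 5, 5)
  S_pred <- S_true
  S_pred[-2, 2] <- 7               # constant column: skipped
  sc <- spearman_score(S_pred, S_true)
  expect_equal(attr(sc, "n_skipped"), 1)
  expect_equal(as.numeric(sc), 1)  # remaining columns still perfect

  S_nan <- S_true
  S_nan[-3, 3] <- NaN              # failed ground-truth column: skipped
  expect_equal(attr(spearman_score(S_pred, S_nan), "n_skipped"), 2)

  expect_warning(out <- spearman_score(matrix(1, 4, 4), matrix(2, 4, 4)),
                 "constant")
  expect_true(is.nan(as.numeric(out)))
})

test_that("spearman score is invariant under increasing transforms", {
  set.seed(8)
  for (rep in 1:5) {
    S <- matrix(rnorm(49), 7, 7)
    T_ <- matrix(rnorm(49), 7, 7)
    base <- as.numeric(spearman_score(S, T_))
    expect_equal(as.numeric(spearman_score(exp(S), T_)), base,
                 tolerance = 1e-12)
    expect_equal(as.numeric(spearman_score(S, atan(T_) * 3 + 1)), base,
                 tolerance = 1e-12)
  }
})

test_that("benchmark scores the biochemical method at exactly 1", {
  models <- generate_ensemble(5, seed = 6, size_range = c(6, 15))
  rep_ <- benchmark_models(models, methods = c("biochemical",
                                               "distance_directed"))
  expect_equal(rep_$scores$biochemical, rep(1, 5))
  expect_equal(unname(rep_$means["biochemical"]), 1)
  expect_true(all(abs(rep_$scores$distance_directed) <= 1))

  # empty method list: a report with zero method columns
  rep0 <- benchmark_models(models, methods = character(0))
  expect_equal(length(rep0$methods), 0)
  expect_equal(names(rep0$scores), c("model_id", "n_species"))
})

test_that("a degenerate model yields NA without aborting the corpus", {
  good <- generate_model(generator_config(n_species = 6, seed = 1))
  # decoupled model: every prediction column is constant, score undefined
  bad <- dynamical_model(diag(-1, 3), model_id = "degenerate")
  rep_ <- suppressWarnings(
    benchmark_models(list(good, bad), methods = c("distance_directed")))
  expect_false(is.na(rep_$scores$distance_directed[1]))
  expect_equal(attr(rep_$means, "n_models")[["distance_directed"]], 1)
})

test_that("pairwise table has n_models rows per method pair", {
  models <- generate_ensemble(5, seed = 14, size_range = c(6, 12))
  rep_ <- benchmark_models(models, methods = c("biochemical",
                                               "distance_directed"))
  tab <- pairwise_accuracy_table(rep_)
  expect_equal(nrow(tab), 5)                    # 1 pair x 5 models
  expect_equal(unique(tab$method_a), "biochemical")

  rep3 <- benchmark_models(models, methods = c("biochemical",
                                               "distance_directed",
                                               "first_neighbor_directed"))
  tab3 <- pairwise_accuracy_table(rep3)
  expect_equal(nrow(tab3), 5 * choose(3, 2))
  # a method's scores paired with themselves correlate perfectly
  sub <- tab3[tab3$method_a == "distance_directed", ]
  expect_equal(cor(rep3$scores$distance_directed,
                   rep3$scores$distance_directed), 1)
})

test_that("heatmap export writes matching CSV and PNG deterministically", {
  S <- ground_truth_sensitivity(generate_model(generator_config(5, seed = 2)))
  dir <- withr::local_tempdir()
  f1 <- sensitivity_heatmap_export(S, file.path(dir, "a"))
  expect_true(file.exists(f1["csv"]) && file.exists(f1["png"]))
  expect_equal(unname(read_matrix_csv(f1[["csv"]])), unclass(S),
               ignore_attr = TRUE, tolerance = 1e-15)
  f2 <- sensitivity_heatmap_export(S, file.path(dir, "b.csv"))
  expect_identical(readLines(f1[["csv"]]), readLines(f2[["csv"]]))
})

test_that("network properties match closed forms on canonical graphs", {
  # directed chain: every node its own strongly connected component
  chain_m <- dynamical_model(local({
    J <- diag(-1, 5); J[cbind(2:5, 1:4)] <- 1; J
  }))
  p <- network_properties(chain_m)
  expect_equal(p$n_scc, 5)
  expect_equal(p$model_size, 5)

  # directed cycle: one SCC
  cyc <- dynamical_model(local({
    J <- diag(-1, 5); J[cbind(c(2:5, 1), 1:5)] <- 1; J
  }))
  expect_equal(network_properties(cyc)$n_scc, 1)

  # star: center's Burt constraint is 1/(n-1)
  n <- 6
  star_m <- dynamical_model(local({
    J <- diag(-1, n); J[2:n, 1] <- 1; J
  }))
  net <- build_influence_network(star_m)
  g <- netpert:::as_igraph(net, directed = FALSE)
  expect_equal(unname(igraph::constraint(g)[1]), 1 / (n - 1))

  # mean log10 |J|: computed over nonzero entries
  expect_equal(p$mean_log10_jacobian, 0)   # all entries magnitude 1
})

test_that("property-accuracy correlations are calibrated against the null", {
  models <- generate_ensemble(12, seed = 33, size_range = c(6, 20))
  rep_ <- benchmark_models(models, methods = c("distance_directed"))
  profiles <- do.call(rbind, lapply(models, network_properties))
  tab <- property_accuracy_correlation(profiles, rep_, n_random = 200,
                                       seed = 5)
  expect_true(all(c("property", "method", "rho", "random_band") %in%
                    names(tab)))
  expect_true(all(tab$random_band > 0))
  # a property equal to the accuracy vector correlates perfectly
  prof2 <- cbind(profiles, oracle_prop = rep_$scores$distance_directed)
  tab2 <- property_accuracy_correlation(prof2, rep_, n_random = 100,
                                        seed = 5)
  expect_equal(tab2$rho[tab2$property == "oracle_prop"], 1)

  # null calibration: about 68% of null correlations fall inside 1 band,
  # about 95% inside 2 bands
  acc <- rep_$scores$distance_directed
  set.seed(99)
  nulls <- replicate(400, suppressWarnings(
    cor(runif(12), acc, method = "spearman")))
  band <- tab$random_band[1]
  expect_gt(mean(abs(nulls) <= band), 0.5)
  expect_lt(mean(abs(nulls) <= band), 0.85)
  expect_gt(mean(abs(nulls) <= 2 * band), 0.9)
})

test_that("the random band shrinks roughly as 1/sqrt(n_models)", {
  band_at <- function(n, seed) {
    models <- generate_ensemble(n, seed = seed, size_range = c(5, 10))
    rep_ <- benchmark_models(models, methods = c("distance_directed"))
    profiles <- do.call(rbind, lapply(models, network_properties))
    property_accuracy_correlation(profiles, rep_, n_random = 400,
                                  seed = 3)$random_band[1]
  }
  b10 <- band_at(10, 1)
  b40 <- band_at(40, 2)
  expect_gt(b10, b40)
  expect_equal(b10 / b40, 2, tolerance = 0.35)
})
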