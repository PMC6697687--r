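#' Column-wise Spearman score of a predicted sensitivity matrix
#'
#' For each source column `j`, the off-diagonal entries of the predicted and
#' true columns are rank-transformed (midranks for ties) and their Pearson
#' correlation `rho_j = cov(rg_X, rg_Y) / (sd(rg_X) sd(rg_Y))` is computed;
#' the score is the mean of `rho_j` over all columns where it is defined.
#' The diagonal is excluded because it is fixed at 1 by convention and
#' carries no information. Columns in which either matrix is constant (or
#' contains non-finite values, e.g. a failed ground-truth solve) are skipped
#' and counted in the `n_skipped` attribute; if every column is skipped the
#' score is `NaN` with a warning.
#'
#' @param S_pred,S_true square numeric matrices of identical shape,
#'   `N >= 3`.
#' @return a single number in `[-1, 1]` with attributes `n_columns` (number
#'   of columns scored) and `n_skipped`.
#' @examples
#' S <- matrix(rnorm(25), 5, 5)
#' spearman_score(S, S)  # 1: perfect self-consistency
#' @export
spearman_score <- function(S_pred, S_true) {
  S_pred <- as.matrix(S_pred); S_true <- as.matrix(S_true)
  if (!all(dim(S_pred) == dim(S_true))) stop("shape mismatch")
  n <- nrow(S_pred)
  if (n < 3) stop("need at least 3 species for column-wise rank correlation")
  rho <- vapply(seq_len(n), function(j) {
    x <- S_pred[-j, j]
    y <- S_true[-j, j]
    if (any(!is.finite(x)) || any(!is.finite(y))) return(NA_real_)
    rx <- rank(x); ry <- rank(y)
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
    stats::cov(rx, ry) / (stats::sd(rx) * stats::sd(ry))
  }, numeric(1))
  ok <- !is.na(rho)
  if (!any(ok)) {
    warning("all columns constant or undefined; score is NaN")
    out <- NaN
  } else {
    out <- mean(rho[ok])
  }
  attr(out, "n_columns") <- sum(ok)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

# Internal: score with the DYNAMO magnitude convention (ranks of |S|),
# dropping attributes to a bare number.
score_magnitude <- function(S_pred, S_true) {
  as.numeric(spearman_score(abs(S_pred), abs(S_true)))
}

#' Benchmark topology and enhancement methods on a model corpus
#'
#' Runs each requested method on every model and scores it against the
#' biochemical ground truth with the column-wise Spearman score. Following
#' the usual evaluation convention for this family of models, scoring ranks
#' magnitudes (`|S|`), since topology predictors are nonnegative while true
#' sensitivities are signed. Models whose ground truth has failed columns
#' are scored on the remaining columns; a method failure on a model is
#' recorded as `NA` and never aborts the corpus.
#'
#' @param models list of [dynamical_model()] objects.
#' @param methods character vector among `"biochemical"`,
#'   `"first_neighbor_directed"`, `"first_neighbor_undirected"`,
#'   `"distance_directed"`, `"distance_undirected"`,
#'   `"propagation_signed_directed"`, `"propagation_directed"`,
#'   `"propagation_undirected"`, `"upper_bound_bio_impact"`,
#'   `"upper_bound_scaled_impact"`.
#' @param enhancers optional named list; each element is a list (parallel to
#'   `models`) of enhancement matrices, typically GCN predictions. Each adds
#'   a method column `distance_x_<name>` scoring
#'   `apply_enhancement(E, distance_model(...))`.
#' @param alpha restart weight for the propagation variants.
#' @param use_magnitude rank `|S|` (default `TRUE`); set `FALSE` to rank
#'   signed values.
#' @return object of class `benchmark_report`: list with `scores`
#'   (data.frame, one row per model, one column per method, plus
#'   `model_id` and `n_species`), `means` (named vector over non-NA models,
#'   with attribute `n_models` giving the per-method count).
#' @export
benchmark_models <- function(models,
                             methods = c("biochemical",
                                         "propagation_signed_directed",
                                         "propagation_directed",
                                         "propagation_undirected",
                                         "distance_directed",
                                         "distance_undirected",
                                         "first_neighbor_directed",
                                         "upper_bound_bio_impact",
                                         "upper_bound_scaled_impact"),
                             enhancers = NULL, alpha = 0.9,
                             use_magnitude = TRUE) {
  stopifnot(length(models) >= 1)
  score_fun <- if (use_magnitude) score_magnitude else
    function(a, b) as.numeric(spearman_score(a, b))
  enh_names <- if (is.null(enhancers)) character(0) else names(enhancers)
  all_methods <- c(methods,
                   if (length(enh_names)) paste0("distance_x_", enh_names))
  rows <- lapply(seq_along(models), function(k) {
    m <- models[[k]]
    truth <- ground_truth_sensitivity(m)
    net <- build_influence_network(m)
    one <- function(expr) {
      tryCatch(score_fun(expr, truth), error = function(e) NA_real_)
    }
    vals <- vapply(methods, function(meth) {
      switch(meth,
        biochemical = one(truth),
        first_neighbor_directed = one(first_neighbor_model(net, TRUE)),
        first_neighbor_undirected = one(first_neighbor_model(net, FALSE)),
        distance_directed = one(distance_model(net, TRUE)),
        distance_undirected = one(distance_model(net, FALSE)),
        propagation_signed_directed =
          one(propagation_model(net, TRUE, signed = TRUE, alpha = alpha)),
        propagation_directed =
          one(propagation_model(net, TRUE, signed = FALSE, alpha = alpha)),
        propagation_undirected =
          one(propagation_model(net, FALSE, signed = FALSE, alpha = alpha)),
        upper_bound_bio_impact = ,
        upper_bound_scaled_impact = {
          ub <- tryCatch(upper_bound_scores(m), error = function(e)
            c(bio_impact_bound = NA_real_, scaled_impact_bound = NA_real_))
          if (meth == "upper_bound_bio_impact") as.numeric(ub[1])
          else as.numeric(ub[2])
        },
        stop("unknown method: ", meth))
    }, numeric(1))
    if (length(enh_names)) {
      base <- distance_model(net, TRUE)
      ev <- vapply(enh_names, function(nm) {
        E <- enhancers[[nm]][[k]]
        if (is.null(E)) return(NA_real_)
        one(apply_enhancement(E, base))
      }, numeric(1))
      vals <- c(vals, ev)
    }
    c(n_species = n_species(m), vals)
  })
  scores <- as.data.frame(do.call(rbind, rows))
  names(scores) <- c("n_species", all_methods)
  scores <- cbind(model_id = vapply(models, `[[`, "", "model_id"), scores)
  means <- vapply(all_methods, function(mth) {
    mean(scores[[mth]], na.rm = TRUE)
  }, numeric(1))
  attr(means, "n_models") <- vapply(all_methods, function(mth) {
    sum(!is.na(scores[[mth]]))
  }, numeric(1))
  structure(list(scores = scores, means = means, methods = all_methods),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report> ", nrow(x$scores), " models\n", sep = "")
  m <- data.frame(method = names(x$means),
                  mean_score = round(unname(x$means), 3),
                  n_models = unname(attr(x$means, "n_models")))
  print(m, row.names = FALSE)
  invisible(x)
}

#' Long-form pairwise accuracy table
#'
#' Emits, for every unordered pair of methods in a benchmark report, the
#' per-model score pairs (the data behind pairwise scatter/diagonal
#' panels): `n_models * choose(n_methods, 2)` rows.
#'
#' @param report a [benchmark_models()] result with at least 2 methods.
#' @return data.frame with columns `model_id`, `method_a`, `method_b`,
#'   `score_a`, `score_b`.
#' @export
pairwise_accuracy_table <- function(report) {
  stopifnot(inherits(report, "benchmark_report"))
  meths <- report$methods
  if (length(meths) < 2) stop("need at least 2 methods")
  pairs <- utils::combn(meths, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1, p]; b <- pairs[2, p]
    data.frame(model_id = report$scores$model_id,
               method_a = a, method_b = b,
               score_a = report$scores[[a]],
               score_b = report$scores[[b]])
  }))
  rownames(out) <- NULL
  out
}

#' Export a sensitivity matrix as CSV plus heatmap
#'
#' Writes `<path>.csv` (full precision) and `<path>.png`, a heatmap with a
#' monotone dark-low/light-high colormap so stronger influence is lighter.
#'
#' @param S square numeric matrix.
#' @param path output path stem (extensions are appended; a trailing
#'   `.csv`/`.png` is stripped first).
#' @return named character vector of the two files written, invisibly.
#' @export
sensitivity_heatmap_export <- function(S, path) {
  stem <- sub("\\.(csv|png)$", "", path)
  csv <- paste0(stem, ".csv"); png <- paste0(stem, ".png")
  write_matrix_csv(as.matrix(unclass(S)), csv)
  grDevices::png(png, width = 640, height = 600)
  on.exit(grDevices::dev.off())
  m <- as.matrix(unclass(S))
  # orient so row 1 is at the top, like the printed matrix
  graphics::image(t(m)[, nrow(m):1, drop = FALSE],
                  col = grDevices::gray.colors(64, start = 0, end = 1),
                  axes = FALSE, main = attr(S, "model_id"))
  invisible(c(csv = csv, png = png))
}

#' Topological and kinetic property profile of a model
#'
#' Per-model descriptors used to relate prediction accuracy to network
#' structure: number of nodes, mean `log10 |J|` over nonzero Jacobian
#' entries, number of strongly connected components of the directed
#' influence network, mean Burt's constraint on the undirected projection
#' (low constraint = many structural holes; undefined values skipped),
#' edge density, and mean directed shortest-path length over reachable
#' pairs.
#'
#' @param model a [dynamical_model()].
#' @param network its [build_influence_network()] (recomputed if missing).
#' @return one-row data.frame with columns `model_id`, `model_size`,
#'   `mean_log10_jacobian`, `n_scc`, `mean_constraint`, `edge_density`,
#'   `mean_shortest_path`.
#' @export
network_properties <- function(model, network = NULL) {
  if (is.null(network)) network <- build_influence_network(model)
  g <- as_igraph(network, directed = TRUE)
  gu <- as_igraph(network, directed = FALSE)
  nz <- abs(model$jacobian[model$jacobian != 0])
  n <- network$n_nodes
  cons <- suppressWarnings(igraph::constraint(gu))
  cons <- cons[is.finite(cons)]
  data.frame(
    model_id = model$model_id,
    model_size = n,
    mean_log10_jacobian = if (length(nz)) mean(log10(nz)) else NA_real_,
    n_scc = igraph::components(g, mode = "strong")$no,
    mean_constraint = if (length(cons)) mean(cons) else NA_real_,
    edge_density = nrow(network$edges) / (n * (n - 1)),
    mean_shortest_path = igraph::mean_distance(g, directed = TRUE,
                                               unconnected = TRUE))
}

#' Correlate network properties with per-model prediction accuracy
#'
#' For every (property, method) pair: the Spearman correlation of the
#' property vector with the method's per-model accuracy, together with a
#' random-expectation band equal to the standard deviation of the same
#' correlation when the property is replaced by uniform random values
#' (`n_random` repetitions, fixed seed). A correlation outside the band is
#' larger than what unstructured noise typically produces.
#'
#' @param profiles data.frame of stacked [network_properties()] rows,
#'   parallel to the report's models.
#' @param report a [benchmark_models()] result.
#' @param n_random number of null repetitions (>= 100).
#' @param seed RNG seed for the null draws.
#' @return data.frame with columns `property`, `method`, `rho`,
#'   `random_band` (the +/- half-width).
#' @export
property_accuracy_correlation <- function(profiles, report,
                                          n_random = 1000, seed = 1) {
  stopifnot(inherits(report, "benchmark_report"), n_random >= 100)
  if (nrow(profiles) < 5) stop("need at least 5 models")
  props <- setdiff(names(profiles), "model_id")
  nm <- nrow(profiles)
  out <- list()
  for (meth in report$methods) {
    acc <- report$scores[[meth]]
    band <- with_local_seed(seed, {
      stats::sd(vapply(seq_len(n_random), function(r) {
        suppressWarnings(stats::cor(stats::runif(nm), acc,
                                    method = "spearman",
                                    use = "complete.obs"))
      }, numeric(1)), na.rm = TRUE)
    })
    for (p in props) {
      v <- profiles[[p]]
      rho <- if (length(unique(v[!is.na(v)])) <= 1) {
        warning("property '", p, "' is constant; correlation undefined")
        NA_real_
      } else {
        suppressWarnings(stats::cor(v, acc, method = "spearman",
                                    use = "complete.obs"))
      }
      out[[length(out) + 1]] <- data.frame(property = p, method = meth,
                                           rho = rho, random_band = band)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
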