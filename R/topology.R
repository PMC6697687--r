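#' First-neighbor sensitivity model
#'
#' The simplest topology-only predictor: a perturbation reaches only the
#' direct neighbors of the source. `S[i, j] = 1` if the edge `j -> i` exists
#' (any edge between `i` and `j` in the undirected variant), else 0;
#' diagonal 1.
#'
#' @param network an [influence_network()].
#' @param directed use edge direction (default `TRUE`); `FALSE` symmetrizes.
#' @return a [sensitivity_matrix()] with method `"first_neighbor"`.
#' @export
first_neighbor_model <- function(network, directed = TRUE) {
  stopifnot(inherits(network, "influence_network"))
  A <- abs(adjacency_matrix(network, signed = FALSE))
  if (!directed) A <- pmax(A, t(A))
  S <- (A != 0) * 1
  diag(S) <- 1
  sensitivity_matrix(S, method = "first_neighbor",
                     model_id = network$model_id, species = network$nodes)
}

#' Distance sensitivity model
#'
#' Perturbation strength falls off inversely with network distance from the
#' source: `S[i, j] = 1 / (1 + d(j -> i))` with `d` the unweighted
#' shortest-path hop count from source `j` to target `i` (following
#' influence edges). Unreachable pairs score exactly 0, which rank-based
#' evaluation treats as tied lowest; the diagonal (`d = 0`) is 1.
#'
#' @inheritParams first_neighbor_model
#' @return a [sensitivity_matrix()] with method `"distance"`.
#' @examples
#' net <- influence_network(3, data.frame(from = c(1, 2), to = c(2, 3),
#'                                        sign = 1, weight = 1))
#' distance_model(net)[, 1]  # 1, 1/2, 1/3 down the chain
#' @export
distance_model <- function(network, directed = TRUE) {
  stopifnot(inherits(network, "influence_network"))
  g <- as_igraph(network, directed = directed)
  # distances(): row = from, col = to; we need hops source j -> target i.
  d <- igraph::distances(g, mode = if (directed) "out" else "all")
  S <- 1 / (1 + t(d))          # S[i, j] keyed by source in column j
  S[is.infinite(t(d))] <- 0
  diag(S) <- 1
  sensitivity_matrix(S, method = "distance",
                     model_id = network$model_id, species = network$nodes)
}

#' Network-propagation sensitivity model
#'
#' Random-walk-with-restart propagation: each node's predicted perturbation
#' is proportional to the degree-weighted sum of its neighbors', giving the
#' closed form `S = (1 - alpha) * (I - alpha * W)^-1` with
#' `W[i, j] = A[i, j] / sqrt(d_out(j) * d_in(i))` the symmetrically
#' degree-normalized adjacency (edge `j -> i`; zero-degree nodes get
#' normalizer 1). The signed variant keeps interaction signs in `A`, so
#' inhibition propagates with negative sign. Columns are rescaled so the
#' diagonal is 1.
#'
#' @inheritParams first_neighbor_model
#' @param signed keep edge signs in the adjacency (default `FALSE`).
#' @param alpha restart weight in (0, 1); larger alpha propagates further
#'   (default 0.9).
#' @return a [sensitivity_matrix()] with method `"propagation"`.
#' @export
propagation_model <- function(network, directed = TRUE, signed = FALSE,
                              alpha = 0.9) {
  stopifnot(inherits(network, "influence_network"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  A <- adjacency_matrix(network, signed = signed)
  if (!directed) {
    M <- abs(A)
    sym <- pmax(M, t(M))
    sgn <- sign(A + t(A))
    sgn[sgn == 0] <- 1
    A <- if (signed) sym * sgn else sym
  }
  W <- normalize_walk(A)
  n <- nrow(A)
  S <- tryCatch((1 - alpha) * solve(diag(n) - alpha * W),
                error = function(e) {
    stop("(I - alpha W) is numerically singular; try a smaller alpha")
  })
  d <- diag(S)
  ok <- abs(d) > 1e-12
  S[, ok] <- sweep(S[, ok, drop = FALSE], 2, d[ok], `/`)
  diag(S) <- 1
  sensitivity_matrix(
    S, method = "propagation",
    model_id = network$model_id, species = network$nodes)
}

# Symmetric degree normalization of a (possibly signed) adjacency with
# rows = targets: each edge j -> i divided by sqrt(out-deg(j) * in-deg(i)).
normalize_walk <- function(A) {
  d_in <- rowSums(abs(A))      # edges arriving at i live in row i
  d_out <- colSums(abs(A))
  d_in[d_in == 0] <- 1
  d_out[d_out == 0] <- 1
  A / sqrt(outer(d_in, d_out))
}
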