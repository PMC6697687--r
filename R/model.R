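#' Construct a dynamical model
#'
#' A `dynamical_model` bundles the state of a biochemical reaction system at a
#' stable steady state: the species names, the steady-state concentrations and
#' the Jacobian matrix of the rate equations evaluated there. Entry
#' `jacobian[i, j]` is the partial derivative of species `i`'s rate with
#' respect to species `j` (units 1/time), so a nonzero `jacobian[i, j]` means
#' species `j` directly influences species `i`.
#'
#' @param jacobian square numeric matrix, `N x N`, finite.
#' @param steady_state numeric vector of `N` nonnegative steady-state values.
#'   Defaults to all ones.
#' @param species character vector of `N` species names. Defaults to
#'   `s1..sN` or the dimnames of `jacobian`.
#' @param rhs optional function `f(x)` returning the `N` rates at state `x`;
#'   present for generated models, absent for imported Jacobians. When given,
#'   `rhs(steady_state)` must vanish to within `1e-8` (max norm).
#' @param model_id character identifier.
#' @param check_stable if `TRUE`, require all Jacobian eigenvalues to have
#'   negative real part.
#' @return an object of class `dynamical_model` with fields `species`,
#'   `steady_state`, `jacobian`, `rhs`, `model_id`.
#' @examples
#' m <- dynamical_model(matrix(c(-1, 1, 0, -1), 2, 2))
#' m$jacobian
#' @export
dynamical_model <- function(jacobian, steady_state = NULL, species = NULL,
                            rhs = NULL, model_id = "model",
                            check_stable = FALSE) {
  jacobian <- as.matrix(jacobian)
  if (nrow(jacobian) != ncol(jacobian)) {
    stop("jacobian must be square, got ", nrow(jacobian), " x ", ncol(jacobian))
  }
  if (!is.numeric(jacobian) || any(!is.finite(jacobian))) {
    stop("jacobian must be finite numeric")
  }
  n <- nrow(jacobian)
  if (is.null(species)) {
    species <- if (!is.null(rownames(jacobian))) rownames(jacobian)
               else paste0("s", seq_len(n))
  }
  if (length(species) != n) stop("length(species) != nrow(jacobian)")
  if (is.null(steady_state)) steady_state <- rep(1, n)
  if (length(steady_state) != n) stop("length(steady_state) != nrow(jacobian)")
  if (any(!is.finite(steady_state)) || any(steady_state < 0)) {
    stop("steady_state must be finite and nonnegative")
  }
  dimnames(jacobian) <- list(species, species)
  if (!is.null(rhs)) {
    res <- max(abs(rhs(steady_state)))
    if (!is.finite(res) || res > 1e-8) {
      stop("rhs(steady_state) is not a steady state (residual ",
           format(res), ")")
    }
  }
  if (check_stable && max(Re(eigen(jacobian, only.values = TRUE)$values)) >= 0) {
    stop("jacobian is not stable (an eigenvalue has nonnegative real part)")
  }
  structure(
    list(species = as.character(species),
         steady_state = as.numeric(steady_state),
         jacobian = jacobian, rhs = rhs, model_id = model_id),
    class = "dynamical_model")
}

#' @export
print.dynamical_model <- function(x, ...) {
  nz <- sum(x$jacobian != 0 & row(x$jacobian) != col(x$jacobian))
  cat("<dynamical_model> ", x$model_id, ": ", length(x$species),
      " species, ", nz, " off-diagonal Jacobian entries",
      if (!is.null(x$rhs)) ", rhs attached" else "", "\n", sep = "")
  invisible(x)
}

n_species <- function(model) length(model$species)

#' Map a Jacobian to its influence network
#'
#' The influence network is the kinetics-free topology of a dynamical model:
#' a directed signed graph with an edge `j -> i` for every off-diagonal
#' Jacobian entry `J[i, j]` with `|J[i, j]| > threshold` (species `j` directly
#' influences species `i`). Edge sign is `sign(J[i, j])` and edge weight
#' `|J[i, j]|`. Self-loops (the diagonal) are excluded.
#'
#' @param model a [dynamical_model()].
#' @param threshold nonnegative magnitude below or at which entries are
#'   treated as zero (default 0, i.e. exact zeros only).
#' @return an object of class `influence_network`: list with `n_nodes`,
#'   `nodes` (species names), `edges` (data.frame `from`, `to`, `sign`,
#'   `weight`; `from`/`to` are 1-based node indices), `directed = TRUE`.
#' @examples
#' m <- dynamical_model(matrix(c(-1, 2, 0, -1), 2, 2))
#' build_influence_network(m)$edges
#' @export
build_influence_network <- function(model, threshold = 0) {
  stopifnot(inherits(model, "dynamical_model"))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    stop("threshold must be a single nonnegative number")
  }
  J <- model$jacobian
  off <- abs(J) > threshold & row(J) != col(J)
  idx <- which(off, arr.ind = TRUE)
  edges <- data.frame(
    from = unname(idx[, "col"]),        # source j of edge j -> i
    to = unname(idx[, "row"]),
    sign = sign(J[idx]),
    weight = abs(J[idx]))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(n_nodes = nrow(J), nodes = model$species, edges = edges,
         directed = TRUE, model_id = model$model_id),
    class = "influence_network")
}

#' Construct an influence network from an edge table
#'
#' @param n_nodes number of nodes.
#' @param edges data.frame with columns `from`, `to` (1-based indices),
#'   `sign` (+1/-1) and `weight` (> 0).
#' @param nodes node names (default `s1..sN`).
#' @param model_id identifier.
#' @return an `influence_network`.
#' @export
influence_network <- function(n_nodes, edges, nodes = NULL,
                              model_id = "network") {
  n_nodes <- as.integer(n_nodes)
  if (is.null(nodes)) nodes <- paste0("s", seq_len(n_nodes))
  stopifnot(length(nodes) == n_nodes)
  edges <- as.data.frame(edges)
  need <- c("from", "to", "sign", "weight")
  if (!all(need %in% names(edges))) {
    stop("edges must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(edges) > 0) {
    if (any(edges$from < 1 | edges$from > n_nodes |
            edges$to < 1 | edges$to > n_nodes)) stop("edge index out of range")
    if (any(edges$from == edges$to)) stop("self-loops are not allowed")
    if (any(!edges$sign %in% c(-1, 1))) stop("edge sign must be +1 or -1")
    if (any(edges$weight <= 0)) stop("edge weight must be positive")
  }
  structure(
    list(n_nodes = n_nodes, nodes = as.character(nodes),
         edges = edges[, need, drop = FALSE], directed = TRUE,
         model_id = model_id),
    class = "influence_network")
}

#' @export
print.influence_network <- function(x, ...) {
  cat("<influence_network> ", x$model_id, ": ", x$n_nodes, " nodes, ",
      nrow(x$edges), " directed signed edges\n", sep = "")
  invisible(x)
}

# Signed adjacency with A[i, j] != 0 iff edge j -> i (rows = targets).
adjacency_matrix <- function(network, signed = TRUE, weighted = FALSE) {
  A <- matrix(0, network$n_nodes, network$n_nodes,
              dimnames = list(network$nodes, network$nodes))
  e <- network$edges
  if (nrow(e) > 0) {
    v <- if (weighted) e$weight else 1
    A[cbind(e$to, e$from)] <- v * (if (signed) e$sign else 1)
  }
  A
}

# igraph view of an influence network; undirected collapses edge pairs.
as_igraph <- function(network, directed = TRUE) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = network$nodes[network$edges$from],
               to = network$nodes[network$edges$to]),
    directed = TRUE,
    vertices = data.frame(name = network$nodes))
  if (!directed) g <- igraph::as_undirected(g, mode = "collapse")
  g
}
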