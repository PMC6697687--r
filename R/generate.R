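#' Configuration for the synthetic model generator
#'
#' The generator emulates the salient statistics of curated biochemical
#' model repositories: small heterogeneous networks, sparse signed
#' Jacobians with log-normally spread interaction strengths, and a stable
#' positive steady state.
#'
#' @param n_species number of species (>= 2).
#' @param edge_density probability in (0, 1] that an off-diagonal Jacobian
#'   entry is nonzero.
#' @param sign_balance fraction of positive off-diagonal entries in [0, 1]
#'   (0.5 = activating and inhibiting interactions equally likely).
#' @param weight_scale sigma of the log-normal draw for `|J[i, j]|`
#'   (meanlog 0).
#' @param ensure_connected if `TRUE`, extra edges along a random spanning
#'   chain guarantee weak connectivity.
#' @param kind `"linear"` (rates `J %*% (x - x*)`) or `"hill"` (saturating
#'   Hill-type interactions whose Jacobian at `x*` equals the stated matrix).
#' @param margin diagonal-dominance margin: the diagonal is set to
#'   `-(rowsum of |off-diagonals| + margin)`, which forces every eigenvalue
#'   (and every principal submatrix used by the ground-truth solve) into the
#'   strict left half plane.
#' @param seed integer seed; the seed fully determines the model.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_species = 20, edge_density = 0.2,
                             sign_balance = 0.5, weight_scale = 1,
                             ensure_connected = TRUE,
                             kind = c("linear", "hill"),
                             margin = 0.1, seed = 1) {
  kind <- match.arg(kind)
  if (n_species < 2) stop("n_species must be >= 2")
  if (edge_density <= 0 || edge_density > 1) stop("edge_density must be in (0, 1]")
  if (sign_balance < 0 || sign_balance > 1) stop("sign_balance must be in [0, 1]")
  if (weight_scale < 0) stop("weight_scale must be nonnegative")
  if (margin <= 0) stop("margin must be positive")
  structure(list(n_species = as.integer(n_species),
                 edge_density = edge_density, sign_balance = sign_balance,
                 weight_scale = weight_scale,
                 ensure_connected = isTRUE(ensure_connected),
                 kind = kind, margin = margin, seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a stable synthetic dynamical model
#'
#' Off-diagonal Jacobian entries are sampled per the config; the diagonal is
#' then set by strict diagonal dominance so the steady state is stable and
#' every reduced Jacobian of the ground-truth solve is invertible. The
#' steady state is sampled log-uniform in \[0.5, 2\]. An evaluable `rhs` is
#' attached so the ODE oracle can verify the linear-response ground truth:
#' for `kind = "linear"` the rates are exactly `J %*% (x - x*)`; for
#' `kind = "hill"` each interaction passes through a Hill saturation
#' `H(x) = x^2 / (x^2 + K^2)` with `K` at the steady state, rescaled so the
#' analytic Jacobian at `x*` equals the stated matrix.
#'
#' @param config a [generator_config()].
#' @return a [dynamical_model()] with `rhs` attached.
#' @examples
#' m <- generate_model(generator_config(n_species = 5, seed = 7))
#' max(Re(eigen(m$jacobian)$values)) < 0
#' @export
generate_model <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_species
  with_local_seed(config$seed, {
    support <- matrix(stats::runif(n * n) < config$edge_density, n, n)
    diag(support) <- FALSE
    if (config$ensure_connected) {
      ord <- sample.int(n)
      for (k in seq_len(n - 1)) support[ord[k + 1], ord[k]] <- TRUE
    }
    mag <- matrix(stats::rlnorm(n * n, 0, config$weight_scale), n, n)
    sgn <- matrix(ifelse(stats::runif(n * n) < config$sign_balance, 1, -1),
                  n, n)
    J <- ifelse(support, mag * sgn, 0)
    diag(J) <- -(rowSums(abs(J)) + config$margin)
    ss <- exp(stats::runif(n, log(0.5), log(2)))
    rhs <- make_rhs(J, ss, config$kind)
    dynamical_model(J, steady_state = ss,
                    species = paste0("s", seq_len(n)), rhs = rhs,
                    model_id = sprintf("synth_n%d_seed%d", n, config$seed))
  })
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# rhs with Jacobian at ss exactly J. Hill variant: off-diagonal terms
# w_ij * (H(x_j) - 1/2) with H(x) = x^2/(x^2 + K_j^2), K_j = ss_j, so
# H(ss_j) = 1/2 and H'(ss_j) = 1/(2 ss_j); w_ij = J_ij * 2 ss_j.
make_rhs <- function(J, ss, kind) {
  if (kind == "linear") {
    force(J); force(ss)
    function(x) as.numeric(J %*% (x - ss))
  } else {
    W <- sweep(J, 2, 2 * ss, `*`)
    diag(W) <- 0
    d <- diag(J)
    K2 <- ss^2
    function(x) {
      h <- x^2 / (x^2 + K2) - 0.5
      as.numeric(W %*% h) + d * (x - ss)
    }
  }
}

#' Generate a heterogeneous ensemble of synthetic models
#'
#' Model sizes are drawn uniformly from `size_range` (default 5-60) to
#' emulate the size heterogeneity of curated repositories; per-model seeds
#' are derived deterministically from the master seed, so the same call
#' always returns the same ensemble.
#'
#' @param count number of models.
#' @param seed master seed.
#' @param size_range integer vector `c(min, max)` of species counts.
#' @param base_config a [generator_config()] providing every field except
#'   `n_species` and `seed`.
#' @return list of [dynamical_model()] objects.
#' @export
generate_ensemble <- function(count, seed = 1, size_range = c(5, 60),
                              base_config = generator_config()) {
  stopifnot(count >= 1, length(size_range) == 2,
            size_range[1] >= 2, size_range[1] <= size_range[2])
  draws <- with_local_seed(seed, list(
    sizes = sample(seq(size_range[1], size_range[2]), count, replace = TRUE),
    seeds = sample.int(.Machine$integer.max - 1L, count)))
  lapply(seq_len(count), function(k) {
    cfg <- base_config
    cfg$n_species <- draws$sizes[k]
    cfg$seed <- draws$seeds[k]
    m <- generate_model(cfg)
    m$model_id <- sprintf("synth_%03d_n%d", k, draws$sizes[k])
    m
  })
}
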