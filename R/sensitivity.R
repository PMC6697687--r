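#' Sensitivity matrix container
#'
#' A sensitivity matrix `S` holds the predicted (or true) steady-state
#' response of every species to a sustained perturbation of every other:
#' `S[i, j] = dx_i / dx_j`, the change in species `i` when species `j` is
#' displaced. Column `j` is the full response pattern to source `j`. By
#' convention the diagonal is 1 (a source responds to itself one-to-one), so
#' self-response never distorts rank comparisons.
#'
#' @param values square numeric matrix.
#' @param method character tag: one of `"biochemical"`, `"first_neighbor"`,
#'   `"distance"`, `"propagation"` or an `"enhanced_*"` tag.
#' @param model_id identifier carried from the model.
#' @param species optional species names for dimnames.
#' @return object of class `sensitivity_matrix` (a numeric matrix with
#'   attributes `method` and `model_id`).
#' @export
sensitivity_matrix <- function(values, method = "unknown",
                               model_id = "model", species = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("sensitivity matrix must be square")
  if (!is.null(species)) dimnames(values) <- list(species, species)
  structure(values, method = method, model_id = model_id,
            class = c("sensitivity_matrix", "matrix", "array"))
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat("<sensitivity_matrix> ", attr(x, "model_id"), " [",
      attr(x, "method"), "] ", nrow(x), " x ", ncol(x), "\n", sep = "")
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' Ground-truth sensitivity from the Jacobian (linear response)
#'
#' Computes the full biochemical ground truth: for each source species `j`
#' the steady state is re-solved with `x_j` clamped at a displaced value.
#' To first order the remaining species shift by the solution of
#' `J[-j, -j] %*% dx = -J[-j, j]`, the implicit-function-theorem response of
#' the steady state to the clamped coordinate. Column `j` of the result is
#' that response, with `S[j, j] = 1`.
#'
#' A column whose reduced Jacobian `J[-j, -j]` is singular cannot be solved;
#' it is filled with `NaN` and the matrix carries a `failed_columns`
#' attribute, so a downstream harness can drop the model the way curated
#' corpora lose models whose steady states are degenerate.
#'
#' @param model a [dynamical_model()]; its Jacobian should be stable.
#' @return a [sensitivity_matrix()] with method `"biochemical"` and
#'   attribute `failed_columns` (integer vector, possibly empty).
#' @examples
#' m <- dynamical_model(matrix(c(-1, 1, 0, -1), 2, 2))
#' ground_truth_sensitivity(m)  # S[2,1] = 1: the chain passes it on
#' @export
ground_truth_sensitivity <- function(model) {
  stopifnot(inherits(model, "dynamical_model"))
  J <- model$jacobian
  n <- nrow(J)
  S <- diag(1, n)
  failed <- integer(0)
  for (j in seq_len(n)) {
    if (n == 1) next
    dx <- tryCatch(solve(J[-j, -j, drop = FALSE], -J[-j, j]),
                   error = function(e) NULL)
    if (is.null(dx) || any(!is.finite(dx))) {
      S[, j] <- NaN
      S[j, j] <- 1
      failed <- c(failed, j)
    } else {
      S[-j, j] <- dx
    }
  }
  out <- sensitivity_matrix(S, method = "biochemical",
                            model_id = model$model_id,
                            species = model$species)
  attr(out, "failed_columns") <- failed
  out
}

#' Independent ODE oracle for one perturbation column
#'
#' Verifies the linear-response computation by brute force: the full ODE
#' system is integrated with the source species clamped at
#' `steady_state[source] + delta` until the state stops changing, and the
#' per-species displacement divided by `delta` is returned. For a linear
#' system this equals the corresponding column of
#' [ground_truth_sensitivity()] exactly (up to integrator tolerance); for a
#' nonlinear system it converges to it as `delta -> 0`.
#'
#' @param model a [dynamical_model()] with `rhs` present.
#' @param source 1-based index of the perturbed species.
#' @param delta absolute displacement of the source. Default
#'   `1e-4 * steady_state[source]`, floored at `1e-6`.
#' @param reltol relative change per time chunk below which the integration
#'   is declared converged (default `1e-10`).
#' @param max_time maximum integration time before giving up.
#' @return numeric vector of length `N`: `(x_new - steady_state) / delta`,
#'   with the source component equal to 1.
#' @export
ode_perturbation_oracle <- function(model, source,
                                    delta = NULL, reltol = 1e-10,
                                    max_time = 2000) {
  stopifnot(inherits(model, "dynamical_model"))
  if (is.null(model$rhs)) stop("model has no rhs; oracle needs an evaluable system")
  n <- n_species(model)
  stopifnot(source >= 1, source <= n)
  if (is.null(delta)) delta <- max(1e-4 * model$steady_state[source], 1e-6)
  x0 <- model$steady_state
  x0[source] <- x0[source] + delta
  rhs <- model$rhs
  deriv <- function(t, x, parms) {
    dx <- rhs(x)
    dx[source] <- 0          # source clamped at its displaced value
    list(dx)
  }
  chunk <- 50
  t0 <- 0
  x <- x0
  repeat {
    sol <- deSolve::lsoda(y = x, times = c(0, chunk), func = deriv,
                          parms = NULL, rtol = 1e-10, atol = 1e-12)
    x_new <- as.numeric(sol[nrow(sol), -1])
    rel <- max(abs(x_new - x) / pmax(abs(x), 1))
    t0 <- t0 + chunk
    x <- x_new
    if (rel < reltol) break
    if (t0 >= max_time) {
      stop("ode_perturbation_oracle did not converge within max_time = ",
           max_time)
    }
  }
  (x - model$steady_state) / delta
}
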