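#' Bio-impact matrix: column-wise ranks of the Jacobian
#'
#' Ranks the entries of each Jacobian column by magnitude, producing the
#' bio-impact matrix of a model. Ranks ascend with impact: the weakest entry
#' of a column has rank 1, the strongest has the column's largest rank, so a
#' model with more than 200 species produces ranks greater than 200. Exact
#' zeros all share the lowest rank (1), and ties share the smallest
#' applicable rank (competition ranking, "1-2-2-4" style). The diagonal is
#' ranked along with the rest of its column. With `signed = TRUE` the raw
#' signed values are ranked instead of magnitudes.
#'
#' @param jacobian square finite numeric matrix (a `dynamical_model`'s
#'   Jacobian, typically).
#' @param signed rank signed values instead of magnitudes (default `FALSE`).
#' @return integer matrix of per-column ranks in `1..N`.
#' @examples
#' bio_impact_matrix(matrix(c(5, 3, 0, 1, 2, 2), 3, 2))
#' @export
bio_impact_matrix <- function(jacobian, signed = FALSE) {
  jacobian <- as.matrix(jacobian)
  if (nrow(jacobian) != ncol(jacobian)) stop("jacobian must be square")
  if (any(is.na(jacobian)) || any(!is.finite(jacobian))) {
    stop("jacobian must be finite (no NaN/Inf)")
  }
  v <- if (signed) jacobian else abs(jacobian)
  apply(v, 2, function(col) {
    # competition rank, ascending: 1 + number of strictly smaller entries
    vapply(col, function(x) 1L + sum(col < x), integer(1))
  })
}

#' Scaled impact matrix: log2-ceiling compression of ranks
#'
#' Compresses the broad range of bio-impact ranks into a small label
#' alphabet suitable for classification:
#' `scaled_rank = ceiling(log2(rank)) + 1`. The logarithm is evaluated in
#' exact integer arithmetic (`ceiling(log2(r))` is the bit length of
#' `r - 1`), so powers of two never suffer floating-point boundary errors:
#' rank 1 -> 1, rank 2 -> 2, rank 4 -> 3, rank 200 -> 9.
#'
#' @param bio_impact matrix (or vector) of positive integer ranks.
#' @return integer matrix of the same shape.
#' @export
scaled_impact <- function(bio_impact) {
  r <- bio_impact
  if (any(is.na(r)) || any(r < 1) || any(r != floor(r))) {
    stop("bio_impact must contain positive integers")
  }
  out <- int_bit_length(as.integer(r) - 1L) + 1L
  if (is.matrix(bio_impact)) {
    out <- matrix(out, nrow(bio_impact), ncol(bio_impact),
                  dimnames = dimnames(bio_impact))
  }
  out
}

# bit length of nonnegative integers: 0 -> 0, 1 -> 1, 2,3 -> 2, ...
int_bit_length <- function(v) {
  out <- integer(length(v))
  repeat {
    pos <- v > 0L
    if (!any(pos)) break
    out[pos] <- out[pos] + 1L
    v <- v %/% 2L
  }
  out
}

#' Normalize a scaled impact matrix into an enhancement factor
#'
#' Divides each column by its diagonal element, so the diagonal of the
#' enhancement factor `E` is exactly 1 and every other entry expresses
#' impact relative to the source's self-impact.
#'
#' @param scaled strictly positive matrix (the scaled impact matrix).
#' @return numeric matrix `E` with unit diagonal.
#' @export
normalize_scaled <- function(scaled) {
  scaled <- as.matrix(scaled)
  d <- diag(scaled)
  if (any(d == 0)) stop("diagonal of scaled impact matrix contains zero")
  if (any(scaled <= 0)) stop("scaled impact matrix must be strictly positive")
  E <- sweep(scaled, 2, d, `/`)
  diag(E) <- 1
  E
}

#' Enhancement factor of a model
#'
#' Convenience wrapper running the three-step construction — column ranks
#' of the Jacobian, log2-ceiling scaling, diagonal normalization — and
#' returning all three matrices.
#'
#' @param model a [dynamical_model()] (or a bare Jacobian matrix).
#' @param signed rank signed values instead of magnitudes.
#' @return list of class `enhancement_factor` with fields `bio_impact`,
#'   `scaled_impact`, `normalized` (the enhancement factor `E`) and
#'   `model_id`.
#' @export
enhancement_factor <- function(model, signed = FALSE) {
  J <- if (inherits(model, "dynamical_model")) model$jacobian else as.matrix(model)
  bi <- bio_impact_matrix(J, signed = signed)
  si <- scaled_impact(bi)
  structure(list(bio_impact = bi, scaled_impact = si,
                 normalized = normalize_scaled(si),
                 model_id = if (inherits(model, "dynamical_model"))
                   model$model_id else "matrix"),
            class = "enhancement_factor")
}

#' @export
print.enhancement_factor <- function(x, ...) {
  cat("<enhancement_factor> ", x$model_id, ": ", nrow(x$normalized), " x ",
      ncol(x$normalized), ", scaled labels in ",
      min(x$scaled_impact), "..", max(x$scaled_impact), "\n", sep = "")
  invisible(x)
}

#' Apply an enhancement factor to a base sensitivity matrix
#'
#' Elementwise product `E * S` with the diagonal reset to 1. Positive
#' per-column rescalings do not change within-column rank order, so the
#' enhancement acts purely by re-weighting entries against each other.
#'
#' @param E enhancement matrix (same shape as `base`); an
#'   [enhancement_factor()] object is also accepted (its `normalized`
#'   matrix is used).
#' @param base a [sensitivity_matrix()].
#' @return a [sensitivity_matrix()] tagged `enhanced_<base method>`.
#' @export
apply_enhancement <- function(E, base) {
  if (inherits(E, "enhancement_factor")) E <- E$normalized
  E <- as.matrix(E)
  if (!all(dim(E) == dim(base))) {
    stop("shape mismatch: E is ", nrow(E), " x ", ncol(E), ", base is ",
         nrow(base), " x ", ncol(base))
  }
  S <- unclass(base) * E
  diag(S) <- 1
  sensitivity_matrix(S,
                     method = paste0("enhanced_", attr(base, "method")),
                     model_id = attr(base, "model_id"),
                     species = rownames(base))
}

#' Upper bounds of rank-based enhancement
#'
#' Scores the enhancement that perfect knowledge of the Jacobian ranks
#' would give: (1) the full bio-impact matrix used directly as the
#' enhancement weight (rank itself, diagonal-normalized, so larger impact
#' means a larger value), and (2) the normalized scaled impact matrix `E`.
#' Each is multiplied into the base topology model and scored against the
#' biochemical ground truth; these are the ceilings a learned enhancement
#' can approach.
#'
#' @param model a [dynamical_model()].
#' @param base_method `"distance"` (default) or another topology method
#'   name among `"first_neighbor"`, `"propagation"`.
#' @param directed passed to the base topology model.
#' @return named numeric vector
#'   `c(bio_impact_bound =, scaled_impact_bound =)`.
#' @export
upper_bound_scores <- function(model, base_method = "distance",
                               directed = TRUE) {
  truth <- ground_truth_sensitivity(model)
  net <- build_influence_network(model)
  base <- switch(base_method,
                 distance = distance_model(net, directed = directed),
                 first_neighbor = first_neighbor_model(net, directed = directed),
                 propagation = propagation_model(net, directed = directed),
                 stop("unknown base_method: ", base_method))
  ef <- enhancement_factor(model)
  E_raw <- sweep(ef$bio_impact, 2, diag(ef$bio_impact), `/`)
  diag(E_raw) <- 1
  c(bio_impact_bound =
      spearman_score(abs(apply_enhancement(E_raw, base)), abs(truth)),
    scaled_impact_bound =
      spearman_score(abs(apply_enhancement(ef$normalized, base)), abs(truth)))
}
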