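#' Parameters of the Gaussian registration energy
#'
#' @param sigma Gaussian aperture: the scale (on mm coordinates) of the
#'   per-point potential `1 - exp(-d^2/sigma^2)`. Default 10, the value found
#'   to be the optimal coordinate scaling for skull-surface data.
#' @param w Attribute weighting factor of the weighted 4-D distance; a very
#'   large real number so that any attribute mismatch dominates the spatial
#'   term (binary matching is its exact `w -> Inf` limit). Must be >= 1e6.
#' @param spring_k Hooke spring constant of the quadratic energy; fixed at 1.
#' @return A list of class `energy_params`.
#' @export
energy_params <- function(sigma = 10, w = 1e9, spring_k = 1) {
  stopifnot(is.numeric(sigma), length(sigma) == 1, sigma > 0)
  if (w < 1e6) abort("`w` must be a very large real number (>= 1e6)")
  if (!identical(as.double(spring_k), 1)) abort("`spring_k` is fixed at 1")
  structure(list(sigma = sigma, w = w, spring_k = 1), class = "energy_params")
}

#' Weighted 4-D distance between two attributed points
#'
#' \deqn{dist_w(p, q) = \sqrt{(\Delta x)^2 + (\Delta y)^2 + (\Delta z)^2 +
#'   w (\Delta a)^2}}
#' For equal attributes this is the Euclidean distance; for unequal attributes
#' and large `w` it is dominated by the attribute term, which is what makes
#' closest-point search reject cross-class pairs.
#'
#' @param p,q Numeric length-4 vectors `(x, y, z, a)`.
#' @param w Positive attribute weight.
#' @return Non-negative scalar.
#' @examples
#' weighted_distance(c(0, 0, 0, 1), c(3, 4, 0, 1), 1e9) # 5
#' @export
weighted_distance <- function(p, q, w) {
  stopifnot(length(p) == 4, length(q) == 4, w >= 0)
  sqrt(sum((p[1:3] - q[1:3])^2) + w * (p[4] - q[4])^2)
}

# Dense Euclidean cross-distance matrix between nx3 and mx3 coordinate sets.
cross_distance <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' Attribute-constrained closest-point correspondence
#'
#' For every moving point with a nonzero form attribute, finds the fixed point
#' of the *same* attribute class minimizing the distance (binary matching:
#' cross-class pairs are rejected outright, the exact `w -> Inf` limit of
#' [weighted_distance()]). Background points (attribute 0) do not participate.
#' Ties are broken by the lowest fixed-point index.
#'
#' @param moving,fixed `attributed_cloud` objects. Every feature class present
#'   in `moving` must also be present in `fixed`.
#' @param params An [energy_params()] object (only its `w` documents the
#'   limit; the search itself is per-class Euclidean).
#' @return A tibble of class `vfa_correspondence` with columns `moving_index`,
#'   `fixed_index` (row indices into the input clouds), `attribute`, and
#'   `distance_mm` (Euclidean, since matches are within-class), ordered by
#'   `moving_index`.
#' @export
closest_points <- function(moving, fixed, params = energy_params()) {
  mv <- attributed_points(moving)
  if (nrow(mv) == 0) abort_empty_feature("moving")
  fx <- attributed_points(fixed)
  if (nrow(fx) == 0) abort_empty_feature("fixed")
  missing <- setdiff(unique(mv$attribute), fx$attribute)
  if (length(missing) > 0) abort_missing_class(sort(missing))

  pieces <- lapply(sort(unique(mv$attribute)), function(cls) {
    mi <- mv$source_index[mv$attribute == cls]
    fi <- fx$source_index[fx$attribute == cls]
    A <- cloud_matrix(moving)[mi, , drop = FALSE]
    B <- cloud_matrix(fixed)[fi, , drop = FALSE]
    dm <- cross_distance(A, B)
    # first minimum per row -> lowest fixed index wins ties (fi is ascending)
    best <- max.col(-dm, ties.method = "first")
    tibble(
      moving_index = mi,
      fixed_index = fi[best],
      attribute = cls,
      # recompute the winning distances directly: the expanded-form matrix is
      # only accurate to ~sqrt(eps) near zero
      distance_mm = sqrt(rowSums((A - B[best, , drop = FALSE])^2))
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(pieces), .data$moving_index)
  class(out) <- c("vfa_correspondence", class(out))
  out
}

#' Brute-force closest points under the literal finite-w distance
#'
#' Exhaustively evaluates the weighted 4-D distance for all moving x fixed
#' pairs and takes the per-moving-point minimum (ties: lowest fixed index).
#' This is the independent oracle for [closest_points()]; with `w = 0` it
#' degenerates to plain Euclidean nearest neighbours ignoring attributes.
#' All moving points participate (there is no class rejection at finite `w`).
#'
#' @param moving,fixed `attributed_cloud` objects with at most 5000 points
#'   each (the search is O(M*N)).
#' @param w Non-negative attribute weight.
#' @return A tibble with columns `moving_index`, `fixed_index`, `attribute`
#'   (of the moving point) and `distance_mm` (the *weighted* distance).
#' @export
brute_force_closest <- function(moving, fixed, w = 1e9) {
  if (nrow(moving) > 5000 || nrow(fixed) > 5000) {
    abort("brute_force_closest is limited to clouds of <= 5000 points")
  }
  A <- cloud_matrix(moving)
  B <- cloud_matrix(fixed)
  d2 <- cross_distance(A, B)^2 +
    w * outer(moving$attribute, fixed$attribute, "-")^2
  best <- max.col(-d2, ties.method = "first")
  tibble(
    moving_index = seq_len(nrow(moving)),
    fixed_index = best,
    attribute = moving$attribute,
    distance_mm = sqrt(
      rowSums((A - B[best, , drop = FALSE])^2) +
        w * (moving$attribute - fixed$attribute[best])^2
    )
  )
}

# Soft (non-binary) correspondence of the Gaussian-fields baseline: all
# attributed moving points against all attributed fixed points, with the
# moderate additive attribute weight w_gf; cross-class matches are allowed but
# penalized. distance_mm is the weighted distance (it enters the energy).
gf_closest <- function(moving, fixed, w_gf) {
  mv <- attributed_points(moving)
  if (nrow(mv) == 0) abort_empty_feature("moving")
  fx <- attributed_points(fixed)
  if (nrow(fx) == 0) abort_empty_feature("fixed")
  A <- cloud_matrix(moving)[mv$source_index, , drop = FALSE]
  B <- cloud_matrix(fixed)[fx$source_index, , drop = FALSE]
  d2 <- cross_distance(A, B)^2 + w_gf * outer(mv$attribute, fx$attribute, "-")^2
  best <- max.col(-d2, ties.method = "first")
  out <- tibble(
    moving_index = mv$source_index,
    fixed_index = fx$source_index[best],
    attribute = mv$attribute,
    distance_mm = sqrt(
      rowSums((A - B[best, , drop = FALSE])^2) +
        w_gf * (mv$attribute - fx$attribute[best])^2
    )
  )
  class(out) <- c("vfa_correspondence", class(out))
  out
}
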