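#' Potential, gradient and force at every attributed moving point
#'
#' Differentiates the per-point Gaussian potential analytically with the
#' closest-point correspondence held fixed (correspondence switches are
#' measure-zero events): for a moving point `q` matched to `p*` at distance
#' `d`, \deqn{\nabla U = (2/\sigma^2)\, e^{-d^2/\sigma^2}\, (q - p^*),}
#' and the force of attraction is `F = -grad(U)`, pointing from `q` toward
#' `p*`.
#'
#' @param moving,fixed `attributed_cloud` objects (current pose of `moving`).
#' @param corr Optional correspondence for the current pose; computed with
#'   [closest_points()] when `NULL`.
#' @param params An [energy_params()] object.
#' @return A tibble with one row per attributed moving point: `moving_index`,
#'   `attribute`, `x`, `y`, `z` (moving-point position), `distance_mm`,
#'   `potential`, gradient components `gx`, `gy`, `gz` (1/mm) and force
#'   components `fx`, `fy`, `fz`.
#' @export
potential_gradient <- function(moving, fixed, corr = NULL,
                               params = energy_params()) {
  if (is.null(corr)) corr <- closest_points(moving, fixed, params)
  q <- cloud_matrix(moving)[corr$moving_index, , drop = FALSE]
  p <- cloud_matrix(fixed)[corr$fixed_index, , drop = FALSE]
  s2 <- params$sigma^2
  wgt <- (2 / s2) * exp(-corr$distance_mm^2 / s2)
  grad <- unname(q - p) * wgt
  q <- unname(q)
  tibble(
    moving_index = corr$moving_index,
    attribute = corr$attribute,
    x = q[, 1], y = q[, 2], z = q[, 3],
    distance_mm = corr$distance_mm,
    potential = gaussian_potential(corr$distance_mm, params$sigma),
    gx = grad[, 1], gy = grad[, 2], gz = grad[, 3],
    fx = -grad[, 1], fy = -grad[, 2], fz = -grad[, 3]
  )
}

#' Curl of a vector field sampled at scattered points
#'
#' Estimates the spatial Jacobian of the field at each sample by a weighted
#' least-squares affine fit over its `k_neighbors` nearest neighbours
#' (Gaussian distance weights, bandwidth = the neighbourhood radius), then
#' reads the curl off the antisymmetric part:
#' \deqn{\nabla \times F = (\partial_y F_z - \partial_z F_y,\;
#'   \partial_z F_x - \partial_x F_z,\; \partial_x F_y - \partial_y F_x).}
#' The fit is exact on affine fields sampled at non-degenerate point sets.
#' Directions in which the neighbourhood has (numerically) no spatial extent
#' cannot constrain a derivative; their contribution is truncated to zero
#' (points sampled on a surface band constrain only in-surface derivatives).
#' A neighbourhood with rank < 2 (collinear points) raises an error of class
#' `vfa_degenerate_neighborhood_error`.
#'
#' @param points n x 3 matrix (or data frame with x, y, z) of sample
#'   positions.
#' @param forces n x 3 matrix (or data frame with fx, fy, fz) of field
#'   vectors at those positions.
#' @param k_neighbors Number of nearest neighbours in each fit (>= 4).
#' @return An n x 3 matrix of curl vectors.
#' @export
curl_field <- function(points, forces, k_neighbors = 12) {
  pts <- as_xyz_matrix(points, c("x", "y", "z"))
  frc <- as_xyz_matrix(forces, c("fx", "fy", "fz"))
  n <- nrow(pts)
  stopifnot(nrow(frc) == n, k_neighbors >= 4)
  if (n < k_neighbors + 1) {
    abort(sprintf("need at least k_neighbors + 1 = %d points", k_neighbors + 1))
  }
  dm <- cross_distance(pts, pts)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    nb <- order(dm[i, ])[seq_len(k_neighbors + 1)] # includes i itself
    J <- local_jacobian(pts[nb, , drop = FALSE], frc[nb, , drop = FALSE],
                        center = pts[i, ], index = i)
    out[i, ] <- c(J[3, 2] - J[2, 3], J[1, 3] - J[3, 1], J[2, 1] - J[1, 2])
  }
  colnames(out) <- c("curl_x", "curl_y", "curl_z")
  out
}

# Weighted affine fit F ~ F0 + J (x - center); returns the 3x3 Jacobian J
# (J[a, b] = dF_a/dx_b). Truncated-SVD pseudo-inverse: singular directions
# below rel. 1e-7 of the leading one get zero derivative.
local_jacobian <- function(pts, frc, center, index) {
  d <- sweep(pts, 2, center)
  r <- sqrt(rowSums(d^2))
  h <- max(r)
  wts <- if (h > 0) exp(-(r / h)^2) else rep(1, length(r))
  sw <- sqrt(wts)
  # weighted centering absorbs the intercept
  wmean <- function(m) colSums(m * wts) / sum(wts)
  dc <- sweep(d, 2, wmean(d)) * sw
  fc <- sweep(frc, 2, wmean(frc)) * sw
  sv <- svd(dc)
  tol <- 1e-7 * max(sv$d)
  rank <- sum(sv$d > tol)
  if (rank < 2) abort_degenerate_neighborhood(index)
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  # Fc = dc J^T  =>  J^T = pinv(dc) Fc  =>  J = Fc^T U D^+ V^T
  crossprod(fc, sv$u) %*% (t(sv$v) * dinv)
}

as_xyz_matrix <- function(x, cols) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    return(unname(x))
  }
  if (is.data.frame(x)) {
    have <- intersect(cols, names(x))
    if (length(have) == 3) return(unname(as.matrix(x[, cols])))
    if (all(c("x", "y", "z") %in% names(x))) {
      return(unname(as.matrix(x[, c("x", "y", "z")])))
    }
  }
  abort("expected an n x 3 matrix or a data frame with 3-vector columns")
}

#' Full vector-field analysis of the registration force field
#'
#' Convenience wrapper: correspondence, potential, gradient, force, curl and
#' curl magnitude for every attributed moving point in one table. This is the
#' field visualized when characterizing the induced rigid motion, and the
#' input of [find_vortex()].
#'
#' @inheritParams potential_gradient
#' @param k_neighbors Neighbourhood size of the curl estimator.
#' @return A tibble of class `vfa_field`: the [potential_gradient()] columns
#'   plus `curl_x`, `curl_y`, `curl_z`, `curl_magnitude` and
#'   `force_magnitude`.
#' @export
field_samples <- function(moving, fixed, params = energy_params(),
                          corr = NULL, k_neighbors = 12) {
  pg <- potential_gradient(moving, fixed, corr, params)
  crl <- curl_field(
    as.matrix(pg[, c("x", "y", "z")]),
    as.matrix(pg[, c("fx", "fy", "fz")]),
    k_neighbors = k_neighbors
  )
  pg$curl_x <- crl[, 1]
  pg$curl_y <- crl[, 2]
  pg$curl_z <- crl[, 3]
  pg$curl_magnitude <- sqrt(rowSums(crl^2))
  pg$force_magnitude <- sqrt(pg$fx^2 + pg$fy^2 + pg$fz^2)
  class(pg) <- c("vfa_field", class(pg))
  pg
}

#' Vortex detection: the instant center of rotation
#'
#' A vortex is a point whose local curl (rotational velocity induced by the
#' force field) vanishes; under the forces of attraction the moving dataset
#' tends to rotate about it, so it is used as the rotation pivot during
#' optimization. Numerically an exact zero rarely exists, so the attributed
#' moving point with minimal curl magnitude is selected, with deterministic
#' tie-breaking by smaller force magnitude, then lower moving index.
#'
#' Selection is restricted to points where the field is active (force
#' magnitude at least `active_fraction` of the maximum): on partially
#' saturated fields both force and curl vanish exponentially at far points,
#' so an unguarded argmin would always return the most disengaged point of
#' the cloud rather than the stagnation point of the induced rotation. When
#' no point passes the guard (a fully degenerate field) all points are
#' candidates.
#'
#' @param field A `vfa_field` tibble from [field_samples()], or any data
#'   frame with columns `moving_index`, `x`, `y`, `z`, `curl_magnitude` and
#'   `force_magnitude`.
#' @param active_fraction Force-magnitude threshold, as a fraction of the
#'   maximum force in the field (default 0.01).
#' @return A one-row tibble with `moving_index`, `x`, `y`, `z`,
#'   `curl_magnitude`, `force_magnitude`.
#' @export
find_vortex <- function(field, active_fraction = 0.01) {
  stopifnot(nrow(field) >= 1)
  active <- field$force_magnitude >= active_fraction * max(field$force_magnitude)
  if (!any(active)) active <- rep(TRUE, nrow(field))
  field <- field[active, , drop = FALSE]
  pick <- order(field$curl_magnitude, field$force_magnitude, field$moving_index)[1]
  tibble(
    moving_index = field$moving_index[pick],
    x = field$x[pick], y = field$y[pick], z = field$z[pick],
    curl_magnitude = field$curl_magnitude[pick],
    force_magnitude = field$force_magnitude[pick]
  )
}
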