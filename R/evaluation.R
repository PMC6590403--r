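#' Target registration error
#'
#' The TRE at a set of corresponding target points: the Euclidean distance
#' between each fixed-space target and the registered (transformed) moving
#' target. Targets are chosen away from the registration surface, so the TRE
#' captures the clinically relevant lever-arm-amplified error.
#'
#' @param targets_fixed,targets_moving Data frames with columns `x`, `y`, `z`
#'   (and optionally `label`), equal length, row-wise corresponding.
#' @param transform The registration result's `rigid_transform`, applied to
#'   the moving targets.
#' @return A tibble of class `tre_report` with columns `label`, `x`, `y`,
#'   `z` (fixed target) and `error_mm`; [glance()] gives `min`, `mean`,
#'   `max`, `n`.
#' @export
tre <- function(targets_fixed, targets_moving, transform) {
  if (nrow(targets_fixed) != nrow(targets_moving)) {
    abort("target lists must have equal length")
  }
  tf_pts <- transform_points(
    as_xyz_matrix(targets_moving, c("x", "y", "z")), transform
  )
  fx <- as_xyz_matrix(targets_fixed, c("x", "y", "z"))
  err <- sqrt(rowSums((fx - tf_pts)^2))
  out <- tibble(
    label = if ("label" %in% names(targets_fixed)) targets_fixed$label
            else sprintf("T%02d", seq_len(nrow(targets_fixed))),
    x = fx[, 1], y = fx[, 2], z = fx[, 3],
    error_mm = err
  )
  class(out) <- c("tre_report", class(out))
  out
}

#' @export
glance.tre_report <- function(x, ...) {
  tibble(
    min = min(x$error_mm), mean = mean(x$error_mm),
    max = max(x$error_mm), n = nrow(x)
  )
}

#' Color-coded distance map of a registered pair
#'
#' Per fixed point, the nearest-neighbour distance to the registered moving
#' cloud, plus a clamped copy for color mapping (the conventional clinical
#' color scale runs green to red over the clamp range).
#'
#' @param fixed An `attributed_cloud`.
#' @param moving_registered The moving cloud after registration.
#' @param clamp_mm Length-2 clamp range, default `c(0.3, 1.5)` mm.
#' @return The fixed cloud with extra columns `distance_mm` (raw) and
#'   `distance_clamped`.
#' @export
distance_map <- function(fixed, moving_registered, clamp_mm = c(0.3, 1.5)) {
  A <- cloud_matrix(fixed)
  B <- cloud_matrix(moving_registered)
  best <- max.col(-cross_distance(A, B), ties.method = "first")
  d <- sqrt(rowSums((A - B[best, , drop = FALSE])^2))
  out <- fixed
  out$distance_mm <- d
  out$distance_clamped <- pmin(pmax(d, clamp_mm[1]), clamp_mm[2])
  out
}

#' Basin-of-convergence sweep about a principal axis
#'
#' Rotates the moving cloud about one principal axis (through its attributed
#' centroid) in fixed angular steps, runs the chosen registration method from
#' each start, and records the residual. `converged` flags runs whose
#' residual is within 10% of the best residual observed across the sweep
#' (with a 1e-6 absolute floor for the degenerate all-zero case).
#'
#' @param fixed,moving `attributed_cloud` objects (aligned `moving` = the
#'   sweep's reference pose).
#' @param config A [registration_config()] selecting the method.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param step_deg Angular step (default 5).
#' @param range_deg Half-range of the sweep (default 180).
#' @return A tibble of class `basin_sweep`: `axis`, `angle_deg`, `residual`,
#'   `optimizer_converged`, `iterations`, `converged`.
#' @export
basin_sweep <- function(fixed, moving, config = registration_config(),
                        axis = c("z", "x", "y"),
                        step_deg = 5, range_deg = 180) {
  axis <- match.arg(axis)
  angles <- seq(-range_deg, range_deg, by = step_deg)
  mv <- attributed_points(moving)
  centroid <- colMeans(cloud_matrix(moving)[mv$source_index, , drop = FALSE])
  rows <- purrr::map(angles, function(a) {
    ang <- c(x = 0, y = 0, z = 0)
    ang[axis] <- a
    displaced <- displace(
      moving, rigid_transform(unname(ang), pivot_mm = centroid)
    )
    res <- register_impl(fixed, displaced, config)
    tibble(
      axis = axis, angle_deg = a, residual = res$residual,
      optimizer_converged = res$converged, iterations = res$iterations
    )
  })
  out <- dplyr::bind_rows(rows)
  best <- min(out$residual)
  out$converged <- out$residual <= 1.1 * best + 1e-6
  class(out) <- c("basin_sweep", class(out))
  attr(out, "method") <- config$method
  out
}

#' Energy surface over a pair of rotation angles
#'
#' Evaluates the registration energy on a 2-D grid of rotations of the
#' moving cloud (about its attributed centroid; the remaining parameters are
#' zero), reproducing the convexity-inspection protocol for the domains
#' phi-theta, theta-psi and phi-psi. The grid covers `[0, 360)` degrees
#' half-open so the identity appears exactly once.
#'
#' @param fixed,moving `attributed_cloud` objects, aligned start.
#' @param pair `"phi-theta"`, `"theta-psi"` or `"phi-psi"`.
#' @param grid_deg Grid spacing in degrees (default 10).
#' @param config A [registration_config()] (supplies the matching rule and
#'   sigma).
#' @return A tibble of class `energy_surface` with columns `angle1`,
#'   `angle2` (degrees) and `energy`; attribute `"pair"` names the axes.
#' @export
energy_surface <- function(fixed, moving,
                           pair = c("phi-theta", "theta-psi", "phi-psi"),
                           grid_deg = 10,
                           config = registration_config()) {
  pair <- match.arg(pair)
  idx <- switch(pair,
    "phi-theta" = c(1L, 2L),
    "theta-psi" = c(2L, 3L),
    "phi-psi" = c(1L, 3L)
  )
  mv <- attributed_points(moving)
  pivot <- colMeans(cloud_matrix(moving)[mv$source_index, , drop = FALSE])
  angles <- seq(0, 360 - grid_deg, by = grid_deg)
  grid <- expand.grid(angle1 = angles, angle2 = angles)
  energy <- purrr::map2_dbl(grid$angle1, grid$angle2, function(a1, a2) {
    p <- c(0, 0, 0, 0, 0, 0)
    p[idx] <- c(a1, a2)
    energy_of_params(p, pivot, fixed, moving, config)
  })
  out <- tibble(angle1 = grid$angle1, angle2 = grid$angle2, energy = energy)
  class(out) <- c("energy_surface", class(out))
  attr(out, "pair") <- pair
  out
}
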