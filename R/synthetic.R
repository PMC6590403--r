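#' Configuration of the synthetic skull-like phantom
#'
#' The phantom stands in for a CT-segmented posterior-skull surface: a
#' smoothly perturbed spherical dome carrying suture-like attributed bands
#' (the arms of a "Lambda" junction) and one compact attributed blob (the
#' external occipital protuberance). The dome spans elevations
#' `[cap_min_elevation_deg, 90]` so that the whole polar scan window of
#' [scan_config()] lies on the surface. The smooth radial bump field breaks
#' all rotational symmetries; distinct attribute classes on the arms break
#' the approximate n-fold symmetry of the arm layout.
#'
#' @param n_surface_points Quasi-uniform background points on the dome.
#' @param radius_mm Base dome radius.
#' @param bump_amplitude_mm Amplitude bound of the smooth radial
#'   perturbation.
#' @param n_suture_arms Number of suture arms radiating from the Lambda
#'   junction (attribute classes `1..n_suture_arms`).
#' @param points_per_arm Attributed points per arm.
#' @param protuberance_points Points in the protuberance blob (attribute
#'   class `n_suture_arms + 1`).
#' @param arm_arc_deg Great-circle arc length of each arm. Long arms spread
#'   the features evenly about the principal axes, which the method requires.
#' @param arm_width_mm Transverse scatter of the arm bands (features are
#'   coarse outlines, not exact curves; a strict curve would make curl
#'   neighbourhoods collinear).
#' @param arm_meander_amplitude_mm Amplitude of the suture-like transverse
#'   meander of each arm. Real sutures are irregular; a meander-free
#'   great-circle arc would be mapped onto itself (reversed) by a half-turn
#'   about its circle axis, an unphysical self-symmetry that creates spurious
#'   deep registration minima.
#' @param protuberance_radius_mm Radius of the blob footprint.
#' @param lambda_elevation_deg,lambda_azimuth_deg Direction of the Lambda
#'   junction.
#' @param cap_min_elevation_deg Lower elevation limit of the background dome.
#' @param seed RNG seed; all output is bit-reproducible given the config.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(n_surface_points = 5000,
                           radius_mm = 90,
                           bump_amplitude_mm = 5,
                           n_suture_arms = 3,
                           points_per_arm = 120,
                           protuberance_points = 60,
                           arm_arc_deg = 150,
                           arm_width_mm = 2.5,
                           arm_meander_amplitude_mm = 8,
                           protuberance_radius_mm = 8,
                           lambda_elevation_deg = 55,
                           lambda_azimuth_deg = 200,
                           cap_min_elevation_deg = -65,
                           seed = 1) {
  stopifnot(
    n_surface_points >= 1, radius_mm > 0, n_suture_arms >= 1,
    points_per_arm >= 1, protuberance_points >= 1, bump_amplitude_mm >= 0
  )
  structure(as.list(environment()), class = "phantom_config")
}

unit_dir <- function(elevation_deg, azimuth_deg) {
  el <- elevation_deg * pi / 180
  az <- azimuth_deg * pi / 180
  c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
}

# Smooth seeded radial bump field on the unit sphere: a handful of
# von Mises-Fisher-shaped lobes with signed coefficients summing (in absolute
# value) to 1, scaled by the amplitude. Returns function(u_matrix) -> radius.
phantom_surface_fn <- function(cfg) {
  lobes <- withr::with_seed(cfg$seed, {
    centers <- matrix(rnorm(6 * 3), ncol = 3)
    centers <- centers / sqrt(rowSums(centers^2))
    list(
      centers = centers,
      widths = runif(6, 0.15, 0.35),
      coefs = {
        co <- runif(6, -1, 1)
        co / sum(abs(co))
      }
    )
  })
  function(u) {
    if (!is.matrix(u)) u <- matrix(u, ncol = 3)
    bump <- rep(0, nrow(u))
    for (j in seq_len(nrow(lobes$centers))) {
      bump <- bump + lobes$coefs[j] *
        exp(-(1 - u %*% lobes$centers[j, ]) / lobes$widths[j])
    }
    cfg$radius_mm + cfg$bump_amplitude_mm * as.double(bump)
  }
}

#' Generate the synthetic attributed phantom surface
#'
#' Background points are laid out on a Fibonacci spiral over the dome
#' (quasi-uniform, deterministic); suture arms are great-circle arcs from the
#' Lambda junction with seeded direction jitter and transverse scatter;
#' the protuberance is a tangent-plane Gaussian blob. All randomness is
#' driven by `cfg$seed` and leaves the caller's RNG state untouched.
#'
#' @param cfg A [phantom_config()].
#' @return An `attributed_cloud` ("phantom") with the config stored in
#'   attribute `"config"`. Attributed point count is
#'   `n_suture_arms * points_per_arm + protuberance_points`.
#' @export
make_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  surf <- phantom_surface_fn(cfg)

  # quasi-uniform dome coverage: Fibonacci spiral in z
  n <- cfg$n_surface_points
  zmin <- sin(cfg$cap_min_elevation_deg * pi / 180)
  i <- seq_len(n)
  zu <- zmin + (i - 0.5) / n * (1 - zmin)
  golden <- pi * (3 - sqrt(5))
  az <- i * golden
  ru <- sqrt(pmax(1 - zu^2, 0))
  bg_u <- cbind(ru * cos(az), ru * sin(az), zu)

  u0 <- unit_dir(cfg$lambda_elevation_deg, cfg$lambda_azimuth_deg)
  # orthonormal tangent basis at the junction
  e1 <- c(-sin(cfg$lambda_azimuth_deg * pi / 180),
          cos(cfg$lambda_azimuth_deg * pi / 180), 0)
  e2 <- pracma_cross(u0, e1)

  feat <- withr::with_seed(cfg$seed + 1L, {
    arms <- lapply(seq_len(cfg$n_suture_arms), function(k) {
      ang <- 2 * pi * (k - 1) / cfg$n_suture_arms + runif(1, -0.26, 0.26)
      w <- cos(ang) * e1 + sin(ang) * e2
      tt <- (seq_len(cfg$points_per_arm) - 0.5) / cfg$points_per_arm *
        cfg$arm_arc_deg * pi / 180
      u <- outer(cos(tt), u0) + outer(sin(tt), w)
      # transverse scatter within the surface (coarse outlining of the band)
      tang <- cbind(-sin(tt)) %*% rbind(u0) + cbind(cos(tt)) %*% rbind(w)
      perp <- t(apply(cbind(u, tang), 1, function(r) {
        pracma_cross(r[1:3], r[4:6])
      }))
      # suture-like meander (smooth, seeded phase/frequency) + band scatter
      phase <- runif(1, 0, 2 * pi)
      freq <- runif(1, 1.5, 2.5)
      meander <- cfg$arm_meander_amplitude_mm / cfg$radius_mm *
        sin(freq * tt / max(tt) * 2 * pi + phase)
      off <- meander + rnorm(cfg$points_per_arm, 0, cfg$arm_width_mm / cfg$radius_mm)
      u <- u + perp * off
      u <- u / sqrt(rowSums(u^2))
      list(u = u, attribute = k)
    })
    blob_ang <- runif(1, 0, 2 * pi)
    wp <- cos(blob_ang) * e1 + sin(blob_ang) * e2
    up <- cos(pi / 2) * u0 + sin(pi / 2) * wp # 90 deg from the junction
    b1 <- pracma_cross(up, u0); b1 <- b1 / sqrt(sum(b1^2))
    b2 <- pracma_cross(up, b1)
    sdev <- cfg$protuberance_radius_mm / 2 / cfg$radius_mm
    bu <- matrix(rep(up, each = cfg$protuberance_points), ncol = 3) +
      outer(rnorm(cfg$protuberance_points, 0, sdev), b1) +
      outer(rnorm(cfg$protuberance_points, 0, sdev), b2)
    bu <- bu / sqrt(rowSums(bu^2))
    c(arms, list(list(u = bu, attribute = cfg$n_suture_arms + 1L)))
  })

  all_u <- rbind(bg_u, do.call(rbind, lapply(feat, `[[`, "u")))
  attrs <- c(
    rep(0L, n),
    unlist(lapply(feat, function(f) rep(f$attribute, nrow(f$u))))
  )
  r <- surf(all_u)
  cloud <- attributed_cloud(
    all_u[, 1] * r, all_u[, 2] * r, all_u[, 3] * r,
    attribute = attrs, name = "phantom"
  )
  attr(cloud, "config") <- cfg
  cloud
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Labeled target points for TRE evaluation
#'
#' Generates a ring of labeled target points on the far side of the phantom
#' from the scanned/attributed pole (low elevations), mimicking clinical
#' targets on the anterior skull: far from the registration surface, so
#' registration errors are amplified by the lever arm.
#'
#' @param phantom A phantom from [make_phantom()] (its stored config supplies
#'   the surface geometry).
#' @param n_targets Number of targets.
#' @return A tibble with columns `label`, `x`, `y`, `z`.
#' @export
phantom_targets <- function(phantom, n_targets = 24) {
  cfg <- attr(phantom, "config")
  if (is.null(cfg)) abort("phantom does not carry its generator config")
  surf <- phantom_surface_fn(cfg)
  az <- seq(0, 360, length.out = n_targets + 1)[-(n_targets + 1)]
  el <- rep(c(-60, -50), length.out = n_targets)
  u <- t(mapply(unit_dir, el, az))
  r <- surf(u)
  tibble(
    label = sprintf("T%02d", seq_len(n_targets)),
    x = u[, 1] * r, y = u[, 2] * r, z = u[, 3] * r
  )
}

#' Configuration of the polar A-mode scan simulator
#'
#' Emulates a single-beam time-of-flight acquisition from the center of a
#' hemispherical positioning shell: rays on a polar grid (azimuth `phi`,
#' elevation `theta`, fixed angular resolution) measure the surface radius,
#' with Gaussian radial noise and random ray dropout.
#'
#' @param phi_range_deg Azimuth range (default `c(0, 360)`, inclusive grid).
#' @param theta_range_deg Elevation range (default `c(-60, 60)`).
#' @param resolution_deg Angular grid resolution (default 1).
#' @param center Scan origin `O` (the shell center), default the coordinate
#'   origin.
#' @param noise_sd_mm Radial Gaussian noise standard deviation (default 0.3;
#'   an assumption at the lower edge of clinically reported error, not a
#'   measured sensor property).
#' @param dropout_rate Fraction of rays discarded at random (default 0.3,
#'   matching the reported ~30% loss of correctly measured points through
#'   soft tissue).
#' @param cone_tolerance_deg A ray registers a hit when some surface point
#'   lies within this angular distance of it (default 0.75).
#' @param seed RNG seed.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(phi_range_deg = c(0, 360),
                        theta_range_deg = c(-60, 60),
                        resolution_deg = 1,
                        center = c(0, 0, 0),
                        noise_sd_mm = 0.3,
                        dropout_rate = 0.3,
                        cone_tolerance_deg = 0.75,
                        seed = 1) {
  stopifnot(
    phi_range_deg[1] < phi_range_deg[2],
    theta_range_deg[1] < theta_range_deg[2],
    resolution_deg > 0, noise_sd_mm >= 0,
    dropout_rate >= 0, dropout_rate < 1
  )
  structure(as.list(environment()), class = "scan_config")
}

#' Simulate a polar-grid A-mode scan of a surface cloud
#'
#' For each grid node a ray is cast radially from the scan center; the
#' nearest surface point within the angular tolerance cone provides the hit
#' radius (nearest-point-along-ray approximation on the point cloud) and the
#' scan point inherits its form attribute. Gaussian radial noise and ray
#' dropout are then applied. Rays without a hit are counted in attribute
#' `"n_no_hit"` of the result, not raised as errors.
#'
#' @param surface An `attributed_cloud` facing/surrounding the scan center
#'   over the scan window.
#' @param cfg A [scan_config()].
#' @return An `attributed_cloud` ("amode_scan") of Cartesian scan points with
#'   attributes `"n_rays"`, `"n_hits"`, `"n_no_hit"` recording the ray
#'   bookkeeping before dropout.
#' @export
simulate_amode_scan <- function(surface, cfg = scan_config()) {
  stopifnot(inherits(cfg, "scan_config"))
  phi <- seq(cfg$phi_range_deg[1], cfg$phi_range_deg[2], by = cfg$resolution_deg)
  theta <- seq(cfg$theta_range_deg[1], cfg$theta_range_deg[2], by = cfg$resolution_deg)
  grid <- expand.grid(phi = phi, theta = theta)
  el <- grid$theta * pi / 180
  az <- grid$phi * pi / 180
  dirs <- cbind(cos(el) * cos(az), cos(el) * sin(az), sin(el))

  rel <- sweep(cloud_matrix(surface), 2, cfg$center)
  rad <- sqrt(rowSums(rel^2))
  un <- rel / rad
  cos_tol <- cos(cfg$cone_tolerance_deg * pi / 180)

  n_rays <- nrow(dirs)
  hit_idx <- integer(n_rays)
  hit_proj <- double(n_rays)
  chunk <- 2000L
  for (s in seq(1, n_rays, by = chunk)) {
    e <- min(s + chunk - 1L, n_rays)
    ca <- tcrossprod(dirs[s:e, , drop = FALSE], un) # cos(angle) ray x point
    best <- max.col(ca, ties.method = "first")
    bc <- ca[cbind(seq_len(e - s + 1L), best)]
    ok <- bc >= cos_tol
    hit_idx[s:e] <- ifelse(ok, best, 0L)
    hit_proj[s:e] <- ifelse(ok, rad[best] * bc, NA_real_)
  }

  hits <- which(hit_idx > 0L)
  n_hits <- length(hits)
  if (n_hits == 0) abort("no ray hit the surface; check the scan window")
  out <- withr::with_seed(cfg$seed, {
    radii <- hit_proj[hits] + rnorm(n_hits, 0, cfg$noise_sd_mm)
    keep <- runif(n_hits) >= cfg$dropout_rate
    pts <- dirs[hits[keep], , drop = FALSE] * radii[keep]
    pts <- sweep(pts, 2, cfg$center, "+")
    attributed_cloud(
      pts[, 1], pts[, 2], pts[, 3],
      attribute = surface$attribute[hit_idx[hits[keep]]],
      name = "amode_scan"
    )
  })
  attr(out, "n_rays") <- n_rays
  attr(out, "n_hits") <- n_hits
  attr(out, "n_no_hit") <- n_rays - n_hits
  attr(out, "config") <- cfg
  out
}

#' Displace a cloud by a rigid transform, remembering the ground truth
#'
#' Alias of [transform_cloud()] that stores the applied transform in
#' attribute `"ground_truth"`, for parameter-recovery experiments.
#'
#' @param cloud An `attributed_cloud`.
#' @param transform A `rigid_transform`.
#' @return The displaced cloud.
#' @export
displace <- function(cloud, transform) {
  out <- transform_cloud(cloud, transform)
  attr(out, "ground_truth") <- transform
  out
}
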