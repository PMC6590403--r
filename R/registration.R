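#' Registration configuration
#'
#' Bundles every tunable of the registration drivers.
#'
#' @param method `"vfa"` (binary matching, rotation pivot at the detected
#'   instant center of rotation) or `"gf"` (Gaussian-fields baseline: soft
#'   additive attribute distance, rotation about the coordinate origin).
#' @param sigma Gaussian aperture of the energy (default 10).
#' @param w Binary-matching attribute weight (default 1e9; see
#'   [energy_params()]).
#' @param w_gf Soft attribute weight of the GF baseline; default `sigma^2`
#'   (attribute mismatches cost one aperture of distance).
#' @param k_neighbors Curl-estimator neighbourhood size (default 12).
#' @param max_iterations,gradient_tolerance,function_tolerance,armijo_constant,backtrack_shrink,max_backtracks
#'   Optimizer controls; see [quasi_newton_minimize()].
#' @param refresh_icr_every Recompute the instant center of rotation every
#'   this many accepted iterations (0 = compute once before optimization,
#'   the default).
#' @param center_initialization Start the optimizer at the translation
#'   aligning the attributed-point centroids of the two clouds (default
#'   TRUE). With `sigma` of a few mm and initial offsets of hundreds of mm
#'   the energy is numerically saturated and gradient-blind; centroid
#'   alignment is the translation half of the rotation/translation
#'   decoupling that the pivot parameterization provides for rotations.
#' @return A list of class `registration_config`.
#' @export
registration_config <- function(method = c("vfa", "gf"),
                                sigma = 10,
                                w = 1e9,
                                w_gf = NULL,
                                k_neighbors = 12,
                                max_iterations = 500,
                                gradient_tolerance = 1e-6,
                                function_tolerance = 1e-9,
                                armijo_constant = 1e-4,
                                backtrack_shrink = 0.5,
                                max_backtracks = 30,
                                refresh_icr_every = 0,
                                center_initialization = TRUE) {
  method <- match.arg(method)
  stopifnot(
    sigma > 0, max_iterations >= 1,
    gradient_tolerance > 0, function_tolerance > 0,
    armijo_constant > 0, armijo_constant < 1,
    backtrack_shrink > 0, backtrack_shrink < 1,
    refresh_icr_every >= 0
  )
  structure(list(
    method = method, sigma = sigma, w = w,
    w_gf = if (is.null(w_gf)) sigma^2 else w_gf,
    k_neighbors = k_neighbors,
    max_iterations = max_iterations,
    gradient_tolerance = gradient_tolerance,
    function_tolerance = function_tolerance,
    armijo_constant = armijo_constant,
    backtrack_shrink = backtrack_shrink,
    max_backtracks = max_backtracks,
    refresh_icr_every = refresh_icr_every,
    center_initialization = center_initialization
  ), class = "registration_config")
}

config_params <- function(config) {
  energy_params(sigma = config$sigma, w = config$w)
}

# correspondence under the configured matching rule, at the given pose
pose_correspondence <- function(moving_posed, fixed, config) {
  if (config$method == "gf") {
    gf_closest(moving_posed, fixed, config$w_gf)
  } else {
    closest_points(moving_posed, fixed, config_params(config))
  }
}

params_to_transform <- function(params6, pivot) {
  rigid_transform(
    angles_deg = params6[1:3],
    translation_mm = params6[4:6],
    pivot_mm = pivot
  )
}

#' Registration energy as a function of the six pose parameters
#'
#' Transforms `moving` by the rigid transform with Euler angles
#' `params6[1:3]` (degrees, about `pivot`) and translation `params6[4:6]`
#' (mm), recomputes the correspondence under the configured matching rule,
#' and returns the total Gaussian energy. This is the objective minimized by
#' [register_vfa()] / [register_gf()].
#'
#' @param params6 Numeric length-6: `(phi, theta, psi, tx, ty, tz)`.
#' @param pivot Length-3 rotation pivot (mm).
#' @param fixed,moving `attributed_cloud` objects.
#' @param config A [registration_config()].
#' @return Scalar energy.
#' @export
energy_of_params <- function(params6, pivot, fixed, moving,
                             config = registration_config()) {
  posed <- transform_cloud(moving, params_to_transform(params6, pivot))
  total_energy(
    pose_correspondence(posed, fixed, config),
    config_params(config)
  )
}

#' Analytic Jacobian of the registration energy
#'
#' Chain rule through the per-point analytic potential gradients with the
#' correspondence frozen at the current pose: for each attributed moving
#' point, \eqn{\partial E/\partial p = \sum_n \nabla U_n \cdot
#' \partial q_n/\partial p}, where the pose derivative of a point is the
#' identity for translations and \eqn{(\partial R/\partial angle)(q_0 - c)}
#' for angles (per degree).
#'
#' @inheritParams energy_of_params
#' @return Numeric length-6 gradient.
#' @export
jacobian_of_params <- function(params6, pivot, fixed, moving,
                               config = registration_config()) {
  tf <- params_to_transform(params6, pivot)
  posed <- transform_cloud(moving, tf)
  corr <- pose_correspondence(posed, fixed, config)
  q <- cloud_matrix(posed)[corr$moving_index, , drop = FALSE]
  p <- cloud_matrix(fixed)[corr$fixed_index, , drop = FALSE]
  s2 <- config$sigma^2
  # for GF the attribute term of the weighted distance is pose-independent,
  # so it only rescales the exponential factor
  wgt <- (2 / s2) * exp(-corr$distance_mm^2 / s2)
  V <- (q - p) * wgt # d E / d q_n, summed below against d q_n / d param
  q0c <- sweep(
    cloud_matrix(moving)[corr$moving_index, , drop = FALSE], 2, pivot
  )
  dR <- rotation_derivatives(params6[1:3])
  unname(c(
    sum(V * (q0c %*% t(dR$dphi))),
    sum(V * (q0c %*% t(dR$dtheta))),
    sum(V * (q0c %*% t(dR$dpsi))),
    colSums(V)
  ))
}

#' Rigid registration by vector field analysis
#'
#' The VFA driver: computes the attribute-constrained correspondence at the
#' initial pose, derives the force field and its curl, selects the vortex
#' (the attributed point of minimal curl magnitude) as the instant center of
#' rotation, and minimizes the Gaussian energy over the six pose parameters
#' with rotations about that pivot, using quasi-Newton descent with Armijo
#' backtracking.
#'
#' @param fixed,moving `attributed_cloud` objects sharing at least one
#'   feature class.
#' @param config A [registration_config()] (its `method` is overridden).
#' @return A `registration_result`: list with `transform` (net moving->fixed
#'   map, origin pivot), `residual` (final energy), `iterations`,
#'   `energy_trace` (tibble of accepted steps), `converged`, `pivot_used`,
#'   `method`, `config`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
register_vfa <- function(fixed, moving, config = registration_config("vfa")) {
  config$method <- "vfa"
  register_impl(fixed, moving, config)
}

#' Rigid registration with the Gaussian-fields baseline
#'
#' Same optimizer and energy shape as [register_vfa()], but matching is soft
#' (weighted 4-D distance over all attributed point pairs, moderate attribute
#' weight `w_gf`) and rotations are parameterized about the coordinate
#' origin. Provided as the comparison baseline; its basin of convergence is
#' substantially narrower.
#'
#' @inheritParams register_vfa
#' @return A `registration_result`; see [register_vfa()].
#' @export
register_gf <- function(fixed, moving, config = registration_config("gf")) {
  config$method <- "gf"
  register_impl(fixed, moving, config)
}

#' Dispatch registration by configured method
#'
#' @inheritParams register_vfa
#' @export
register_clouds <- function(fixed, moving, config = registration_config()) {
  register_impl(fixed, moving, config)
}

register_impl <- function(fixed, moving, config) {
  mv <- attributed_points(moving)
  if (nrow(mv) == 0) abort_empty_feature("moving")
  fx <- attributed_points(fixed)
  if (nrow(fx) == 0) abort_empty_feature("fixed")

  t0 <- c(0, 0, 0)
  if (isTRUE(config$center_initialization)) {
    t0 <- colMeans(cloud_matrix(fixed)[fx$source_index, , drop = FALSE]) -
      colMeans(cloud_matrix(moving)[mv$source_index, , drop = FALSE])
  }

  pivot_at <- function(tf) {
    if (config$method == "gf") return(c(0, 0, 0))
    posed <- transform_cloud(moving, tf)
    fld <- field_samples(
      posed, fixed, config_params(config),
      k_neighbors = config$k_neighbors
    )
    vx <- find_vortex(fld)
    c(vx$x, vx$y, vx$z)
  }

  x <- c(0, 0, 0, t0)
  pivot <- pivot_at(params_to_transform(x, c(0, 0, 0)))
  ctl <- config[c(
    "max_iterations", "gradient_tolerance", "function_tolerance",
    "armijo_constant", "backtrack_shrink", "max_backtracks"
  )]
  if (config$method == "vfa") {
    # Stepping-out proposals for the widened line search: the ICR
    # parameterization decouples rotation from translation, so at stall we
    # probe large single- and double-axis rotation offsets with the
    # translation re-solved by aligning the attributed centroids under the
    # probed rotation. Probes are only accepted when they strictly lower the
    # energy.
    mu_f <- colMeans(cloud_matrix(fixed)[fx$source_index, , drop = FALSE])
    mu_m <- colMeans(cloud_matrix(moving)[mv$source_index, , drop = FALSE])
    recenter <- function(ang, pivot) {
      R <- rotation_matrix(ang)
      as.double(mu_f - (R %*% (mu_m - pivot) + pivot))
    }
    rot_net <- as.matrix(expand.grid(
      phi = seq(0, 330, by = 30), theta = seq(0, 330, by = 30),
      psi = seq(0, 330, by = 30)
    ))
    make_candidates <- function(pivot) {
      force(pivot)
      function(x) {
        cands <- list(c(x[1:3], recenter(x[1:3], pivot)))
        # relative offsets: refine a near-miss orientation cheaply
        for (i in 1:3) {
          for (delta in c(seq(-150, -30, by = 30), seq(30, 180, by = 30))) {
            ang <- x[1:3]
            ang[i] <- ang[i] + delta
            cands[[length(cands) + 1L]] <- c(ang, recenter(ang, pivot))
          }
        }
        for (pr in list(c(1L, 2L), c(1L, 3L), c(2L, 3L))) {
          ang <- x[1:3]
          ang[pr] <- ang[pr] + 180
          cands[[length(cands) + 1L]] <- c(ang, recenter(ang, pivot))
        }
        # absolute coarse net over the rotation group: guarantees a probe
        # within ~half the net spacing of any orientation
        for (r in seq_len(nrow(rot_net))) {
          ang <- rot_net[r, ]
          cands[[length(cands) + 1L]] <- c(ang, recenter(ang, pivot))
        }
        cands
      }
    }
  }

  ectx <- make_energy_context(fixed, moving, config)
  run_segment <- function(x0, pivot, budget) {
    seg_ctl <- ctl
    seg_ctl$max_iterations <- budget
    if (config$method == "vfa") seg_ctl$stall_candidates <- make_candidates(pivot)
    quasi_newton_minimize(
      function(p) ectx$energy(p, pivot),
      function(p) ectx$jacobian(p, pivot),
      x0, seg_ctl
    )
  }

  if (config$method == "vfa" && config$refresh_icr_every > 0) {
    remaining <- config$max_iterations
    traces <- list()
    iters <- 0L
    repeat {
      budget <- min(config$refresh_icr_every, remaining)
      fit <- run_segment(x, pivot, budget)
      seg <- fit$trace
      seg$iteration <- seg$iteration + iters
      traces[[length(traces) + 1L]] <- seg
      iters <- iters + fit$iterations
      remaining <- remaining - fit$iterations
      if ((fit$converged && fit$iterations < budget) || remaining <= 0) {
        fit$iterations <- iters
        fit$converged <- fit$converged && remaining > 0
        break
      }
      # carry the pose over to a freshly detected pivot: same rotation,
      # translation adjusted so the net mapping is unchanged
      new_pivot <- pivot_at(params_to_transform(fit$x, pivot))
      R <- rotation_matrix(fit$x[1:3])
      t_new <- fit$x[4:6] + (pivot - R %*% pivot) - (new_pivot - R %*% new_pivot)
      x <- c(fit$x[1:3], as.double(t_new))
      pivot <- new_pivot
    }
    trace <- dplyr::bind_rows(traces)
    fit$trace <- trace
  } else {
    fit <- run_segment(x, pivot, config$max_iterations)
  }

  net <- as_origin_pivot(params_to_transform(fit$x, pivot))
  structure(list(
    transform = net,
    residual = fit$value,
    iterations = fit$iterations,
    energy_trace = fit$trace,
    converged = fit$converged,
    evaluations = fit$evaluations,
    pivot_used = pivot,
    method = config$method,
    config = config
  ), class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "<registration_result: %s> residual %.6g after %d iterations (%s)\n",
    toupper(x$method), x$residual, x$iterations,
    if (x$converged) "converged" else "max iterations reached"
  ))
  cat(sprintf(
    "  pivot used (mm): [%s]\n",
    paste(signif(x$pivot_used, 6), collapse = ", ")
  ))
  print(x$transform)
  invisible(x)
}

#' @export
tidy.registration_result <- function(x, ...) {
  tf <- x$transform
  tibble(
    term = c("phi_deg", "theta_deg", "psi_deg", "tx_mm", "ty_mm", "tz_mm"),
    estimate = c(tf$angles_deg, tf$translation_mm)
  )
}

#' @export
glance.registration_result <- function(x, ...) {
  tibble(
    method = x$method,
    residual = x$residual,
    iterations = x$iterations,
    evaluations = x$evaluations,
    converged = x$converged,
    sigma = x$config$sigma
  )
}
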