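#' @export
autoplot.registration_result <- function(object, ...) {
  ggplot2::ggplot(object$energy_trace, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_step(color = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "accepted quasi-Newton step",
      y = expression(E[sigma]),
      title = sprintf("%s registration: energy trace", toupper(object$method)),
      subtitle = sprintf(
        "residual %.4g after %d iterations", object$residual, object$iterations
      )
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.energy_surface <- function(object, ...) {
  pair <- strsplit(attr(object, "pair"), "-")[[1]]
  ggplot2::ggplot(object, ggplot2::aes(.data$angle1, .data$angle2, fill = .data$energy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = sprintf("%s (deg)", pair[1]), y = sprintf("%s (deg)", pair[2]),
      fill = expression(E[sigma]),
      title = sprintf("Energy surface: %s", attr(object, "pair"))
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.basin_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$angle_deg, .data$residual)) +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(color = .data$converged)) +
    ggplot2::labs(
      x = sprintf("initial rotation about %s (deg)", object$axis[1]),
      y = "residual energy",
      color = "reached global minimum",
      title = sprintf("Basin of convergence (%s)", toupper(attr(object, "method")))
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.vfa_field <- function(object, scale = 20, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_segment(
      ggplot2::aes(
        xend = .data$x + scale * .data$fx, yend = .data$y + scale * .data$fy,
        color = .data$curl_magnitude
      ),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm"))
    ) +
    ggplot2::scale_color_gradient(low = "forestgreen", high = "red") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "x (mm)", y = "y (mm)", color = "|curl|",
      title = "Force field (x-y projection)"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tre_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$label, .data$error_mm)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$error_mm)) +
    ggplot2::scale_fill_gradient(low = "forestgreen", high = "red",
                                 limits = c(0.3, 1.5), oob = scales_squish) +
    ggplot2::labs(x = NULL, y = "TRE (mm)", fill = "TRE (mm)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

# clamp out-of-bounds values into the fill limits (avoids a scales dependency
# in Imports; identical to scales::squish)
scales_squish <- function(x, range = c(0, 1), only.finite = TRUE) {
  force(range)
  finite <- if (only.finite) is.finite(x) else TRUE
  x[finite & x < range[1]] <- range[1]
  x[finite & x > range[2]] <- range[2]
  x
}
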