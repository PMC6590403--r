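#' Rigid transforms with an explicit rotation pivot
#'
#' A rigid transform is parameterized by three Euler angles (degrees) about the
#' fixed x, y, z axes, a translation vector (mm), and a pivot point (mm) about
#' which the rotation is applied. The rotation matrix is composed extrinsically
#' as \eqn{R = R_z(\psi) R_y(\theta) R_x(\phi)}. A point `p` maps to
#' \deqn{p' = R (p - c) + c + t}
#' where `c` is the pivot and `t` the translation. The pivot is a
#' parameterization convenience only: any pivoted transform has an equivalent
#' origin-pivot form with `t' = t + c - R c` (see [as_origin_pivot()]).
#'
#' @param angles_deg Numeric length-3: rotations (phi, theta, psi) in degrees
#'   about the x, y and z axes.
#' @param translation_mm Numeric length-3 translation (mm).
#' @param pivot_mm Numeric length-3 rotation pivot (mm). Default origin.
#' @return An object of class `rigid_transform`.
#' @examples
#' tf <- rigid_transform(c(180, 0, 0))
#' transform_cloud(attributed_cloud(1, 2, 3), tf) # (1, -2, -3)
#' @export
rigid_transform <- function(angles_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0),
                            pivot_mm = c(0, 0, 0)) {
  stopifnot(
    length(angles_deg) == 3, length(translation_mm) == 3, length(pivot_mm) == 3,
    all(is.finite(angles_deg)), all(is.finite(translation_mm)), all(is.finite(pivot_mm))
  )
  structure(
    list(
      angles_deg = as.double(angles_deg),
      translation_mm = as.double(translation_mm),
      pivot_mm = as.double(pivot_mm),
      rotation = rotation_matrix(angles_deg)
    ),
    class = "rigid_transform"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> angles (deg): [%s]  t (mm): [%s]  pivot (mm): [%s]\n",
    paste(signif(x$angles_deg, 6), collapse = ", "),
    paste(signif(x$translation_mm, 6), collapse = ", "),
    paste(signif(x$pivot_mm, 6), collapse = ", ")
  ))
  invisible(x)
}

rot_x <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c_, s, 0, -s, c_), 3, 3)
}
rot_y <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(c_, 0, -s, 0, 1, 0, s, 0, c_), 3, 3)
}
rot_z <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3, 3)
}

#' Rotation matrix from extrinsic x-y-z Euler angles
#'
#' @param angles_deg Length-3 numeric, rotations about x, y, z in degrees.
#' @return 3x3 orthonormal matrix with determinant +1,
#'   `R = Rz(psi) %*% Ry(theta) %*% Rx(phi)`.
#' @export
rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  rot_z(a[3]) %*% rot_y(a[2]) %*% rot_x(a[1])
}

# Derivatives of the rotation matrix w.r.t. each angle, in 1/degree.
rotation_derivatives <- function(angles_deg) {
  a <- angles_deg * pi / 180
  d_rot_x <- function(t) {
    c_ <- cos(t); s <- sin(t)
    matrix(c(0, 0, 0, 0, -s, c_, 0, -c_, -s), 3, 3)
  }
  d_rot_y <- function(t) {
    c_ <- cos(t); s <- sin(t)
    matrix(c(-s, 0, -c_, 0, 0, 0, c_, 0, -s), 3, 3)
  }
  d_rot_z <- function(t) {
    c_ <- cos(t); s <- sin(t)
    matrix(c(-s, c_, 0, -c_, -s, 0, 0, 0, 0), 3, 3)
  }
  scale <- pi / 180
  list(
    dphi   = (rot_z(a[3]) %*% rot_y(a[2]) %*% d_rot_x(a[1])) * scale,
    dtheta = (rot_z(a[3]) %*% d_rot_y(a[2]) %*% rot_x(a[1])) * scale,
    dpsi   = (d_rot_z(a[3]) %*% rot_y(a[2]) %*% rot_x(a[1])) * scale
  )
}

# Apply a rigid transform to an nx3 coordinate matrix.
transform_points <- function(xyz, transform) {
  R <- transform$rotation
  c_ <- transform$pivot_mm
  t_ <- transform$translation_mm
  shifted <- sweep(xyz, 2, c_)
  out <- shifted %*% t(R)
  sweep(out, 2, c_ + t_, "+")
}

#' Apply a rigid transform to a point cloud
#'
#' Transforms coordinates; attributes (and any extra columns) are unchanged.
#'
#' @param cloud An `attributed_cloud` (or any data frame with x, y, z).
#' @param transform A `rigid_transform`.
#' @return A cloud of the same shape with transformed coordinates.
#' @export
transform_cloud <- function(cloud, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  set_cloud_matrix(cloud, transform_points(cloud_matrix(cloud), transform))
}

#' Invert a rigid transform
#'
#' Returns a transform `Tinv` with `Tinv(T(p)) = p` for all points. The
#' inverse is expressed with pivot at the origin; angles are not decomposed
#' (the rotation matrix of the inverse is `t(R)`), so the stored `angles_deg`
#' of the inverse are `NA` and only its matrix form is meaningful.
#'
#' @param transform A `rigid_transform`.
#' @return A `rigid_transform` representing the inverse mapping.
#' @export
invert_transform <- function(transform) {
  # net origin-pivot form: p' = R p + b  with  b = t + c - R c
  R <- transform$rotation
  b <- net_offset(transform)
  new_matrix_transform(t(R), -t(R) %*% b)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(first, second)` returns the transform applying `first`
#' then `second`.
#'
#' @param first,second `rigid_transform` objects.
#' @return A `rigid_transform` (origin pivot, matrix form).
#' @export
compose_transforms <- function(first, second) {
  R1 <- first$rotation; b1 <- net_offset(first)
  R2 <- second$rotation; b2 <- net_offset(second)
  new_matrix_transform(R2 %*% R1, R2 %*% b1 + b2)
}

# translation of the equivalent origin-pivot form
net_offset <- function(transform) {
  c_ <- transform$pivot_mm
  as.double(transform$translation_mm + c_ - transform$rotation %*% c_)
}

# Build a rigid_transform directly from (R, b); used for inverses/compositions
# where no Euler decomposition is needed (transforms are always built from
# parameters, never decomposed, so angles are carried as NA here).
new_matrix_transform <- function(R, b) {
  structure(
    list(
      angles_deg = c(NA_real_, NA_real_, NA_real_),
      translation_mm = as.double(b),
      pivot_mm = c(0, 0, 0),
      rotation = R
    ),
    class = "rigid_transform"
  )
}

#' Re-express a transform with pivot at the origin
#'
#' The returned transform acts identically on every point but stores
#' `pivot_mm = c(0,0,0)` and `translation_mm = t + c - R c`.
#'
#' @param transform A `rigid_transform`.
#' @return A `rigid_transform` with origin pivot.
#' @export
as_origin_pivot <- function(transform) {
  out <- transform
  out$translation_mm <- net_offset(transform)
  out$pivot_mm <- c(0, 0, 0)
  out
}

#' Discrepancy between two rigid transforms
#'
#' Measures how far two transforms are from describing the same point mapping:
#' the relative rotation angle (degrees) and the translation difference (mm)
#' of their net origin-pivot forms. Used to verify transform recovery.
#'
#' @param a,b `rigid_transform` objects.
#' @return A list with `angle_deg` and `translation_mm` (non-negative scalars).
#' @export
transform_discrepancy <- function(a, b) {
  Rrel <- t(a$rotation) %*% b$rotation
  ctheta <- (sum(diag(Rrel)) - 1) / 2
  angle <- acos(pmin(1, pmax(-1, ctheta))) * 180 / pi
  dt <- sqrt(sum((net_offset(a) - net_offset(b))^2))
  list(angle_deg = angle, translation_mm = dt)
}

#' Read / write a rigid transform as JSON
#'
#' The JSON schema is
#' `{"angles_deg": [phi, theta, psi], "axis_order": "xyz-extrinsic",
#'   "translation_mm": [x, y, z], "pivot_mm": [x, y, z]}`.
#'
#' @param path File path.
#' @return `read_transform_json` returns a `rigid_transform`;
#'   `write_transform_json` returns `path` invisibly.
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (fld in c("angles_deg", "translation_mm")) {
    if (is.null(obj[[fld]])) abort_parse(path, paste0("missing field '", fld, "'"))
  }
  if (!is.null(obj$axis_order) && !identical(obj$axis_order, "xyz-extrinsic")) {
    abort_parse(path, paste0("unsupported axis_order '", obj$axis_order, "'"))
  }
  rigid_transform(
    angles_deg = obj$angles_deg,
    translation_mm = obj$translation_mm,
    pivot_mm = if (is.null(obj$pivot_mm)) c(0, 0, 0) else obj$pivot_mm
  )
}

#' @param transform A `rigid_transform` to serialize.
#' @rdname read_transform_json
#' @export
write_transform_json <- function(transform, path) {
  obj <- list(
    angles_deg = transform$angles_deg,
    axis_order = "xyz-extrinsic",
    translation_mm = transform$translation_mm,
    pivot_mm = transform$pivot_mm
  )
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Random rigid transform (for experiments)
#'
#' Draws Euler angles uniformly over `[0, 360)` degrees per axis and
#' translation components uniformly over `[-max_translation_mm,
#' +max_translation_mm]`. Uses the current RNG state; seed externally.
#'
#' @param max_translation_mm Half-width of the uniform translation range.
#' @param pivot_mm Rotation pivot of the generated transform.
#' @return A `rigid_transform`.
#' @export
random_transform <- function(max_translation_mm = 200, pivot_mm = c(0, 0, 0)) {
  rigid_transform(
    angles_deg = runif(3, 0, 360),
    translation_mm = runif(3, -max_translation_mm, max_translation_mm),
    pivot_mm = pivot_mm
  )
}
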