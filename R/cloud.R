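#' Attributed 3-D point clouds
#'
#' An attributed point cloud is the central data container of vfareg: a tibble
#' with one row per point and columns `x`, `y`, `z` (Cartesian coordinates in
#' mm, right-handed frame) and `attribute` (a non-negative integer "form
#' attribute"). Nonzero attributes mark points belonging to named anatomical
#' features (e.g. the individual sutures of the Lambda fissure, or the external
#' occipital protuberance); attribute 0 marks unlabelled background surface.
#' Only points with nonzero attributes take part in matching and registration;
#' background points are carried along for visualization and error mapping.
#'
#' @param x,y,z Numeric coordinate vectors of equal length (mm).
#' @param attribute Integer vector of non-negative form attributes (recycled if
#'   length 1). Default 0 (background).
#' @param name Optional free-text label for the cloud.
#' @return A tibble of class `attributed_cloud` with columns
#'   `x`, `y`, `z`, `attribute`.
#' @examples
#' attributed_cloud(c(0, 5), c(0, 0), c(0, 0), attribute = c(1L, 2L))
#' @export
attributed_cloud <- function(x, y, z, attribute = 0L, name = NULL) {
  df <- tibble(
    x = as.double(x), y = as.double(y), z = as.double(z),
    attribute = as.integer(rep_len(attribute, length(x)))
  )
  as_attributed_cloud(df, name = name)
}

#' Coerce a data frame to an attributed point cloud
#'
#' Validates the `attributed_cloud` invariants: columns `x`, `y`, `z`,
#' `attribute` present; at least one point; all coordinates finite; all
#' attributes non-negative integers.
#'
#' @param df A data frame with columns `x`, `y`, `z` and (optionally)
#'   `attribute`; a missing attribute column is filled with zeros.
#' @param name Optional label stored as an attribute on the object.
#' @return A tibble of class `attributed_cloud`.
#' @export
as_attributed_cloud <- function(df, name = NULL) {
  if (!is.data.frame(df)) abort("`df` must be a data frame")
  missing_xyz <- setdiff(c("x", "y", "z"), names(df))
  if (length(missing_xyz) > 0) {
    abort(paste0("missing coordinate column(s): ", paste(missing_xyz, collapse = ", ")))
  }
  if (!"attribute" %in% names(df)) df$attribute <- 0L
  out <- as_tibble(df)[, c("x", "y", "z", "attribute")]
  out$x <- as.double(out$x)
  out$y <- as.double(out$y)
  out$z <- as.double(out$z)
  out$attribute <- as.integer(out$attribute)
  class(out) <- c("attributed_cloud", class(tibble()))
  if (!is.null(name)) attr(out, "cloud_name") <- name
  validate_attributed_cloud(out)
}

validate_attributed_cloud <- function(cloud) {
  if (nrow(cloud) < 1) abort("an attributed cloud must contain at least one point")
  xyz <- cloud_matrix(cloud)
  if (!all(is.finite(xyz))) abort("all coordinates must be finite")
  if (anyNA(cloud$attribute) || any(cloud$attribute < 0)) {
    abort("all form attributes must be non-negative integers")
  }
  cloud
}

#' @export
print.attributed_cloud <- function(x, ...) {
  nm <- attr(x, "cloud_name")
  cls <- feature_classes(x)
  cat(sprintf(
    "<attributed_cloud%s> %d points, %d attributed (%s)\n",
    if (is.null(nm)) "" else paste0(" '", nm, "'"),
    nrow(x), sum(x$attribute > 0L),
    if (length(cls) == 0) "no feature classes"
    else paste0("classes ", paste(cls, collapse = ", "))
  ))
  NextMethod()
}

#' Feature classes of a cloud
#'
#' The sorted set of distinct nonzero attribute values. A cloud with no
#' feature classes cannot drive registration.
#'
#' @param cloud An `attributed_cloud`.
#' @return Sorted integer vector (possibly empty).
#' @export
feature_classes <- function(cloud) {
  sort(unique(cloud$attribute[cloud$attribute > 0L]))
}

#' Subset of points carrying a nonzero form attribute
#'
#' @param cloud An `attributed_cloud`.
#' @return An `attributed_cloud` restricted to attributed points, with a
#'   `source_index` column giving each point's row index in `cloud`.
#' @export
attributed_points <- function(cloud) {
  idx <- which(cloud$attribute > 0L)
  out <- cloud[idx, , drop = FALSE]
  out$source_index <- idx
  out
}

# nx3 coordinate matrix (internal workhorse)
cloud_matrix <- function(cloud) {
  cbind(x = cloud$x, y = cloud$y, z = cloud$z)
}

# Replace coordinates, keep attributes and metadata
set_cloud_matrix <- function(cloud, xyz) {
  cloud$x <- xyz[, 1]
  cloud$y <- xyz[, 2]
  cloud$z <- xyz[, 3]
  cloud
}
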