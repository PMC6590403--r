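#' Read an attributed point cloud from PLY or CSV
#'
#' PLY files are expected in ASCII format with vertex properties `x`, `y`,
#' `z` and (optionally) an integer property `attribute`; when the attribute
#' property is absent all points get attribute 0 and a warning of class
#' `vfa_missing_attribute_warning` is issued. CSV files need columns
#' `x,y,z,attribute`. Coordinates are interpreted as mm.
#'
#' @param path File path.
#' @param format `"auto"` (from the extension), `"ply"` or `"csv"`.
#' @return An `attributed_cloud`.
#' @export
read_cloud <- function(path, format = c("auto", "ply", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      ply = "ply", csv = "csv",
      abort_parse(path, "cannot infer format from extension; pass `format`")
    )
  }
  if (!file.exists(path)) abort_parse(path, "file does not exist")
  if (format == "csv") read_cloud_csv(path) else read_cloud_ply(path)
}

read_cloud_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("x", "y", "z") %in% names(df))) {
    abort_parse(path, "CSV must have columns x, y, z[, attribute]")
  }
  if (!"attribute" %in% names(df)) {
    warn_missing_attribute(path)
    df$attribute <- 0L
  }
  as_attributed_cloud(df, name = basename(path))
}

read_cloud_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "ply") {
    abort_parse(path, "not a PLY file (missing 'ply' magic)")
  }
  end <- match("end_header", trimws(lines))
  if (is.na(end)) abort_parse(path, "no end_header line")
  header <- trimws(lines[seq_len(end)])
  if (!any(grepl("^format\\s+ascii", header))) {
    abort_parse(path, "only ascii PLY is supported")
  }
  # collect the property names of the vertex element, in order
  props <- character(0)
  n_vertex <- NA_integer_
  in_vertex <- FALSE
  for (h in header) {
    tok <- strsplit(h, "\\s+")[[1]]
    if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (in_vertex) n_vertex <- as.integer(tok[3])
    } else if (tok[1] == "property" && in_vertex) {
      props <- c(props, tok[length(tok)])
    }
  }
  if (is.na(n_vertex)) abort_parse(path, "no vertex element in header")
  if (!all(c("x", "y", "z") %in% props)) {
    abort_parse(path, "vertex element lacks x/y/z properties")
  }
  body <- lines[(end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n_vertex) {
    abort_parse(path, sprintf(
      "expected %d vertex rows, found %d", n_vertex, length(body)
    ))
  }
  vals <- scan(
    text = paste(body[seq_len(n_vertex)], collapse = "\n"),
    what = double(), quiet = TRUE
  )
  if (length(vals) != n_vertex * length(props)) {
    abort_parse(path, "vertex row width does not match declared properties")
  }
  m <- matrix(vals, ncol = length(props), byrow = TRUE,
              dimnames = list(NULL, props))
  df <- tibble(x = m[, "x"], y = m[, "y"], z = m[, "z"])
  if ("attribute" %in% props) {
    df$attribute <- as.integer(m[, "attribute"])
  } else {
    warn_missing_attribute(path)
    df$attribute <- 0L
  }
  as_attributed_cloud(df, name = basename(path))
}

#' Write an attributed point cloud to PLY or CSV
#'
#' Output is deterministic: identical clouds produce byte-identical files.
#'
#' @param cloud An `attributed_cloud`.
#' @param path Output path.
#' @param format `"auto"`, `"ply"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, format = c("auto", "ply", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      ply = "ply", csv = "csv",
      abort_parse(path, "cannot infer format from extension; pass `format`")
    )
  }
  if (format == "csv") {
    readr::write_csv(cloud[, c("x", "y", "z", "attribute")], path,
                     progress = FALSE)
  } else {
    write_ply(
      cbind(cloud_matrix(cloud), attribute = cloud$attribute), path,
      int_props = "attribute"
    )
  }
  invisible(path)
}

# Minimal deterministic ASCII PLY writer; columns of `m` become vertex
# properties (those named in int_props as int, the rest as float).
write_ply <- function(m, path, int_props = character(0)) {
  props <- colnames(m)
  decl <- vapply(props, function(p) {
    sprintf("property %s %s", if (p %in% int_props) "int" else "float", p)
  }, character(1))
  header <- c(
    "ply", "format ascii 1.0",
    "comment produced by vfareg",
    sprintf("element vertex %d", nrow(m)),
    decl,
    "end_header"
  )
  fmt_cell <- function(v, p) {
    if (p %in% int_props) sprintf("%d", as.integer(v)) else sprintf("%.9g", v)
  }
  cols <- lapply(props, function(p) fmt_cell(m[, p], p))
  rows <- do.call(paste, cols)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Export a vector-field analysis as PLY
#'
#' Writes the attributed moving points with per-vertex vector properties
#' `gradient`, `force`, `curl` (component-wise) and scalar `curl_magnitude`,
#' for inspection in any polygonal viewer.
#'
#' @param field A `vfa_field` tibble from [field_samples()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_ply <- function(field, path) {
  m <- as.matrix(field[, c(
    "x", "y", "z", "gx", "gy", "gz", "fx", "fy", "fz",
    "curl_x", "curl_y", "curl_z", "curl_magnitude"
  )])
  m <- cbind(m, attribute = field$attribute)
  write_ply(m, path, int_props = "attribute")
}

#' Write a registration result as JSON
#'
#' Schema: `method`, `transform` (the [write_transform_json()] schema),
#' `residual`, `iterations`, `converged`, `pivot_used_mm`, `energy_trace`
#' (arrays `iteration` and `value`), and `config` (the full configuration
#' echo).
#'
#' @param result A `registration_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path) {
  tf <- result$transform
  obj <- list(
    method = result$method,
    transform = list(
      angles_deg = tf$angles_deg,
      axis_order = "xyz-extrinsic",
      translation_mm = tf$translation_mm,
      pivot_mm = tf$pivot_mm,
      rotation_matrix = unname(apply(tf$rotation, 1, as.double, simplify = FALSE))
    ),
    residual = result$residual,
    iterations = result$iterations,
    converged = result$converged,
    pivot_used_mm = result$pivot_used,
    energy_trace = list(
      iteration = result$energy_trace$iteration,
      value = result$energy_trace$value
    ),
    config = unclass(result$config)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a result table as CSV
#'
#' Thin deterministic wrapper around [readr::write_csv()]; the column order
#' of `rows` is preserved.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}
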