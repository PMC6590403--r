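# Structured error conditions shared across the package. Every error carries a
# class so callers (and the CLI) can branch on the failure mode instead of
# matching message text.

abort_missing_class <- function(missing, call = rlang::caller_env()) {
  abort(
    sprintf(
      "moving cloud has attribute class(es) %s with no counterpart in the fixed cloud",
      paste(missing, collapse = ", ")
    ),
    class = "vfa_missing_class_error",
    missing_classes = missing,
    call = call
  )
}

abort_empty_feature <- function(which = "moving", call = rlang::caller_env()) {
  abort(
    sprintf("%s cloud has no points with a nonzero form attribute", which),
    class = "vfa_empty_feature_error",
    call = call
  )
}

abort_degenerate_neighborhood <- function(index, call = rlang::caller_env()) {
  abort(
    sprintf(
      "neighborhood of point %d is rank-deficient (collinear positions); increase k_neighbors",
      index
    ),
    class = "vfa_degenerate_neighborhood_error",
    index = index,
    call = call
  )
}

abort_nonfinite_objective <- function(x, value, call = rlang::caller_env()) {
  abort(
    sprintf(
      "objective returned a non-finite value (%s) at parameters [%s]",
      format(value), paste(signif(x, 6), collapse = ", ")
    ),
    class = "vfa_nonfinite_objective_error",
    parameters = x,
    call = call
  )
}

abort_parse <- function(path, what, call = rlang::caller_env()) {
  abort(
    sprintf("failed to parse %s: %s", path, what),
    class = "vfa_parse_error",
    path = path,
    call = call
  )
}

warn_missing_attribute <- function(path) {
  warn(
    sprintf("%s has no 'attribute' vertex property; assigning attribute 0 to all points", path),
    class = "vfa_missing_attribute_warning"
  )
}
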