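# Lean internal evaluator used by the registration drivers. Precomputes the
# per-class coordinate matrices once, then evaluates energy and Jacobian with
# plain matrix arithmetic: identical mathematics to energy_of_params() /
# jacobian_of_params() (which remain the reference implementations), minus
# the per-call correspondence table construction.

make_energy_context <- function(fixed, moving, config) {
  mv <- attributed_points(moving)
  if (nrow(mv) == 0) abort_empty_feature("moving")
  fx <- attributed_points(fixed)
  if (nrow(fx) == 0) abort_empty_feature("fixed")
  s2 <- config$sigma^2

  if (config$method == "gf") {
    A0 <- cloud_matrix(moving)[mv$source_index, , drop = FALSE]
    B <- cloud_matrix(fixed)[fx$source_index, , drop = FALSE]
    pen <- config$w_gf * outer(mv$attribute, fx$attribute, "-")^2
    bb <- rowSums(B^2)
    blocks <- list(list(A0 = A0, B = B, pen = pen, bb = bb))
  } else {
    missing <- setdiff(unique(mv$attribute), fx$attribute)
    if (length(missing) > 0) abort_missing_class(sort(missing))
    blocks <- lapply(sort(unique(mv$attribute)), function(cls) {
      A0 <- cloud_matrix(moving)[mv$source_index[mv$attribute == cls], , drop = FALSE]
      B <- cloud_matrix(fixed)[fx$source_index[fx$attribute == cls], , drop = FALSE]
      list(A0 = A0, B = B, pen = NULL, bb = rowSums(B^2))
    })
  }
  n_total <- sum(vapply(blocks, function(b) nrow(b$A0), 0L))

  pose_block <- function(b, R, c_, t_) {
    sweep(sweep(b$A0, 2, c_) %*% t(R), 2, c_ + t_, "+")
  }

  energy <- function(params6, pivot) {
    R <- rotation_matrix(params6[1:3])
    t_ <- params6[4:6]
    e <- 0
    for (b in blocks) {
      A <- pose_block(b, R, pivot, t_)
      d2 <- outer(rowSums(A^2), b$bb, "+") - 2 * tcrossprod(A, b$B)
      if (!is.null(b$pen)) d2 <- d2 + b$pen
      dmin <- d2[cbind(seq_len(nrow(d2)), max.col(-d2, ties.method = "first"))]
      e <- e + sum(1 - exp(-pmax(dmin, 0) / s2))
    }
    e
  }

  jacobian <- function(params6, pivot) {
    R <- rotation_matrix(params6[1:3])
    t_ <- params6[4:6]
    dR <- rotation_derivatives(params6[1:3])
    g <- numeric(6)
    for (b in blocks) {
      A <- pose_block(b, R, pivot, t_)
      d2 <- outer(rowSums(A^2), b$bb, "+") - 2 * tcrossprod(A, b$B)
      if (!is.null(b$pen)) d2 <- d2 + b$pen
      best <- max.col(-d2, ties.method = "first")
      diffs <- A - b$B[best, , drop = FALSE]
      d2b <- rowSums(diffs^2)
      if (!is.null(b$pen)) d2b <- d2b + b$pen[cbind(seq_along(best), best)]
      V <- diffs * ((2 / s2) * exp(-d2b / s2))
      q0c <- sweep(b$A0, 2, pivot)
      g <- g + c(
        sum(V * (q0c %*% t(dR$dphi))),
        sum(V * (q0c %*% t(dR$dtheta))),
        sum(V * (q0c %*% t(dR$dpsi))),
        colSums(V)
      )
    }
    unname(g)
  }

  list(energy = energy, jacobian = jacobian, n = n_total)
}
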