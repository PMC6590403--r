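#' Quasi-Newton minimization with Armijo backtracking
#'
#' BFGS minimizer used by both registration drivers. Maintains an inverse
#' Hessian approximation, searches along the quasi-Newton direction with
#' Armijo backtracking (sufficient-decrease condition), and terminates when
#' the gradient norm or the accepted function decrease falls below tolerance,
#' or after `max_iterations` accepted steps. The best point visited by any
#' evaluation (including rejected line-search probes) is returned.
#'
#' @param objective Function of a numeric vector returning a scalar. A
#'   non-finite value raises an error of class
#'   `vfa_nonfinite_objective_error`.
#' @param jacobian Function of a numeric vector returning the gradient.
#' @param x0 Numeric start vector.
#' @param control List of options: `max_iterations` (500),
#'   `gradient_tolerance` (1e-6, Euclidean norm), `function_tolerance`
#'   (1e-9, absolute accepted decrease), `armijo_constant` (1e-4),
#'   `backtrack_shrink` (0.5), `max_backtracks` (30), `step_out` (TRUE),
#'   `step_out_probes` (20), `stall_candidates` (NULL).
#'
#' @details
#' When `step_out` is enabled the line search widens at stall: whenever a
#' convergence test triggers (or no Armijo step is admissible), the search
#' probes a set of distant points before convergence is declared, and resumes
#' from the best probed point if one strictly improves on the incumbent. By
#' default the probes are geometrically expanding step lengths along the
#' current descent directions; a caller with problem structure can supply
#' `stall_candidates`, a `function(x)` returning a list of candidate
#' parameter vectors to test instead (the registration drivers use this to
#' probe large rotation offsets with the translation re-centered). Only
#' improving points are ever accepted, so the accepted-step energy trace
#' remains non-increasing; the exploratory oscillations live inside the line
#' search. This is what lets the minimizer step out of local minima of a
#' multi-modal objective while still terminating at tolerance on convex
#' problems.
#' @return A list with `x` (best visited point), `value`, `iterations`
#'   (accepted steps), `converged` (TRUE when a tolerance triggered, FALSE on
#'   hitting `max_iterations`), `evaluations`, and `trace`: a tibble with one
#'   row per accepted step (`iteration`, `value`, `step_size`,
#'   `gradient_norm`), `value` non-increasing.
#' @export
quasi_newton_minimize <- function(objective, jacobian, x0,
                                  control = list()) {
  ctl <- utils::modifyList(list(
    max_iterations = 500,
    gradient_tolerance = 1e-6,
    function_tolerance = 1e-9,
    armijo_constant = 1e-4,
    backtrack_shrink = 0.5,
    max_backtracks = 30,
    step_out = TRUE,
    step_out_probes = 20,
    stall_window = 25,
    stall_window_rel = 1e-3,
    stall_candidates = NULL,
    step_out_greedy = 0.25
  ), control)

  n_eval <- 0L
  best_x <- NULL
  best_f <- Inf
  f_of <- function(x) {
    v <- objective(x)
    n_eval <<- n_eval + 1L
    if (!is.finite(v)) abort_nonfinite_objective(x, v)
    if (v < best_f) {
      best_f <<- v
      best_x <<- x
    }
    v
  }

  x <- as.double(x0)
  f <- f_of(x)
  g <- jacobian(x)
  H <- diag(length(x))
  trace_it <- integer(0)
  trace_f <- double(0)
  trace_step <- double(0)
  trace_g <- double(0)
  push <- function(it, fv, step, gn) {
    trace_it <<- c(trace_it, it)
    trace_f <<- c(trace_f, fv)
    trace_step <<- c(trace_step, step)
    trace_g <<- c(trace_g, gn)
  }
  push(0L, f, 0, sqrt(sum(g^2)))

  # widened line search at stall: probe distant points, return the best
  # strictly-improving one or NULL
  step_out_probe <- function(x, f, dirs) {
    cands <- if (is.function(ctl$stall_candidates)) {
      ctl$stall_candidates(x)
    } else {
      out <- list()
      for (d in dirs) {
        nd <- sqrt(sum(d^2))
        if (!is.finite(nd) || nd == 0) next
        d <- d / nd
        for (k in seq_len(ctl$step_out_probes)) {
          out <- c(out, list(x + 2^(k - 2) * d), list(x - 2^(k - 2) * d))
        }
      }
      out
    }
    best_probe <- NULL
    best_pf <- f
    for (xt in cands) {
      ft <- f_of(xt)
      if (ft < best_pf) {
        best_pf <- ft
        best_probe <- xt
        # a probe this much better is worth taking immediately; later stalls
        # re-probe anyway
        if (ft < f - ctl$step_out_greedy * abs(f)) break
      }
    }
    best_probe
  }

  converged <- FALSE
  stalled <- sqrt(sum(g^2)) < ctl$gradient_tolerance
  stall_soft <- FALSE
  iter <- 0L
  window_iter <- 0L
  window_f <- f
  p <- -g
  while (iter < ctl$max_iterations) {
    if (!stalled) {
      p <- -as.double(H %*% g)
      gp <- sum(g * p)
      if (!is.finite(gp) || gp >= 0) { # not a descent direction: reset to steepest
        H <- diag(length(x))
        p <- -g
        gp <- -sum(g^2)
      }
      alpha <- 1
      accepted <- FALSE
      for (bt in seq_len(ctl$max_backtracks + 1L)) {
        x_new <- x + alpha * p
        f_new <- f_of(x_new)
        if (f_new <= f + ctl$armijo_constant * alpha * gp) {
          accepted <- TRUE
          break
        }
        alpha <- alpha * ctl$backtrack_shrink
      }
      if (!accepted) {
        stalled <- TRUE
        next
      }
      g_new <- jacobian(x_new)
      s <- x_new - x
      yv <- g_new - g
      sy <- sum(s * yv)
      if (sy > 1e-10 * sqrt(sum(s^2)) * sqrt(sum(yv^2))) {
        rho <- 1 / sy
        I <- diag(length(x))
        V <- I - rho * tcrossprod(s, yv)
        H <- V %*% H %*% t(V) + rho * tcrossprod(s)
      }
      delta_f <- f - f_new
      x <- x_new
      f <- f_new
      g <- g_new
      iter <- iter + 1L
      push(iter, f, alpha, sqrt(sum(g^2)))
      if (sqrt(sum(g^2)) < ctl$gradient_tolerance ||
          abs(delta_f) < ctl$function_tolerance) {
        stalled <- TRUE
      }
      # windowed progress check: a descent that only crawls (e.g. on a
      # saturated plateau, where per-step decreases stay above the function
      # tolerance but go nowhere) gets a probe round too, without affecting
      # the convergence report
      if (iter - window_iter >= ctl$stall_window) {
        if ((window_f - f) < ctl$stall_window_rel * max(abs(f), 1)) {
          stalled <- TRUE
          stall_soft <- TRUE
        }
        window_iter <- iter
        window_f <- f
      }
    } else {
      # a convergence test triggered (or no Armijo step exists); before
      # declaring convergence, widen the search along the current descent
      # directions
      if (!isTRUE(ctl$step_out)) {
        converged <- TRUE
        break
      }
      escape <- step_out_probe(x, f, list(p, -g))
      if (is.null(escape)) {
        if (stall_soft) { # slow but live descent: keep going
          stalled <- FALSE
          stall_soft <- FALSE
          next
        }
        converged <- TRUE
        break
      }
      x <- escape
      f <- f_of(escape) # re-evaluate to keep f exact (cheap, cached-by-value)
      g <- jacobian(x)
      H <- diag(length(x))
      iter <- iter + 1L
      push(iter, f, NA_real_, sqrt(sum(g^2)))
      stalled <- sqrt(sum(g^2)) < ctl$gradient_tolerance
      stall_soft <- FALSE
      window_iter <- iter
      window_f <- f
    }
  }
  if (iter >= ctl$max_iterations) converged <- FALSE

  # the best visited point may beat the last accepted one by a sub-tolerance
  # margin; report it, keeping the trace monotone
  if (best_f < trace_f[length(trace_f)]) {
    push(iter, best_f, NA_real_, NA_real_)
  }
  list(
    x = best_x,
    value = best_f,
    iterations = iter,
    converged = converged,
    evaluations = n_eval,
    trace = tibble(
      iteration = trace_it, value = trace_f,
      step_size = trace_step, gradient_norm = trace_g
    )
  )
}
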