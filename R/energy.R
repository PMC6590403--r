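#' Gaussian per-point potential
#'
#' The potential energy of a moving point at closest-distance `d` from its
#' match, in Gaussian scale space: \deqn{U = 1 - \exp(-d^2/\sigma^2).}
#' It is 0 at perfect alignment, strictly increasing in `d`, and saturates at
#' 1 for `d >> sigma`. Near alignment it approximates `d^2/sigma^2`, i.e. a
#' (scaled) Hooke spring energy.
#'
#' @param d Non-negative distance(s) in mm (vectorized).
#' @param sigma Positive Gaussian aperture.
#' @return Values in `[0, 1)`.
#' @examples
#' gaussian_potential(10, 10) # 1 - exp(-1)
#' @export
gaussian_potential <- function(d, sigma = 10) {
  stopifnot(sigma > 0, all(d >= 0))
  1 - exp(-(d / sigma)^2)
}

#' Hooke (spring) energy of a correspondence
#'
#' The quadratic registration energy `sum(d_n^2)` with unit spring constant:
#' the absolute work done by elastic forces pulling every matched moving point
#' onto its fixed counterpart.
#'
#' @param corr A correspondence from [closest_points()].
#' @return Non-negative scalar (mm^2).
#' @export
hooke_energy <- function(corr) {
  sum(corr$distance_mm^2)
}

#' Total Gaussian registration energy
#'
#' \deqn{E_\sigma = \sum_n (1 - \exp(-d_n^2/\sigma^2))}
#' over all matched moving points; bounded in `[0, N]`. This is the objective
#' minimized by the registration drivers.
#'
#' @param corr A correspondence from [closest_points()].
#' @param params An [energy_params()] object (supplies `sigma`).
#' @return Non-negative scalar, at most `nrow(corr)`.
#' @export
total_energy <- function(corr, params = energy_params()) {
  sum(gaussian_potential(corr$distance_mm, params$sigma))
}
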