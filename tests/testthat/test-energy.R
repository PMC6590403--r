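test_that("Gaussian potential has the right anchors and monotonicity", {
  expect_identical(gaussian_potential(0, 10), 0)
  expect_equal(gaussian_potential(10, 10), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(gaussian_potential(1e6, 10), 1, tolerance = 1e-15)
  d <- seq(0, 50, by = 0.5)
  expect_true(all(diff(gaussian_potential(d, 10)) > 0))
  expect_true(all(gaussian_potential(d, 10) >= 0 & gaussian_potential(d, 10) < 1))
})

test_that("Hooke and Gaussian energies reduce to their sums", {
  corr <- tibble::tibble(distance_mm = c(3, 4))
  expect_identical(hooke_energy(corr), 25)

  set.seed(301)
  d <- runif(200, 0, 40)
  corr <- tibble::tibble(distance_mm = d)
  # term-by-term loop oracle
  acc <- 0
  for (x in d) acc <- acc + x^2
  expect_equal(hooke_energy(corr), acc, tolerance = 1e-9)
  expect_equal(
    total_energy(corr, energy_params(sigma = 10)),
    sum(1 - exp(-(d / 10)^2)),
    tolerance = 1e-12
  )
  # bounded in [0, N]; saturates when all points are far
  expect_lt(total_energy(corr), length(d))
  far <- tibble::tibble(distance_mm = rep(1e4, 50))
  expect_equal(total_energy(far), 50, tolerance = 1e-12)
})

test_that("small-displacement energy approximates the scaled Hooke energy", {
  set.seed(302)
  d <- runif(300, 0, 1) # all below 0.1 * sigma
  corr <- tibble::tibble(distance_mm = d)
  e <- total_energy(corr, energy_params(sigma = 10))
  expect_lt(abs(e - sum(d^2) / 100) / e, 0.01)
})

test_that("energy is invariant under a joint rigid motion of both clouds", {
  set.seed(303)
  fixed <- random_cloud(80, k = 3)
  moving <- transform_cloud(fixed, rigid_transform(c(4, -3, 7), c(2, 1, -2)))
  e0 <- total_energy(closest_points(moving, fixed))
  tf <- random_transform(100)
  e1 <- total_energy(closest_points(
    transform_cloud(moving, tf), transform_cloud(fixed, tf)
  ))
  expect_equal(e1, e0, tolerance = 1e-9)
})

test_that("energy is zero iff the attributed clouds coincide", {
  set.seed(304)
  cl <- random_cloud(60, k = 3)
  expect_identical(total_energy(closest_points(cl, cl)), 0)
  nudged <- cl
  nudged$x[1] <- nudged$x[1] + 0.5
  expect_gt(total_energy(closest_points(nudged, cl)), 0)
})

test_that("analytic potential gradient matches the closed form and finite differences", {
  fixed <- attributed_cloud(0, 0, 0, attribute = 1L)
  moving <- attributed_cloud(10, 0, 0, attribute = 1L)
  pg <- potential_gradient(moving, fixed)
  expect_equal(pg$gx, 0.2 * exp(-1), tolerance = 1e-9)
  expect_equal(pg$gx, 0.073576, tolerance = 1e-5)
  expect_equal(c(pg$gy, pg$gz), c(0, 0))
  expect_equal(c(pg$fx, pg$fy, pg$fz), -c(pg$gx, pg$gy, pg$gz))

  # gradient vanishes at a perfectly matched point
  pg0 <- potential_gradient(fixed, fixed)
  expect_equal(c(pg0$gx, pg0$gy, pg0$gz), c(0, 0, 0))

  # random configurations against central finite differences of the
  # frozen-correspondence potential
  set.seed(305)
  params <- energy_params(sigma = 10)
  for (rep in 1:100) {
    q <- runif(3, -15, 15)
    p <- runif(3, -15, 15)
    f <- function(v) gaussian_potential(sqrt(sum((v - p)^2)), 10)
    got <- (2 / 100) * exp(-sum((q - p)^2) / 100) * (q - p)
    expect_equal(got, num_grad(f, q, h = 1e-4), tolerance = 1e-5)
  }
})

test_that("forces attract: a small step along the force never raises the potential", {
  set.seed(306)
  fixed <- random_cloud(60, k = 3)
  moving <- transform_cloud(fixed, rigid_transform(c(6, -4, 10), c(3, 1, -2)))
  pg <- potential_gradient(moving, fixed)
  eps <- 1e-4
  moved <- moving
  att <- pg$moving_index
  moved$x[att] <- moved$x[att] + eps * pg$fx
  moved$y[att] <- moved$y[att] + eps * pg$fy
  moved$z[att] <- moved$z[att] + eps * pg$fz
  # same correspondence, recomputed distances
  fx_pts <- cloud_matrix(fixed)
  corr <- closest_points(moving, fixed)
  d_new <- sqrt(rowSums((cloud_matrix(moved)[corr$moving_index, , drop = FALSE] -
    fx_pts[corr$fixed_index, , drop = FALSE])^2))
  expect_true(all(
    gaussian_potential(d_new, 10) <= gaussian_potential(corr$distance_mm, 10) + 1e-12
  ))
})

test_that("energy parameter validation enforces the contracts", {
  expect_error(energy_params(sigma = 0), "sigma")
  expect_error(energy_params(w = 100), "very large")
  expect_error(energy_params(spring_k = 2), "fixed at 1")
  p <- energy_params()
  expect_identical(c(p$sigma, p$w, p$spring_k), c(10, 1e9, 1))
  expect_error(registration_config(max_iterations = 0))
})
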