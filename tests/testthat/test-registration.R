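test_that("energy_of_params is consistent with direct energies", {
  set.seed(601)
  fixed <- random_cloud(80, k = 3)
  cfg <- registration_config("vfa")

  # zero parameters leave aligned clouds at zero energy, for any pivot
  expect_identical(energy_of_params(rep(0, 6), c(0, 0, 0), fixed, fixed, cfg), 0)
  expect_identical(energy_of_params(rep(0, 6), c(50, -20, 10), fixed, fixed, cfg), 0)

  # value at the generating displacement equals the energy of the
  # directly-displaced clouds
  piv <- c(10, -5, 20)
  p6 <- c(12, -8, 25, 4, -2, 6)
  moving <- fixed
  posed <- transform_cloud(moving, rigid_transform(p6[1:3], p6[4:6], piv))
  expect_equal(
    energy_of_params(p6, piv, fixed, moving, cfg),
    total_energy(closest_points(posed, fixed), energy_params(cfg$sigma)),
    tolerance = 1e-12
  )
})

test_that("the internal fast evaluator agrees with the reference path", {
  set.seed(602)
  fixed <- random_cloud(70, k = 3, background = 10)
  moving <- random_cloud(50, k = 3, background = 5)
  piv <- rnorm(3, sd = 15)
  for (method in c("vfa", "gf")) {
    cfg <- registration_config(method)
    ctx <- vfareg:::make_energy_context(fixed, moving, cfg)
    for (rep in 1:10) {
      p6 <- c(runif(3, -180, 180), runif(3, -30, 30))
      expect_equal(ctx$energy(p6, piv),
                   energy_of_params(p6, piv, fixed, moving, cfg),
                   tolerance = 1e-10)
      expect_equal(ctx$jacobian(p6, piv),
                   jacobian_of_params(p6, piv, fixed, moving, cfg),
                   tolerance = 1e-10)
    }
  }
})

test_that("analytic parameter Jacobian matches finite differences", {
  set.seed(603)
  fixed <- random_cloud(60, k = 3)
  moving <- transform_cloud(fixed, rigid_transform(c(3, -2, 5), c(1, 2, -1)))
  cfg <- registration_config("vfa")
  piv <- c(5, 5, -5)

  # stationary at perfect alignment
  j0 <- jacobian_of_params(rep(0, 6), piv, fixed, fixed, cfg)
  expect_lt(max(abs(j0)), 1e-9)

  # translation components reduce to the summed per-point gradients
  p0 <- rep(0, 6)
  j <- jacobian_of_params(p0, piv, fixed, moving, cfg)
  pg <- potential_gradient(moving, fixed)
  expect_equal(j[4:6], c(sum(pg$gx), sum(pg$gy), sum(pg$gz)), tolerance = 1e-9)

  # finite-difference oracle at engaged random poses
  for (rep in 1:10) {
    p6 <- c(runif(3, -15, 15), runif(3, -8, 8))
    fd <- num_grad(function(p) energy_of_params(p, piv, fixed, moving, cfg), p6)
    an <- jacobian_of_params(p6, piv, fixed, moving, cfg)
    expect_equal(an, fd, tolerance = 1e-4)
  }
})

test_that("registration of already-aligned clouds is an immediate identity", {
  ph <- small_phantom()
  res <- register_vfa(ph, ph)
  expect_lte(res$iterations, 2)
  expect_true(res$converged)
  expect_lt(res$residual, 1e-9)
  d <- transform_discrepancy(res$transform, rigid_transform())
  expect_lt(d$angle_deg, 1e-6)
  expect_lt(d$translation_mm, 1e-6)

  resg <- register_gf(ph, ph)
  expect_lt(resg$residual, 1e-9)
})

test_that("a displaced identical phantom is recovered to numerical precision", {
  ph <- small_phantom()
  tf <- rigid_transform(c(130, 40, -75), c(60, -120, 90))
  mv <- displace(ph, tf)
  res <- register_vfa(ph, mv)
  expect_lt(res$residual, 1e-3)
  err <- recovery_error(tf, res$transform)
  expect_lt(err$angle_deg, 0.1)
  expect_lt(err$translation_mm, 0.1)
  # net transform is reported pivot-free
  expect_equal(res$transform$pivot_mm, c(0, 0, 0))
  # trace is non-increasing and ends at the residual
  expect_true(all(diff(res$energy_trace$value) <= 1e-12))
  expect_equal(res$residual, tail(res$energy_trace$value, 1))
})

test_that("GF converges from small rotations but fails from a half-turn", {
  ph <- small_phantom()
  att <- attributed_points(ph)
  cen <- colMeans(cloud_matrix(ph)[att$source_index, ])

  mv_small <- displace(ph, rigid_transform(c(0, 0, 8), pivot_mm = cen))
  res_small <- register_gf(ph, mv_small)
  expect_lt(res_small$residual, 1e-3)

  mv_flip <- displace(ph, rigid_transform(c(0, 0, 180), pivot_mm = cen))
  res_gf <- register_gf(ph, mv_flip)
  res_vfa <- register_vfa(ph, mv_flip)
  expect_lt(res_vfa$residual, 1e-3)
  expect_gt(res_gf$residual, 5 * max(res_vfa$residual, 1))
})

test_that("registration propagates matching errors", {
  fixed <- attributed_cloud(c(0, 1), c(0, 0), c(0, 0), attribute = c(1L, 2L))
  moving <- attributed_cloud(0, 0, 0, attribute = 3L)
  expect_error(register_vfa(fixed, moving), class = "vfa_missing_class_error")
  bg <- attributed_cloud(0, 0, 0, attribute = 0L)
  expect_error(register_vfa(fixed, bg), class = "vfa_empty_feature_error")
})

test_that("result accessors tidy, glance and autoplot work", {
  ph <- small_phantom()
  res <- register_vfa(ph, displace(ph, rigid_transform(c(5, 0, 0), c(1, 0, 0))))
  td <- tidy(res)
  expect_identical(td$term,
                   c("phi_deg", "theta_deg", "psi_deg", "tx_mm", "ty_mm", "tz_mm"))
  gl <- glance(res)
  expect_identical(gl$method, "vfa")
  expect_true(is.numeric(gl$residual))
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("registering the noisy scan stays within the clinical error budget", {
  ph <- standard_phantom()
  sc <- standard_scan()
  truth <- rigid_transform(c(25, -40, 110), c(30, -20, 45))
  fit <- register_vfa(ph, displace(sc, truth))
  expect_gt(fit$residual, 0) # noise keeps the energy off its floor
  targets <- phantom_targets(ph)
  rep <- tre(targets, transform_cloud(targets, truth), fit$transform)
  expect_lte(glance(rep)$max, 1.5)
})

test_that("periodic ICR refresh reaches the same minimum", {
  ph <- small_phantom()
  tf <- rigid_transform(c(40, -20, 70), c(30, -10, 20))
  mv <- displace(ph, tf)
  res <- register_vfa(ph, mv, registration_config("vfa", refresh_icr_every = 15))
  expect_lt(res$residual, 1e-3)
  err <- recovery_error(tf, res$transform)
  expect_lt(err$angle_deg, 0.1)
  expect_true(all(diff(res$energy_trace$value) <= 1e-12))
})
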