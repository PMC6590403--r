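test_that("weighted distance reduces to Euclidean for equal attributes", {
  expect_identical(weighted_distance(c(0, 0, 0, 1), c(3, 4, 0, 1), 1e9), 5)
  expect_identical(weighted_distance(c(0, 0, 0, 1), c(0, 0, 0, 1), 1e9), 0)
  # attribute mismatch at coincident coordinates is dominated by w
  expect_equal(
    weighted_distance(c(0, 0, 0, 1), c(0, 0, 0, 2), 1e9),
    sqrt(1e9),
    tolerance = 1e-12
  )
})

test_that("closest_points matches the worked example and the identity case", {
  moving <- attributed_cloud(c(0, 5), c(0, 0), c(0, 0), attribute = c(1L, 2L))
  fixed <- attributed_cloud(
    c(1, 0, 9), c(0, 1, 9), c(0, 0, 9), attribute = c(1L, 2L, 1L)
  )
  corr <- closest_points(moving, fixed)
  expect_equal(corr$moving_index, c(1L, 2L))
  expect_equal(corr$fixed_index, c(1L, 2L))
  expect_equal(corr$distance_mm, c(1, sqrt(26)), tolerance = 1e-12)

  # identical clouds: every matched distance is zero
  set.seed(201)
  cl <- random_cloud(80, k = 4)
  self <- closest_points(cl, cl)
  expect_equal(max(self$distance_mm), 0)
  expect_equal(nrow(self), sum(cl$attribute > 0))
})

test_that("matching errors carry structured classes", {
  moving <- attributed_cloud(0, 0, 0, attribute = 3L)
  fixed <- attributed_cloud(c(0, 1), c(0, 0), c(0, 0), attribute = c(1L, 2L))
  expect_error(closest_points(moving, fixed), class = "vfa_missing_class_error")

  bg_only <- attributed_cloud(c(0, 1), c(0, 0), c(0, 0), attribute = 0L)
  expect_error(closest_points(bg_only, fixed), class = "vfa_empty_feature_error")
})

test_that("fast matching agrees with the brute-force and loop oracles", {
  set.seed(202)
  for (rep in 1:25) {
    moving <- random_cloud(sample(10:60, 1), k = sample(1:4, 1), background = 5)
    fixed <- random_cloud(sample(20:80, 1), k = 4, background = 5)
    corr <- closest_points(moving, fixed)
    bf <- brute_force_closest(moving, fixed, w = 1e9)
    keep <- bf$moving_index %in% corr$moving_index
    expect_identical(corr$fixed_index, bf$fixed_index[keep])
    expect_equal(corr$distance_mm, bf$distance_mm[keep], tolerance = 1e-9)
  }
  # small case against the literal nested-loop reference
  moving <- random_cloud(15, k = 2)
  fixed <- random_cloud(25, k = 2)
  ref <- ref_closest(moving, fixed, w = 1e9)
  bf <- brute_force_closest(moving, fixed, w = 1e9)
  expect_identical(bf$fixed_index, ref$fixed_index)
  expect_equal(bf$distance_mm, ref$distance_mm, tolerance = 1e-9)
})

test_that("w = 0 brute force ignores attributes", {
  set.seed(203)
  moving <- random_cloud(20, k = 3)
  fixed <- random_cloud(30, k = 3)
  bf <- brute_force_closest(moving, fixed, w = 0)
  dm <- as.matrix(dist(rbind(cloud_matrix(moving), cloud_matrix(fixed))))
  dm <- dm[seq_len(20), 20 + seq_len(30)]
  expect_equal(bf$fixed_index, unname(apply(dm, 1, which.min)))
  expect_equal(bf$distance_mm, unname(apply(dm, 1, min)), tolerance = 1e-9)
})

test_that("adding fixed points never increases a matched distance", {
  set.seed(204)
  moving <- random_cloud(40, k = 3)
  fixed <- random_cloud(60, k = 3)
  extra <- random_cloud(30, k = 3)
  bigger <- as_attributed_cloud(rbind(
    fixed[, c("x", "y", "z", "attribute")],
    extra[, c("x", "y", "z", "attribute")]
  ))
  d1 <- closest_points(moving, fixed)$distance_mm
  d2 <- closest_points(moving, bigger)$distance_mm
  expect_true(all(d2 <= d1 + 1e-12))
})

test_that("nearest-neighbour ties go to the lowest fixed index", {
  moving <- attributed_cloud(0, 0, 0, attribute = 1L)
  fixed <- attributed_cloud(c(1, -1, 1), c(0, 0, 0), c(0, 0, 0), attribute = 1L)
  expect_identical(closest_points(moving, fixed)$fixed_index, 1L)
  expect_identical(brute_force_closest(moving, fixed, 1e9)$fixed_index, 1L)
})
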