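test_that("identity and elementary rotations act as expected", {
  cl <- attributed_cloud(1, 2, 3, attribute = 1L)

  out <- transform_cloud(cl, rigid_transform())
  expect_identical(cloud_matrix(out), cloud_matrix(cl))

  # half-turn about x negates y and z
  out <- transform_cloud(cl, rigid_transform(c(180, 0, 0)))
  expect_equal(unname(cloud_matrix(out)[1, ]), c(1, -2, -3), tolerance = 1e-12)

  # attributes ride along untouched
  expect_identical(out$attribute, cl$attribute)
})

test_that("rotation matrices are orthonormal with unit determinant on an angle grid", {
  grid <- seq(0, 360, by = 15)
  worst_orth <- 0
  worst_det <- 0
  for (a in grid) for (b in grid) for (c_ in grid) {
    R <- rotation_matrix(c(a, b, c_))
    worst_orth <- max(worst_orth, max(abs(crossprod(R) - diag(3))))
    worst_det <- max(worst_det, abs(det(R) - 1))
  }
  expect_lt(worst_orth, 1e-9)
  expect_lt(worst_det, 1e-9)
})

test_that("transforms preserve pairwise distances", {
  set.seed(101)
  cl <- random_cloud(50)
  tf <- random_transform(100)
  out <- transform_cloud(cl, tf)
  expect_equal(
    as.matrix(dist(cloud_matrix(out))),
    as.matrix(dist(cloud_matrix(cl))),
    tolerance = 1e-9
  )
  # and agree with direct matrix construction
  R <- rotation_matrix(tf$angles_deg)
  direct <- sweep(sweep(cloud_matrix(cl), 2, tf$pivot_mm) %*% t(R),
                  2, tf$pivot_mm + tf$translation_mm, "+")
  expect_equal(cloud_matrix(out), direct, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("inversion and composition round-trip points", {
  expect_equal(
    invert_transform(rigid_transform())$translation_mm, c(0, 0, 0)
  )
  # pure translation inverts to its negation
  inv <- invert_transform(rigid_transform(c(0, 0, 0), c(1, 2, 3)))
  expect_equal(inv$translation_mm, c(-1, -2, -3), tolerance = 1e-12)

  set.seed(102)
  cl <- random_cloud(100)
  for (i in 1:5) {
    tf <- random_transform(150, pivot_mm = rnorm(3, sd = 20))
    back <- transform_cloud(transform_cloud(cl, tf), invert_transform(tf))
    expect_equal(cloud_matrix(back), cloud_matrix(cl), tolerance = 1e-9)

    net <- compose_transforms(tf, invert_transform(tf))
    d <- transform_discrepancy(net, rigid_transform())
    # the acos-based angle metric bottoms out near sqrt(machine eps)
    expect_lt(d$angle_deg, 1e-5)
    expect_lt(d$translation_mm, 1e-9)
  }
})

test_that("pivot is parameterization only", {
  set.seed(103)
  cl <- random_cloud(100)
  tf <- rigid_transform(c(40, -25, 110), c(5, -8, 3), pivot_mm = c(30, -10, 70))
  equiv <- as_origin_pivot(tf)
  expect_equal(equiv$pivot_mm, c(0, 0, 0))
  expect_equal(
    cloud_matrix(transform_cloud(cl, tf)),
    cloud_matrix(transform_cloud(cl, equiv)),
    tolerance = 1e-9
  )
  # same-mapping transforms with different pivots compare as identical
  d <- transform_discrepancy(tf, equiv)
  expect_lt(d$angle_deg, 1e-5)
  expect_lt(d$translation_mm, 1e-9)
})

test_that("transform JSON round-trips", {
  tf <- rigid_transform(c(38, -5, -160), c(0.06, 0.04, 0), pivot_mm = c(1, 2, 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_transform_json(tf, path)
  back <- read_transform_json(path)
  expect_equal(back$angles_deg, tf$angles_deg)
  expect_equal(back$translation_mm, tf$translation_mm)
  expect_equal(back$pivot_mm, tf$pivot_mm)
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(foo = 1), bad)
  expect_error(read_transform_json(bad), class = "vfa_parse_error")
})

test_that("cloud validation enforces the container invariants", {
  expect_error(attributed_cloud(numeric(0), numeric(0), numeric(0)), "at least one")
  expect_error(attributed_cloud(Inf, 0, 0), "finite")
  expect_error(attributed_cloud(0, 0, 0, attribute = -1L), "non-negative")
  cl <- attributed_cloud(c(0, 1), c(0, 0), c(0, 0), attribute = c(0L, 2L))
  expect_identical(feature_classes(cl), 2L)
  expect_identical(attributed_points(cl)$source_index, 2L)
})
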