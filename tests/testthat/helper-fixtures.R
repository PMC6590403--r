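# Shared fixtures and independent reference implementations (oracles).
# Everything is generated in code; heavyweight objects are cached per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the study-condition phantom (generator defaults, seed 1)
standard_phantom <- function() {
  cached("phantom", function() make_phantom(phantom_config(seed = 1)))
}

# the study-condition CT-like / scan-like pair
standard_scan <- function() {
  cached("scan", function() {
    simulate_amode_scan(standard_phantom(), scan_config(seed = 1))
  })
}

# a small phantom for cheap registration tests
small_phantom <- function() {
  cached("small_phantom", function() {
    make_phantom(phantom_config(n_surface_points = 800, seed = 2))
  })
}

# random attributed cloud: n points, classes drawn from 1..k (plus optional
# background points with attribute 0)
random_cloud <- function(n, k = 3, spread = 50, background = 0) {
  attrs <- c(sample.int(k, n, replace = TRUE), rep(0L, background))
  m <- n + background
  attributed_cloud(
    runif(m, -spread, spread), runif(m, -spread, spread),
    runif(m, -spread, spread), attribute = attrs
  )
}

# oracle: closest points by plain nested loops over the weighted 4-D distance
ref_closest <- function(moving, fixed, w) {
  res <- lapply(seq_len(nrow(moving)), function(i) {
    p <- c(moving$x[i], moving$y[i], moving$z[i], moving$attribute[i])
    d <- vapply(seq_len(nrow(fixed)), function(j) {
      q <- c(fixed$x[j], fixed$y[j], fixed$z[j], fixed$attribute[j])
      weighted_distance(p, q, w)
    }, 0)
    j <- which.min(d) # which.min takes the first (lowest index) minimum
    c(j, d[j])
  })
  data.frame(
    moving_index = seq_len(nrow(moving)),
    fixed_index = as.integer(vapply(res, `[`, 0, 1)),
    distance_mm = vapply(res, `[`, 0, 2)
  )
}

# oracle: central finite differences of a scalar function
num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x))
    e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, 0)
}

# discrepancy of a recovered registration against the ground-truth displacement
recovery_error <- function(truth, recovered) {
  transform_discrepancy(compose_transforms(truth, recovered), rigid_transform())
}
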