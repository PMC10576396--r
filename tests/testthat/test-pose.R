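test_that("normals on a dense plane sample are exact", {
  set.seed(51)
  P <- cbind(stats::runif(3000, -2, 2), stats::runif(3000, -2, 2), 0)
  est <- estimate_normal(P, c(0, 0, 0))
  expect_equal(abs(est$normal[3]), 1, tolerance = 1e-6)
  expect_equal(sqrt(sum(est$normal^2)), 1, tolerance = 1e-9)
  expect_gt(est$triangle_area, 0)
  # the support triangle lies inside the search region
  sup <- P[est$support_triangle, ]
  expect_lt(max(sqrt(rowSums(sweep(sup, 2, est$position)^2))), 0.3 + 1e-12)
})

test_that("normals on a femur-scale shell stay within a degree", {
  shell <- surface_hemisphere_shell(98)
  set.seed(52)
  for (i in 1:10) {
    # random query on the upper shell, locally dense cloud
    th <- stats::runif(1, 0.2, 1.2); ph <- stats::runif(1, 0, 2 * pi)
    q <- 98 * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    s <- sample_surface(shell, 600, region = list(center = q, radius = 1.5),
                        seed = 52 + i)
    radial <- q / sqrt(sum(q^2))
    est <- estimate_normal(s$cloud, q, search_diameter_mm = 0.6,
                           reference = radial)
    expect_lt(ang_dif(est$normal, radial), 1.0)
  }
})

test_that("small neighbourhoods match the exhaustive-triangle oracle", {
  set.seed(53)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    P <- matrix(stats::rnorm(3 * n, 0, 0.1), n, 3)
    P <- sweep(P, 2, colMeans(P))          # keep inside the search region
    est <- tryCatch(estimate_normal(P, c(0, 0, 0), search_diameter_mm = 2),
                    error = function(e) NULL)
    if (is.null(est)) next
    # brute force over every triple
    best_area <- -1; best_n <- NULL
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      a <- P[j, ] - P[i, ]; b <- P[k, ] - P[i, ]
      cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
              a[1] * b[2] - a[2] * b[1])
      ar <- 0.5 * sqrt(sum(cr^2))
      if (ar > best_area) { best_area <- ar; best_n <- cr / sqrt(sum(cr^2)) }
    }
    expect_equal(est$triangle_area, best_area, tolerance = 1e-12)
    expect_equal(abs(sum(est$normal * best_n)), 1, tolerance = 1e-9)
  }
})

test_that("degenerate neighbourhoods raise distinct errors", {
  P2 <- matrix(stats::rnorm(6), 2, 3)
  expect_error(estimate_normal(P2, c(0, 0, 0)), "insufficient support")
  # collinear points within range
  line <- cbind(seq(-0.2, 0.2, length.out = 10), 0, 0)
  expect_error(estimate_normal(line, c(0, 0, 0)), "collinear")
})

test_that("ang_dif matches the atan2 oracle and its invariances", {
  expect_equal(ang_dif(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(ang_dif(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_error(ang_dif(c(0, 0, 0), c(0, 0, 1)), "zero")
  set.seed(54)
  for (i in 1:10000) {
    u <- stats::rnorm(3); v <- stats::rnorm(3)
    got <- ang_dif(u, v)
    cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    want <- atan2(sqrt(sum(cr^2)), sum(u * v)) * 180 / pi
    expect_lt(abs(got - want), 1e-9)
    # symmetry and scale invariance (spot-checked on a subsample)
    if (i %% 1000 == 0) {
      expect_equal(ang_dif(v, u), got, tolerance = 1e-12)
      expect_equal(ang_dif(3.7 * u, 0.2 * v), got, tolerance = 1e-9)
    }
  }
})

test_that("normal estimation is equivariant under rigid motions", {
  set.seed(55)
  s <- sample_surface(surface_sphere(c(0, 0, 50), 20), 500,
                      region = list(center = c(0, 0, 30), radius = 1.5),
                      seed = 7)
  q <- c(0, 0, 30)
  ref <- c(0, 0, -1)
  est0 <- estimate_normal(s$cloud, q, reference = ref)
  for (i in 1:10) {
    R <- random_rotation(); tr <- stats::rnorm(3, 0, 20)
    Pq <- as.numeric(R %*% q + tr)
    est <- estimate_normal(sweep(s$cloud %*% t(R), 2, tr, "+"), Pq,
                           reference = as.numeric(R %*% ref))
    expect_lt(max(abs(est$normal - as.numeric(R %*% est0$normal))), 1e-9)
  }
})

test_that("navigation reports AngDif at contact and nothing otherwise", {
  plane_cloud <- point_cloud(
    cbind(stats::runif(4000, -5, 5), stats::runif(4000, -5, 5), 0), "femur")
  # instrument perpendicular to the plane
  sim <- simulate_instrument_at(c(0, 0, 0.01), c(0, 0, -1))
  nav <- navigate(plane_cloud, sim$sensor2, sim$sensor3, sim$ic)
  expect_s3_class(nav, "navigation_sample")
  expect_lt(nav$ang_dif_deg, 1)
  # tilted by exactly 10 degrees
  dir10 <- c(sin(10 * pi / 180), 0, -cos(10 * pi / 180))
  sim10 <- simulate_instrument_at(c(0, 0, 0.01), dir10)
  nav10 <- navigate(plane_cloud, sim10$sensor2, sim10$sensor3, sim10$ic)
  expect_lt(abs(nav10$ang_dif_deg - 10), 1)
  expect_true(nav10$ang_dif_deg >= 0 && nav10$ang_dif_deg <= 90)
  # far away: no contact signal
  sim_far <- simulate_instrument_at(c(0, 0, 50), c(0, 0, -1))
  expect_null(navigate(plane_cloud, sim_far$sensor2, sim_far$sensor3,
                       sim_far$ic))
  # frame tags still matter
  cam_cloud <- point_cloud(plane_cloud$points, "camera")
  expect_error(navigate(cam_cloud, sim$sensor2, sim$sensor3, sim$ic),
               "femur")
})
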