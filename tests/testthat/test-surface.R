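test_that("points snap to the nearest grid vertex, halves to the lower", {
  t <- 0.4
  g <- rearrange_points(point_cloud(matrix(c(0, 0, 0), 1, 3), "femur"), t)
  expect_equal(sum(g$occupancy), 1)
  expect_equal(sum(g$counts), 1)
  expect_equal(as.numeric(occupied_vertices(g)), c(0, 0, 0), tolerance = 1e-12)
  # a second point just under half an interval away shares the vertex;
  # just over half an interval claims the next vertex
  p2 <- rbind(c(0, 0, 0), rep(0.49 * t, 3))
  g2 <- rearrange_points(point_cloud(p2, "femur"), t)
  expect_equal(sum(g2$occupancy), 1)
  expect_equal(max(g2$counts), 2)
  p3 <- rbind(c(0, 0, 0), rep(0.51 * t, 3))
  g3 <- rearrange_points(point_cloud(p3, "femur"), t)
  expect_equal(sum(g3$occupancy), 2)
  expect_error(rearrange_points(point_cloud(p3, "femur"), 0), "positive")
  expect_error(rearrange_points(point_cloud(matrix(0, 0, 3), "femur"), t),
               "empty")
})

test_that("rearrangement conserves points and bounds the snap distance", {
  set.seed(31)
  t <- 0.3
  P <- matrix(stats::runif(3e4, -5, 5), 1e4, 3)
  g <- rearrange_points(point_cloud(P, "femur"), t)
  expect_equal(sum(g$counts), 1e4)
  expect_true(all(g$occupancy == (g$counts >= 1)))
  # every point's Linf distance to its snapped vertex
  snap <- function(x, o) o + t * ceiling((x - o) / t - 0.5)
  V <- sapply(1:3, function(a) snap(P[, a], g$origin[a]))
  expect_lt(max(abs(P - V)), t / 2 + 1e-12)
  # Hausdorff bound from the cloud to the occupied vertex set
  occ <- occupied_vertices(g)
  expect_lte(max(abs(P - V)), t / 2 + 1e-12)
  d_euc <- sqrt(rowSums((P - V)^2))
  expect_lt(max(d_euc), sqrt(3) / 2 * t + 1e-12)
  expect_equal(nrow(occ), sum(g$occupancy))
})

test_that("an isolated occupied vertex meshes into a closed octahedron", {
  g <- rearrange_points(point_cloud(matrix(c(1, 2, 3), 1, 3), "femur"), 0.5)
  m <- extract_surface(g)
  expect_equal(nrow(m$vertices), 6)
  expect_equal(nrow(m$faces), 8)
  ed <- rbind(m$faces[, 1:2], m$faces[, 2:3], m$faces[, c(3, 1)])
  ed <- unique(t(apply(ed, 1, sort)))
  expect_equal(nrow(m$vertices) - nrow(ed) + nrow(m$faces), 2)  # Euler
  # normals point away from the occupied vertex
  ctr <- c(1, 2, 3)
  a <- m$vertices[m$faces[, 2], ] - m$vertices[m$faces[, 1], ]
  b <- m$vertices[m$faces[, 3], ] - m$vertices[m$faces[, 1], ]
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  fc <- (m$vertices[m$faces[, 1], ] + m$vertices[m$faces[, 2], ] +
         m$vertices[m$faces[, 3], ]) / 3
  expect_true(all(rowSums(nrm * sweep(fc, 2, ctr)) > 0))
})

test_that("every cube case produces watertight, consistently linked patches", {
  tab <- stereonav:::.mc_table()
  expect_length(tab, 256)
  expect_equal(lengths(tab)[c(1, 256)], c(0L, 0L), ignore_attr = TRUE)
  geo <- stereonav:::.mc_env$geo
  for (byte in 0:255) {
    occ <- as.integer(bitwAnd(bitwShiftR(byte, 0:7), 1L))
    cut <- sum(occ[geo$edges[, 1]] != occ[geo$edges[, 2]])
    tris <- tab[[byte + 1]]
    if (cut == 0) {
      expect_length(tris, 0)
    } else {
      # within one cube, every boundary edge of the patch appears exactly
      # once per winding direction (the patch is bounded by face crossings)
      used <- unique(unlist(tris))
      expect_equal(sort(used), sort(which(occ[geo$edges[, 1]] != occ[geo$edges[, 2]])))
    }
  }
})

test_that("a dense plane sample meshes within half an interval of the plane", {
  set.seed(37)
  t <- 0.3
  c0 <- 12.5
  P <- cbind(stats::runif(4000, 0, 6), stats::runif(4000, 0, 6), c0)
  g <- rearrange_points(point_cloud(P, "femur"), t)
  m <- extract_surface(g)
  expect_gt(nrow(m$faces), 0)
  expect_lt(max(abs(m$vertices[, 3] - c0)), t / 2 + 1e-9)
  # empty grid meshes to nothing
  g0 <- rearrange_points(point_cloud(matrix(c(0, 0, 0), 1, 3), "femur"), t)
  g0$occupancy[] <- FALSE
  expect_equal(nrow(extract_surface(g0)$faces), 0)
})

test_that("plane fitting recovers exact and noisy planes", {
  set.seed(41)
  P <- cbind(stats::runif(500, 0, 30), stats::runif(500, 0, 30), 0)
  tilt <- rotation_about_axis(c(1, 2, 0), 0.3)
  Pt <- P %*% t(tilt)
  fit <- fit_plane(Pt)
  expect_lt(fit$rmse_mm, 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(abs(sum(fit$normal * tilt[, 3])), 1, tolerance = 1e-9)
  # depth noise recovery at the magnitude typical of speckle stereo
  sigma <- 0.135
  Pn <- cbind(stats::runif(1e5, 0, 36), stats::runif(1e5, 0, 27),
              stats::rnorm(1e5, 0, sigma))
  fitn <- fit_plane(Pn)
  expect_equal(fitn$rmse_mm, sigma, tolerance = 0.005 / sigma)
  expect_error(fit_plane(cbind(1:5, 2 * (1:5), 3 * (1:5))), "collinear")
  expect_error(fit_plane(matrix(0, 2, 3)), "at least 3")
})

test_that("sphere fitting recovers exact and noisy spheres", {
  set.seed(43)
  shell <- sample_surface(surface_sphere(c(1, -2, 50), 40.09 / 2), 4000,
                          region = list(center = c(1, -2, 29), radius = 15),
                          seed = 5)
  fit <- fit_sphere(shell$cloud)
  expect_equal(fit$diameter_mm, 40.09, tolerance = 1e-6 / 40.09)
  expect_lt(fit$rmse_mm, 1e-9)
  expect_equal(fit$center, c(1, -2, 50), tolerance = 1e-6)
  # radial noise on full-sphere coverage: diameter within 3 sigma / sqrt(n)
  sigma <- 0.2; n <- 5000
  dirs <- matrix(stats::rnorm(3 * n), n, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  noisy <- sweep(dirs * (40.09 / 2 + stats::rnorm(n, 0, sigma)), 2,
                 c(1, -2, 50), "+")
  fitn <- fit_sphere(noisy)
  expect_lt(abs(fitn$diameter_mm - 40.09), 3 * sigma / sqrt(n))
  expect_equal(fitn$rmse_mm, sigma, tolerance = 0.1)
  # coplanar circle is degenerate
  th <- seq(0, 2 * pi, length.out = 100)
  expect_error(fit_sphere(cbind(cos(th), sin(th), 0)), "coplanar")
})

test_that("clouds and meshes round-trip through ASCII PLY", {
  tdir <- withr::local_tempdir()
  set.seed(47)
  P <- matrix(stats::rnorm(60), 20, 3)
  f1 <- file.path(tdir, "cloud.ply")
  write_ply(point_cloud(P, "femur"), f1)
  expect_equal(read_ply(f1), P, tolerance = 1e-5, ignore_attr = TRUE)
  g <- rearrange_points(point_cloud(matrix(c(0, 0, 0), 1, 3), "femur"), 0.5)
  m <- extract_surface(g)
  f2 <- file.path(tdir, "mesh.ply")
  write_ply(m, f2)
  back <- read_ply(f2)
  expect_equal(back$vertices, m$vertices, tolerance = 1e-5, ignore_attr = TRUE)
  expect_identical(back$faces, m$faces)
})
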