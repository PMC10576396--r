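test_that("distortion inverts to the ideal pinhole projection", {
  cam <- camera_model(300, 300, 159.5, 119.5, 320, 240,
                      k1 = -0.08, k2 = 0.01, p1 = 5e-4, p2 = -5e-4)
  set.seed(1)
  P <- cbind(stats::runif(1000, -15, 15), stats::runif(1000, -12, 12),
             stats::runif(1000, 35, 45))
  uv <- project_points(cam, P)
  xy <- undistort_points(cam, uv)
  ideal_px <- cbind(cam$fx * P[, 1] / P[, 3] + cam$cx,
                    cam$fy * P[, 2] / P[, 3] + cam$cy)
  undist_px <- cbind(cam$fx * xy[, 1] + cam$cx, cam$fy * xy[, 2] + cam$cy)
  expect_lt(max(abs(undist_px - ideal_px)), 0.05)
})

test_that("rectification aligns corresponding rows", {
  # a mildly converging rig: small rotation and vertical offset
  caml <- camera_model(310, 305, 160, 122, 320, 240, k1 = -0.05, k2 = 0.005)
  camr <- camera_model(298, 301, 158, 118, 320, 240, k1 = -0.06, k2 = 0.004)
  rig <- stereo_rig(caml, camr, rotation_about_axis(c(0, 1, 0), 0.01),
                    c(-4, 0.1, -0.05))
  geo <- rectify_rig(rig)
  expect_true(geo$rig$rectified)
  expect_gt(geo$rig$baseline_mm, 0)
  C2 <- as.numeric(-t(rig$rotation) %*% rig$translation_mm)
  set.seed(2)
  P <- cbind(stats::runif(1000, -10, 10), stats::runif(1000, -8, 8),
             stats::runif(1000, 35, 45))
  uvl <- project_points(geo$rig$left, P %*% t(geo$R_left))
  uvr <- project_points(geo$rig$right,
                        sweep(P, 2, C2) %*% t(rig$rotation) %*% t(geo$R_right))
  expect_lt(max(abs(uvl[, 2] - uvr[, 2])), 0.1)
})

test_that("an already-parallel distortion-free rig rectifies to itself", {
  rig <- stereo_rig(camera_model(300, 300, 31.5, 23.5, 64, 48),
                    camera_model(300, 300, 31.5, 23.5, 64, 48),
                    diag(3), c(-4, 0, 0))
  set.seed(3)
  img <- list(left = matrix(stats::runif(48 * 64, 0, 255), 48, 64),
              right = matrix(stats::runif(48 * 64, 0, 255), 48, 64))
  out <- undistort_rectify(img, rig)
  expect_equal(out$left, img$left, tolerance = 1e-9)
  expect_equal(out$right, img$right, tolerance = 1e-9)
  expect_equal(out$rig$baseline_mm, 4, tolerance = 1e-12)
  bad <- list(left = img$left[1:40, ], right = img$right)
  expect_error(undistort_rectify(bad, rig), "declares")
})

test_that("triangulation follows Z = f B / d and drops invalid pixels", {
  rig <- stereo_rig(camera_model(700, 700, 63.5, 47.5, 128, 96),
                    camera_model(700, 700, 63.5, 47.5, 128, 96),
                    diag(3), c(-4, 0, 0))
  rig$rectified <- TRUE
  d <- disparity_map(matrix(70, 96, 128), matrix(TRUE, 96, 128))
  cl <- triangulate_disparity(d, rig)
  expect_equal(unique(round(cl$points[, 3], 9)), 40)
  expect_identical(cl$frame, "camera")
  # invalid everywhere: empty cloud
  d2 <- disparity_map(matrix(70, 96, 128), matrix(FALSE, 96, 128))
  expect_equal(nrow(triangulate_disparity(d2, rig)$points), 0)
  # unrectified rigs are refused
  rig$rectified <- FALSE
  expect_error(triangulate_disparity(d, rig), "rectified")
})

test_that("matching a shifted random-dot stereogram recovers the shift", {
  rds <- make_rds(80, 120, shift = 7, seed = 4)
  d <- sgm_disparity(rds, sgm_params(d_min = 0, d_max = 15))
  expect_gt(mean(d$valid), 0.5)
  err <- abs(d$disparity - 7)
  expect_gt(mean(err[d$valid] <= 0.5), 0.99)
})

test_that("featureless images are rejected by the ambiguity check", {
  u <- matrix(100, 60, 90)
  d <- sgm_disparity(list(left = u, right = u),
                     sgm_params(d_min = 0, d_max = 12))
  expect_gt(mean(!d$valid), 0.9)
})

test_that("a two-plane stereogram yields two disparity plateaus", {
  h <- 80; w <- 140; k1 <- 4; k2 <- 10
  set.seed(5)
  base <- matrix(ifelse(stats::runif(h * (w + k2)) < 0.25, 230, 20), h, w + k2)
  left <- base[, 1:w]
  right <- left * 0
  # left half of the scene at shift k1, right half at k2
  right[, ] <- base[, (k1 + 1):(w + k1)]
  right[, 1:(w / 2)] <- base[, (k2 + 1):(w / 2 + k2)]
  # note: left pixel x in columns > w/2 matches right x - k1; in the left
  # half the true shift is k2
  d <- sgm_disparity(list(left = left, right = right),
                     sgm_params(d_min = 0, d_max = 15))
  left_half <- d$disparity[, 16:(w / 2 - 15)][d$valid[, 16:(w / 2 - 15)]]
  right_half <- d$disparity[, (w / 2 + 16):(w - 15)][d$valid[, (w / 2 + 16):(w - 15)]]
  expect_lt(abs(stats::median(left_half) - k2), 0.5)
  expect_lt(abs(stats::median(right_half) - k1), 0.5)
})

test_that("disparity search ranges wider than the image are refused", {
  img <- matrix(0, 20, 30)
  expect_error(sgm_disparity(list(left = img, right = img),
                             sgm_params(d_min = 0, d_max = 30)), "width")
  expect_error(sgm_params(d_min = 5, d_max = 5))
  expect_error(sgm_params(d_min = -1, d_max = 5))
})

test_that("disparity maps round-trip through fixed-point PNG", {
  set.seed(6)
  disp <- matrix(stats::runif(300, 0, 60), 15, 20)
  valid <- matrix(stats::runif(300) > 0.3, 15, 20)
  d <- disparity_map(disp, valid)
  stem <- file.path(withr::local_tempdir(), "d")
  write_disparity_png(d, stem)
  back <- read_disparity_png(stem)
  expect_identical(back$valid, valid)
  expect_lt(max(abs(back$disparity[valid] - disp[valid])), 1 / 16)
})
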