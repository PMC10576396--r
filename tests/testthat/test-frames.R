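test_that("compose and invert satisfy the rigid-group axioms", {
  set.seed(41)
  id_ct <- identity_transform("camera", "transmitter")
  X <- random_rigid("camera", "transmitter")
  # identity composition
  XI <- compose_transforms(X, identity_transform("camera"))
  expect_equal(XI$rotation, X$rotation, tolerance = 1e-12)
  expect_equal(XI$translation, X$translation, tolerance = 1e-12)
  # inverse composition gives the identity
  XiX <- compose_transforms(X, invert_transform(X))
  expect_lt(max(abs(XiX$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(XiX$translation)), 1e-9)
  # involution
  Xii <- invert_transform(invert_transform(X))
  expect_equal(Xii$rotation, X$rotation, tolerance = 1e-12)
  expect_equal(Xii$translation, X$translation, tolerance = 1e-12)
  # sequential-application oracle over random pairs
  for (i in 1:100) {
    a <- random_rigid("transmitter", "femur")
    b <- random_rigid("camera", "transmitter")
    p <- stats::rnorm(3, 0, 50)
    via_compose <- apply_transform(compose_transforms(a, b), p)
    sequential <- apply_transform(a, apply_transform(b, p))
    expect_lt(max(abs(via_compose - sequential)), 1e-9)
  }
  # round-trip points through invert
  for (i in 1:10) {
    X <- random_rigid("camera", "transmitter")
    p <- matrix(stats::rnorm(300, 0, 100), 100, 3)
    back <- apply_transform(invert_transform(X), apply_transform(X, p))
    expect_lt(max(abs(back - p)), 1e-9)
  }
})

test_that("frame bookkeeping rejects broken chains and bad rotations", {
  a <- identity_transform("camera", "transmitter")
  b <- identity_transform("sensor2", "transmitter")
  expect_error(compose_transforms(b, a), "frame chain")
  expect_error(rigid_transform(matrix(1, 3, 3), c(0, 0, 0),
                               "camera", "sensor1"), "orthonormal")
  # reflections are not rotations
  expect_error(rigid_transform(diag(c(1, 1, -1)), c(0, 0, 0),
                               "camera", "sensor1"), "determinant")
  expect_error(rigid_transform(diag(3), c(0, 0, 0), "elbow", "sensor1"),
               "unknown frame")
  cl <- point_cloud(matrix(0, 1, 3), "transmitter")
  expect_error(transform_cloud(identity_transform("camera", "sensor1"), cl),
               "frame mismatch")
})

test_that("quaternions convert to rotations and back", {
  set.seed(7)
  for (i in 1:50) {
    R <- random_rotation()
    q <- rotmat_to_quat(R)
    expect_equal(quat_to_rotmat(q), R, tolerance = 1e-9)
  }
  # near-unit quaternions are renormalised, others rejected
  q <- c(1, 0, 0, 0) * (1 + 1e-8)
  expect_equal(quat_to_rotmat(q), diag(3), tolerance = 1e-7)
  expect_error(quat_to_rotmat(c(2, 0, 0, 0)), "norm")
})

test_that("camera-to-transmitter chain matches the per-point arithmetic", {
  # all identities: cloud unchanged
  cl <- point_cloud(matrix(stats::rnorm(30), 10, 3), "camera")
  out <- camera_to_transmitter(cl, identity_transform("sensor1", "transmitter"),
                               hand_eye_calibration())
  expect_equal(out$points, cl$points, tolerance = 1e-12)
  expect_identical(out$frame, "transmitter")
  # origin with identity rotations lands at d_s1 + P_ts1
  he <- hand_eye_calibration(diag(3), c(1, 2, 3))
  s1 <- rigid_transform(diag(3), c(10, 20, 30), "sensor1", "transmitter")
  out <- camera_to_transmitter(point_cloud(matrix(0, 1, 3), "camera"), s1, he)
  expect_equal(as.numeric(out$points), c(11, 22, 33), tolerance = 1e-12)
  # random configuration against an independent per-point oracle
  set.seed(11)
  for (i in 1:5) {
    he <- hand_eye_calibration(random_rotation(), stats::rnorm(3))
    s1 <- random_rigid("sensor1", "transmitter")
    P <- matrix(stats::rnorm(300, 0, 40), 100, 3)
    got <- camera_to_transmitter(point_cloud(P, "camera"), s1, he)$points
    want <- t(apply(P, 1, function(p) {
      s1$rotation %*% (he$offset_mm + he$rotation %*% p) + s1$translation
    }))
    expect_lt(max(abs(got - want)), 1e-9)
  }
})

test_that("femur frame is reached by a round-trippable chain", {
  set.seed(13)
  he <- hand_eye_calibration(random_rotation(), stats::rnorm(3))
  s1 <- random_rigid("sensor1", "transmitter")
  s3 <- random_rigid("sensor3", "transmitter")
  cl <- point_cloud(matrix(stats::rnorm(60, 0, 30), 20, 3), "camera")
  # sensor3 identity: femur result equals the transmitter result
  fem0 <- camera_to_femur(cl, s1, identity_transform("sensor3", "transmitter"), he)
  trans <- camera_to_transmitter(cl, s1, he)
  expect_equal(fem0$points, trans$points, tolerance = 1e-12)
  # push a femur-native cloud out to the camera and back
  fem_native <- matrix(stats::rnorm(60, 0, 30), 20, 3)
  cam_to_s1 <- rigid_transform(he$rotation, he$offset_mm, "camera", "sensor1")
  fwd <- compose_transforms(invert_transform(s3),
                            compose_transforms(s1, cam_to_s1))
  cam_pts <- apply_transform(invert_transform(fwd), fem_native)
  back <- camera_to_femur(point_cloud(cam_pts, "camera"), s1, s3, he)
  expect_lt(max(abs(back$points - fem_native)), 1e-9)
})

test_that("femur coordinates survive transmitter knocks and specimen motion", {
  set.seed(17)
  he <- hand_eye_calibration(random_rotation(), stats::rnorm(3))
  s1 <- random_rigid("sensor1", "transmitter")
  s3 <- random_rigid("sensor3", "transmitter")
  cl <- point_cloud(matrix(stats::rnorm(90, 0, 25), 30, 3), "camera")
  ref <- camera_to_femur(cl, s1, s3, he)$points
  for (i in 1:20) {
    # a knocked transmitter re-expresses every tracked pose through the same
    # transmitter-frame motion M; the femur-frame cloud must not move
    M <- random_rigid("transmitter", "transmitter")
    s1_k <- compose_transforms(M, s1)
    s3_k <- compose_transforms(M, s3)
    got <- camera_to_femur(cl, s1_k, s3_k, he)$points
    expect_lt(max(abs(got - ref)), 1e-9)
  }
})

test_that("the instrument segment maps rigidly into the femur frame", {
  ic <- instrument_calibration(c(0, 0, 0), c(0, 0, 10))
  seg <- instrument_axis_in_femur(identity_transform("sensor2", "transmitter"),
                                  identity_transform("sensor3", "transmitter"),
                                  ic)
  expect_equal(seg$tip, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(seg$butt, c(0, 0, 10), tolerance = 1e-12)
  # rigid chains preserve the calibrated length
  set.seed(19)
  for (i in 1:50) {
    ic <- instrument_calibration(stats::rnorm(3), stats::rnorm(3, 0, 40))
    seg <- instrument_axis_in_femur(random_rigid("sensor2", "transmitter"),
                                    random_rigid("sensor3", "transmitter"), ic)
    expect_equal(sqrt(sum((seg$butt - seg$tip)^2)),
                 sqrt(sum(ic$axis_mm^2)), tolerance = 1e-9)
  }
  # sensor2 == sensor3: the calibrated tip is already in femur coordinates
  s <- random_rigid("sensor2", "transmitter")
  s3 <- rigid_transform(s$rotation, s$translation, "sensor3", "transmitter")
  ic <- instrument_calibration(c(3, -4, 5), c(0, 0, 10))
  seg <- instrument_axis_in_femur(s, s3, ic)
  expect_equal(seg$tip, c(3, -4, 5), tolerance = 1e-9)
  expect_error(instrument_calibration(c(0, 0, 0), c(0, 0, 0)), "positive length")
})

test_that("every frame mapping is an isometry on point clouds", {
  set.seed(23)
  he <- hand_eye_calibration(random_rotation(), stats::rnorm(3))
  s1 <- random_rigid("sensor1", "transmitter")
  s3 <- random_rigid("sensor3", "transmitter")
  P <- matrix(stats::rnorm(45, 0, 20), 15, 3)
  dist0 <- as.matrix(stats::dist(P))
  fem <- camera_to_femur(point_cloud(P, "camera"), s1, s3, he)$points
  expect_lt(max(abs(as.matrix(stats::dist(fem)) - dist0)), 1e-9)
})

test_that("pose streams and calibrations round-trip through their files", {
  set.seed(29)
  tdir <- withr::local_tempdir()
  poses <- lapply(c("sensor1", "sensor2", "sensor3"),
                  function(id) random_rigid(id, "transmitter"))
  stream <- do.call(rbind, Map(transform_to_pose_row, poses,
                               time_s = c(0, 0.1, 0.2)))
  f <- file.path(tdir, "poses.csv")
  write_pose_stream(stream, f)
  back <- read_pose_stream(f)
  for (i in 1:3) {
    tr <- pose_row_to_transform(back[i, ])
    expect_equal(tr$rotation, poses[[i]]$rotation, tolerance = 1e-6)
    expect_equal(tr$translation, poses[[i]]$translation, tolerance = 1e-6)
  }
  he <- hand_eye_calibration(random_rotation(), c(1.5, -2, 0.25))
  ic <- instrument_calibration(c(1, 2, 3), c(0, 0, 80))
  cf <- file.path(tdir, "calib.json")
  write_calibration(he, ic, cf)
  got <- read_calibration(cf)
  expect_equal(got$hand_eye$rotation, he$rotation, tolerance = 1e-9)
  expect_equal(got$hand_eye$offset_mm, he$offset_mm, tolerance = 1e-12)
  expect_equal(got$instrument$tip_mm, ic$tip_mm, tolerance = 1e-12)
})
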