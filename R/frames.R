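#' @useDynLib stereonav, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Frame identifiers used throughout the pipeline.  The femur frame is the
# patient tracking frame and is physically realised by sensor-3, so the two
# ids are interchangeable when chaining transforms.
FRAME_IDS <- c("camera", "sensor1", "sensor2", "sensor3", "transmitter", "femur")

.frames_equivalent <- function(a, b) {
  eq <- function(f) if (f %in% c("sensor3", "femur")) "femur" else f
  eq(a) == eq(b)
}

.check_frame_id <- function(frame) {
  if (!(is.character(frame) && length(frame) == 1L && frame %in% FRAME_IDS)) {
    stop("unknown frame id: ", paste(frame, collapse = ","), call. = FALSE)
  }
  frame
}

#' Rigid-body transform between two named coordinate frames
#'
#' A rotation plus translation mapping points expressed in `from_frame` into
#' `to_frame` (`p_to = R %*% p_from + t`).  Every tracked EM pose is stored in
#' the sensor-to-transmitter direction; transmitter-to-sensor maps are always
#' derived with [invert_transform()], never stored.
#'
#' @param rotation 3x3 orthonormal rotation matrix (det +1), or a unit
#'   quaternion of length 4 in `(qw, qx, qy, qz)` order.  Quaternions whose
#'   norm deviates from 1 by less than 1e-6 are renormalised; larger
#'   deviations are rejected.
#' @param translation numeric length-3 translation in millimetres.
#' @param from_frame,to_frame frame ids, one of
#'   `camera, sensor1, sensor2, sensor3, transmitter, femur`.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            from_frame, to_frame) {
  if (is.numeric(rotation) && length(rotation) == 4L) {
    rotation <- quat_to_rotmat(rotation)
  }
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) {
    stop("rotation must be a 3x3 matrix or a length-4 quaternion", call. = FALSE)
  }
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-9) stop("rotation is not orthonormal (max |R'R - I| = ",
                       format(err), ")", call. = FALSE)
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must have determinant +1 (proper rotation)", call. = FALSE)
  }
  translation <- as.numeric(translation)
  if (length(translation) != 3L || !all(is.finite(translation))) {
    stop("translation must be a finite 3-vector (mm)", call. = FALSE)
  }
  structure(
    list(rotation = rotation, translation = translation,
         from_frame = .check_frame_id(from_frame),
         to_frame = .check_frame_id(to_frame)),
    class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform %s -> %s>\n", x$from_frame, x$to_frame))
  cat("rotation:\n"); print(round(x$rotation, 6))
  cat("translation (mm):", round(x$translation, 6), "\n")
  invisible(x)
}

#' Convert a unit quaternion to a rotation matrix
#'
#' @param q numeric length 4, `(qw, qx, qy, qz)`.
#' @return 3x3 rotation matrix.
#' @export
quat_to_rotmat <- function(q) {
  q <- as.numeric(q)
  if (length(q) != 4L) stop("quaternion must have length 4 (qw, qx, qy, qz)")
  n <- sqrt(sum(q^2))
  if (abs(n - 1) >= 1e-6) {
    stop("quaternion norm deviates from 1 by ", format(abs(n - 1)),
         "; refusing to normalise", call. = FALSE)
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

#' Convert a rotation matrix to a unit quaternion
#'
#' Returns the quaternion with non-negative scalar part.
#' @param R 3x3 rotation matrix.
#' @return numeric length 4, `(qw, qx, qy, qz)`.
#' @export
rotmat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

#' Rotation about an arbitrary axis
#'
#' Rodrigues form; convenience constructor used by the simulator and tests.
#' @param axis 3-vector rotation axis (normalised internally).
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  a <- as.numeric(axis)
  n <- sqrt(sum(a^2))
  if (n == 0) stop("rotation axis must be non-zero")
  a <- a / n
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` applies `b` first, then `a`; the frame chain
#' must connect (`a$from_frame == b$to_frame`).
#'
#' @param a,b `rigid_transform` objects.
#' @return `rigid_transform` from `b$from_frame` to `a$to_frame`.
#' @export
compose_transforms <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  if (!.frames_equivalent(a$from_frame, b$to_frame)) {
    stop(sprintf("frame chain broken: cannot compose [%s -> %s] after [%s -> %s]",
                 a$from_frame, a$to_frame, b$from_frame, b$to_frame),
         call. = FALSE)
  }
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation,
                  from_frame = b$from_frame, to_frame = a$to_frame)
}

#' Invert a rigid transform
#'
#' Uses the closed form for rigid motions: the inverse rotation is the
#' transpose and the inverse translation is `-R' t`.  Frames are swapped.
#'
#' @param t a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  Rt <- t(t$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% t$translation),
                  from_frame = t$to_frame, to_frame = t$from_frame)
}

#' Identity transform between two frames
#' @param from_frame,to_frame frame ids.
#' @return `rigid_transform`.
#' @export
identity_transform <- function(from_frame, to_frame = from_frame) {
  rigid_transform(diag(3), c(0, 0, 0), from_frame, to_frame)
}

#' Point cloud tagged with its coordinate frame
#'
#' @param points n x 3 numeric matrix of coordinates in millimetres.
#' @param frame frame id the coordinates are expressed in.
#' @return object of class `point_cloud`.
#' @export
point_cloud <- function(points, frame) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  if (nrow(points) > 0 && !all(is.finite(points))) {
    stop("point cloud contains non-finite coordinates")
  }
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  structure(list(points = points, frame = .check_frame_id(frame)),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud: %d points in frame '%s'>\n",
              nrow(x$points), x$frame))
  invisible(x)
}

#' Apply a rigid transform to a point cloud
#'
#' Frame tags are checked: the cloud must be expressed in the transform's
#' source frame.  Silent frame coercion is deliberately impossible.
#'
#' @param t `rigid_transform`.
#' @param cloud `point_cloud` expressed in `t$from_frame`.
#' @return transformed `point_cloud` in `t$to_frame`.
#' @export
transform_cloud <- function(t, cloud) {
  stopifnot(inherits(t, "rigid_transform"), inherits(cloud, "point_cloud"))
  if (!.frames_equivalent(cloud$frame, t$from_frame)) {
    stop(sprintf("frame mismatch: cloud is in '%s' but transform maps '%s' -> '%s'",
                 cloud$frame, t$from_frame, t$to_frame), call. = FALSE)
  }
  point_cloud(apply_transform(t, cloud$points), t$to_frame)
}

#' Apply a rigid transform to bare coordinates
#' @param t `rigid_transform`.
#' @param p a 3-vector or n x 3 matrix.
#' @return object of the same shape as `p`.
#' @export
apply_transform <- function(t, p) {
  if (is.null(dim(p))) {
    as.numeric(t$rotation %*% p) + t$translation
  } else {
    sweep(p %*% t(t$rotation), 2, t$translation, "+")
  }
}

#' Hand-eye calibration between the endoscope camera and sensor-1
#'
#' The fixed rigid relation between the left camera and the EM sensor mounted
#' in the endoscope tip.  `offset_mm` is the camera origin expressed in the
#' sensor-1 frame: camera points are first rotated into the sensor-1
#' orientation and offset, then carried to the transmitter by the tracked
#' sensor-1 pose.
#'
#' @param rotation 3x3 rotation (camera axes in sensor-1 axes) or quaternion.
#' @param offset_mm 3-vector, camera origin in the sensor-1 frame (mm).
#' @return object of class `hand_eye_calibration`.
#' @export
hand_eye_calibration <- function(rotation = diag(3), offset_mm = c(0, 0, 0)) {
  t <- rigid_transform(rotation, offset_mm, "camera", "sensor1")
  structure(list(rotation = t$rotation, offset_mm = t$translation),
            class = "hand_eye_calibration")
}

#' Instrument (bone harvester) calibration in the sensor-2 frame
#'
#' @param tip_mm 3-vector, position of the harvester tip T in sensor-2
#'   coordinates (mm), measured beforehand.
#' @param axis_mm 3-vector from the tip T to the butt B in sensor-2
#'   coordinates (mm); its norm is the instrument segment length and must be
#'   positive.
#' @return object of class `instrument_calibration`.
#' @export
instrument_calibration <- function(tip_mm, axis_mm) {
  tip_mm <- as.numeric(tip_mm); axis_mm <- as.numeric(axis_mm)
  stopifnot(length(tip_mm) == 3L, length(axis_mm) == 3L,
            all(is.finite(tip_mm)), all(is.finite(axis_mm)))
  if (sqrt(sum(axis_mm^2)) <= 0) stop("instrument axis must have positive length")
  structure(list(tip_mm = tip_mm, axis_mm = axis_mm),
            class = "instrument_calibration")
}

#' Transform a camera-frame cloud into the transmitter frame
#'
#' Chains the hand-eye calibration with the tracked sensor-1 pose:
#' each point `p` maps to `R_s1t (d_s1 + R_cs1 p) + P_ts1`.
#'
#' @param cloud `point_cloud` in the camera frame.
#' @param sensor1 `rigid_transform` sensor1 -> transmitter (tracked pose).
#' @param he `hand_eye_calibration`.
#' @return `point_cloud` in the transmitter frame.
#' @export
camera_to_transmitter <- function(cloud, sensor1, he) {
  stopifnot(inherits(he, "hand_eye_calibration"))
  if (!.frames_equivalent(cloud$frame, "camera")) {
    stop("cloud must be expressed in the camera frame, got '", cloud$frame, "'")
  }
  if (!(.frames_equivalent(sensor1$from_frame, "sensor1") &&
        .frames_equivalent(sensor1$to_frame, "transmitter"))) {
    stop("sensor1 must be a sensor1 -> transmitter pose")
  }
  cam_to_s1 <- rigid_transform(he$rotation, he$offset_mm, "camera", "sensor1")
  transform_cloud(compose_transforms(sensor1, cam_to_s1), cloud)
}

#' Transform a camera-frame cloud into the patient (femur) frame
#'
#' The femur frame is the sensor-3 frame, rigidly attached to the bone.  The
#' transmitter acts only as an intermediary: the cloud is carried camera ->
#' sensor1 -> transmitter -> sensor3.  Because both tracked poses are
#' referenced to the transmitter, any common motion of the transmitter (or of
#' the whole specimen with its sensors) cancels and the femur-frame
#' coordinates are unchanged.
#'
#' @param cloud `point_cloud` in the camera frame.
#' @param sensor1 `rigid_transform` sensor1 -> transmitter.
#' @param sensor3 `rigid_transform` sensor3 -> transmitter, sampled at the
#'   same instant as `sensor1`.
#' @param he `hand_eye_calibration`.
#' @return `point_cloud` in the femur frame.
#' @export
camera_to_femur <- function(cloud, sensor1, sensor3, he) {
  if (!(.frames_equivalent(sensor3$from_frame, "femur") &&
        .frames_equivalent(sensor3$to_frame, "transmitter"))) {
    stop("sensor3 must be a sensor3 -> transmitter pose")
  }
  in_t <- camera_to_transmitter(cloud, sensor1, he)
  out <- transform_cloud(invert_transform(sensor3), in_t)
  out$frame <- "femur"
  out
}

#' Instrument tip and butt in the femur frame
#'
#' Maps the calibrated tip point and tip-to-butt displacement through the
#' tracked sensor-2 pose and down into the sensor-3 (femur) frame.  The chain
#' is rigid, so the returned segment has exactly the calibrated length.
#'
#' @param sensor2 `rigid_transform` sensor2 -> transmitter.
#' @param sensor3 `rigid_transform` sensor3 -> transmitter.
#' @param ic `instrument_calibration`.
#' @return list with `tip` and `butt`, 3-vectors in femur coordinates (mm).
#' @export
instrument_axis_in_femur <- function(sensor2, sensor3, ic) {
  stopifnot(inherits(ic, "instrument_calibration"))
  if (!(.frames_equivalent(sensor2$from_frame, "sensor2") &&
        .frames_equivalent(sensor2$to_frame, "transmitter"))) {
    stop("sensor2 must be a sensor2 -> transmitter pose")
  }
  if (!(.frames_equivalent(sensor3$from_frame, "femur") &&
        .frames_equivalent(sensor3$to_frame, "transmitter"))) {
    stop("sensor3 must be a sensor3 -> transmitter pose")
  }
  chain <- compose_transforms(invert_transform(sensor3), sensor2)
  list(tip = apply_transform(chain, ic$tip_mm),
       butt = apply_transform(chain, ic$tip_mm + ic$axis_mm))
}
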