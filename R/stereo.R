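# Pinhole camera model with Brown radial/tangential distortion, stereo rig
# rectification, and disparity-to-depth triangulation.
#
# Conventions: images are numeric matrices (rows = image y, cols = image x,
# 8-bit scale 0..255); pixel coordinates are 0-based at pixel centres, so
# matrix element [r, c] sits at (u, v) = (c - 1, r - 1).  Camera frames are
# right-handed with +z along the optical axis.

#' Pinhole camera with radial and tangential distortion
#'
#' @param fx,fy focal lengths in pixels (> 0).
#' @param cx,cy principal point in pixels (inside the image).
#' @param width,height image size in pixels.
#' @param k1,k2 radial distortion coefficients.
#' @param p1,p2 tangential distortion coefficients.
#' @return object of class `camera_model`.
#' @export
camera_model <- function(fx, fy, cx, cy, width, height,
                         k1 = 0, k2 = 0, p1 = 0, p2 = 0) {
  stopifnot(fx > 0, fy > 0, cx >= 0, cx < width, cy >= 0, cy < height)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height),
                 k1 = k1, k2 = k2, p1 = p1, p2 = p2),
            class = "camera_model")
}

.has_distortion <- function(cam) {
  any(c(cam$k1, cam$k2, cam$p1, cam$p2) != 0)
}

#' Stereo rig of two pinhole cameras
#'
#' @param left,right `camera_model`s.
#' @param rotation 3x3 rotation of the right camera relative to the left:
#'   `p_right = R p_left + t`.
#' @param translation_mm 3-vector `t` of the same motion (mm).
#' @return object of class `stereo_rig` with a derived `baseline_mm`
#'   (distance between the optical centres, > 0).
#' @export
stereo_rig <- function(left, right, rotation = diag(3),
                       translation_mm = c(-4, 0, 0)) {
  stopifnot(inherits(left, "camera_model"), inherits(right, "camera_model"))
  rotation <- as.matrix(rotation)
  translation_mm <- as.numeric(translation_mm)
  baseline <- sqrt(sum((-t(rotation) %*% translation_mm)^2))
  if (baseline <= 0) stop("stereo baseline must be positive")
  structure(list(left = left, right = right, rotation = rotation,
                 translation_mm = translation_mm, baseline_mm = baseline,
                 rectified = FALSE, R_from_camera = diag(3)),
            class = "stereo_rig")
}

# Apply Brown distortion to normalized image coordinates (n x 2).
.distort_normalized <- function(cam, xy) {
  x <- xy[, 1]; y <- xy[, 2]
  r2 <- x^2 + y^2
  radial <- 1 + cam$k1 * r2 + cam$k2 * r2^2
  xd <- x * radial + 2 * cam$p1 * x * y + cam$p2 * (r2 + 2 * x^2)
  yd <- y * radial + cam$p1 * (r2 + 2 * y^2) + 2 * cam$p2 * x * y
  cbind(xd, yd)
}

#' Project camera-frame points to pixel coordinates
#'
#' Pinhole projection followed by the camera's distortion model.  Points with
#' non-positive depth yield NA.
#'
#' @param cam `camera_model`.
#' @param P n x 3 matrix of points in the camera frame (mm).
#' @return n x 2 matrix of (u, v) pixel coordinates (0-based centres).
#' @export
project_points <- function(cam, P) {
  P <- rbind(P)[, 1:3, drop = FALSE]
  z <- P[, 3]
  ok <- z > 0
  xy <- cbind(P[, 1] / z, P[, 2] / z)
  xy[!ok, ] <- NA_real_
  xyd <- .distort_normalized(cam, xy)
  cbind(cam$fx * xyd[, 1] + cam$cx, cam$fy * xyd[, 2] + cam$cy)
}

#' Undistort pixel coordinates to ideal pinhole pixels
#'
#' Inverts the distortion model by fixed-point iteration in normalized
#' coordinates (20 iterations, ample for endoscope-scale distortion).
#'
#' @param cam `camera_model`.
#' @param uv n x 2 matrix of observed (distorted) pixel coordinates.
#' @return n x 2 matrix of undistorted normalized coordinates.
#' @export
undistort_points <- function(cam, uv) {
  uv <- rbind(uv)
  xd <- (uv[, 1] - cam$cx) / cam$fx
  yd <- (uv[, 2] - cam$cy) / cam$fy
  x <- xd; y <- yd
  for (i in 1:20) {
    r2 <- x^2 + y^2
    radial <- 1 + cam$k1 * r2 + cam$k2 * r2^2
    dx <- 2 * cam$p1 * x * y + cam$p2 * (r2 + 2 * x^2)
    dy <- cam$p1 * (r2 + 2 * y^2) + 2 * cam$p2 * x * y
    x <- (xd - dx) / radial
    y <- (yd - dy) / radial
  }
  cbind(x, y)
}

#' Compute the rectifying geometry of a stereo rig
#'
#' Standard epipolar alignment of two pinhole cameras: the rectified x-axis
#' is taken along the baseline, the rectified frame is shared by both
#' cameras, and both virtual cameras get a common distortion-free intrinsic
#' matrix (averaged focal length and principal point).  The rigs used here
#' are nominally parallel, so the rectifying rotations are small.
#'
#' @param rig `stereo_rig`.
#' @return list with `rig` (rectified `stereo_rig`), `R_left`, `R_right`
#'   (rotations mapping original left/right camera coordinates into the
#'   rectified frame).
#' @export
rectify_rig <- function(rig) {
  # optical centre of the right camera in left-camera coordinates
  C2 <- as.numeric(-t(rig$rotation) %*% rig$translation_mm)
  B <- sqrt(sum(C2^2))
  r1 <- C2 / B
  zl <- c(0, 0, 1)
  r2 <- c(zl[2] * r1[3] - zl[3] * r1[2],
          zl[3] * r1[1] - zl[1] * r1[3],
          zl[1] * r1[2] - zl[2] * r1[1])
  r2 <- r2 / sqrt(sum(r2^2))
  r3 <- c(r1[2] * r2[3] - r1[3] * r2[2],
          r1[3] * r2[1] - r1[1] * r2[3],
          r1[1] * r2[2] - r1[2] * r2[1])
  Rrect <- rbind(r1, r2, r3)
  dimnames(Rrect) <- NULL

  f <- mean(c(rig$left$fx, rig$left$fy, rig$right$fx, rig$right$fy))
  cx <- mean(c(rig$left$cx, rig$right$cx))
  cy <- mean(c(rig$left$cy, rig$right$cy))
  mk <- function(w, h) camera_model(f, f, cx, cy, w, h)
  newrig <- stereo_rig(mk(rig$left$width, rig$left$height),
                       mk(rig$right$width, rig$right$height),
                       rotation = diag(3),
                       translation_mm = c(-B, 0, 0))
  newrig$rectified <- TRUE
  newrig$R_from_camera <- Rrect
  list(rig = newrig,
       R_left = Rrect,
       R_right = Rrect %*% t(rig$rotation))
}

# Vectorized bilinear sampling of img at 0-based pixel coords (u, v).
# Out-of-bounds samples return `fill`.
.bilinear_sample <- function(img, u, v, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  inb <- !is.na(u) & !is.na(v) & u >= 0 & u <= w - 1 & v >= 0 & v <= h - 1
  u[!inb] <- 0; v[!inb] <- 0
  # clamp the anchor to the penultimate pixel so the last row/column are
  # reached with an interpolation weight of exactly one
  u0 <- pmin(floor(u), w - 2); v0 <- pmin(floor(v), h - 2)
  du <- u - u0; dv <- v - v0
  u0c <- pmin(pmax(u0, 0), w - 2); v0c <- pmin(pmax(v0, 0), h - 2)
  i00 <- v0c + 1 + h * u0c          # [v0+1, u0+1] in column-major order
  val <- (1 - du) * (1 - dv) * img[i00] +
         du * (1 - dv) * img[i00 + h] +
         (1 - du) * dv * img[i00 + 1] +
         du * dv * img[i00 + h + 1]
  val[!inb] <- fill
  val
}

#' Undistort and rectify a stereo image pair
#'
#' Computes the rectified rig with [rectify_rig()] and remaps both images by
#' inverse warping with bilinear resampling: each rectified pixel is carried
#' back through the rectifying rotation and the original distortion model to
#' a source location in the raw image.
#'
#' @param pair list with `left` and `right` image matrices.
#' @param rig the raw `stereo_rig` the images were taken with.
#' @return list with `left`, `right` (rectified images), `rig` (rectified
#'   `stereo_rig`), `R_left`, `R_right`.
#' @export
undistort_rectify <- function(pair, rig) {
  for (side in c("left", "right")) {
    cam <- rig[[side]]
    img <- pair[[side]]
    if (nrow(img) != cam$height || ncol(img) != cam$width) {
      stop(sprintf("%s image is %dx%d but the rig declares %dx%d",
                   side, ncol(img), nrow(img), cam$width, cam$height))
    }
  }
  geo <- rectify_rig(rig)
  remap <- function(img, cam_src, cam_new, R_to_rect) {
    h <- cam_new$height; w <- cam_new$width
    uu <- rep(0:(w - 1), each = h)
    vv <- rep(0:(h - 1), times = w)
    d <- cbind((uu - cam_new$cx) / cam_new$fx,
               (vv - cam_new$cy) / cam_new$fy, 1)
    d_src <- d %*% R_to_rect      # rows: t(R) %*% d, back into source camera
    uvs <- project_points(cam_src, d_src)
    matrix(.bilinear_sample(img, uvs[, 1], uvs[, 2]), nrow = h)
  }
  list(left = remap(pair$left, rig$left, geo$rig$left, geo$R_left),
       right = remap(pair$right, rig$right, geo$rig$right, geo$R_right),
       rig = geo$rig, R_left = geo$R_left, R_right = geo$R_right)
}

#' Per-pixel disparity map with validity mask
#'
#' @param disparity numeric matrix of subpixel disparities (pixels).
#' @param valid logical matrix of the same size; invalid pixels are excluded
#'   from all downstream statistics (no sentinel values are used).
#' @param d_range optional numeric length 2, the search range used.
#' @return object of class `disparity_map`.
#' @export
disparity_map <- function(disparity, valid, d_range = NULL) {
  stopifnot(is.matrix(disparity), all(dim(valid) == dim(disparity)))
  structure(list(disparity = disparity, valid = valid,
                 width = ncol(disparity), height = nrow(disparity),
                 d_range = d_range),
            class = "disparity_map")
}

#' @export
print.disparity_map <- function(x, ...) {
  cat(sprintf("<disparity_map %dx%d, %.1f%% valid>\n", x$width, x$height,
              100 * mean(x$valid)))
  invisible(x)
}

#' Triangulate a disparity map into a camera-frame point cloud
#'
#' For a rectified rig, depth along the rectified axis is `Z = f B / d`.
#' Only valid pixels with disparity above `eps` survive; points are rotated
#' back from the rectified frame into the original left-camera frame using
#' the rig's stored rectifying rotation.
#'
#' @param d `disparity_map` from the rectified pair.
#' @param rig rectified `stereo_rig` (as produced by [rectify_rig()]).
#' @param eps minimum disparity in pixels; pixels at or below it (at or
#'   behind infinity) are dropped.
#' @return `point_cloud` in the camera frame (mm).  May be empty.
#' @export
triangulate_disparity <- function(d, rig, eps = 1e-6) {
  stopifnot(inherits(d, "disparity_map"), inherits(rig, "stereo_rig"))
  if (!isTRUE(rig$rectified)) stop("triangulation requires a rectified rig")
  cam <- rig$left
  keep <- d$valid & d$disparity > eps
  if (!any(keep)) return(point_cloud(matrix(0, 0, 3), "camera"))
  idx <- which(keep)
  vv <- (idx - 1) %% d$height        # 0-based row
  uu <- (idx - 1) %/% d$height       # 0-based col
  Z <- cam$fx * rig$baseline_mm / d$disparity[idx]
  X <- (uu - cam$cx) * Z / cam$fx
  Y <- (vv - cam$cy) * Z / cam$fy
  pts <- cbind(X, Y, Z) %*% rig$R_from_camera  # rows: t(R_from_camera) %*% p
  point_cloud(pts, "camera")
}
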