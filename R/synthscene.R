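# Synthetic stand-in for all hardware: parametric surfaces with analytic
# normals, speckle-pattern stereo rendering with per-pixel ground truth, and
# noisy EM pose streams with tracker-grade noise.

# Run expr with a fixed RNG seed without disturbing the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Parametric test surfaces with analytic normals
#'
#' Constructors for the surface models the simulator can image: an infinite
#' plane, a sphere, a hemispherical shell resting on the z = 0 plane
#' (centre at the origin), and a smooth bumpy height field standing in for
#' a femur-like free-form surface.  Each model supports
#' [surface_distance()], [surface_normal_at()], [sample_surface()] and ray
#' intersection inside the renderer.
#'
#' @param normal,offset_mm plane `normal . x = offset` (normal normalised).
#' @param center,radius_mm sphere centre (mm) and radius (mm).
#' @param base_z_mm,bumps bumpy surface `z = base + sum of Gaussian bumps`;
#'   `bumps` is a data.frame with columns `cx, cy, amp, width` (mm, bump
#'   amplitudes of a few mm at most — no claim of anatomical fidelity).
#' @return object of class `surface_model`.
#' @name surface_models
NULL

#' @rdname surface_models
#' @export
surface_plane <- function(normal = c(0, 0, 1), offset_mm = 0) {
  structure(list(kind = "plane", normal = .unitize(as.numeric(normal)),
                 offset = offset_mm),
            class = "surface_model")
}

#' @rdname surface_models
#' @export
surface_sphere <- function(center = c(0, 0, 0), radius_mm = 20) {
  stopifnot(radius_mm > 0)
  structure(list(kind = "sphere", center = as.numeric(center),
                 radius = radius_mm),
            class = "surface_model")
}

#' @rdname surface_models
#' @export
surface_hemisphere_shell <- function(radius_mm = 98) {
  stopifnot(radius_mm > 0)
  structure(list(kind = "hemisphere_shell", center = c(0, 0, 0),
                 radius = radius_mm),
            class = "surface_model")
}

#' @rdname surface_models
#' @export
surface_bumpy <- function(base_z_mm = 40,
                          bumps = data.frame(cx = c(0, 6, -5),
                                             cy = c(0, -4, 5),
                                             amp = c(-2.5, -1.5, -2),
                                             width = c(6, 4, 5))) {
  structure(list(kind = "bumpy", base_z = base_z_mm, bumps = bumps),
            class = "surface_model")
}

.bumpy_height <- function(m, x, y) {
  z <- rep(m$base_z, length(x))
  for (i in seq_len(nrow(m$bumps))) {
    b <- m$bumps[i, ]
    z <- z + b$amp * exp(-((x - b$cx)^2 + (y - b$cy)^2) / (2 * b$width^2))
  }
  z
}

.bumpy_grad <- function(m, x, y) {
  gx <- numeric(length(x)); gy <- numeric(length(x))
  for (i in seq_len(nrow(m$bumps))) {
    b <- m$bumps[i, ]
    g <- b$amp * exp(-((x - b$cx)^2 + (y - b$cy)^2) / (2 * b$width^2))
    gx <- gx - g * (x - b$cx) / b$width^2
    gy <- gy - g * (y - b$cy) / b$width^2
  }
  cbind(gx, gy)
}

#' Signed distance from points to a surface model
#'
#' Exact for planes and spheres; for the bumpy height field the vertical
#' distance `z - h(x, y)` is returned.
#'
#' @param m `surface_model`.
#' @param p 3-vector or n x 3 matrix (mm).
#' @return numeric vector of distances (mm).
#' @export
surface_distance <- function(m, p) {
  p <- rbind(p)
  switch(m$kind,
    plane = as.numeric(p %*% m$normal) - m$offset,
    sphere = ,
    hemisphere_shell = sqrt(rowSums(sweep(p, 2, m$center)^2)) - m$radius,
    bumpy = p[, 3] - .bumpy_height(m, p[, 1], p[, 2]),
    stop("unknown surface kind"))
}

#' Analytic unit normal at surface points
#' @param m `surface_model`.
#' @param p 3-vector or n x 3 matrix of points on the surface.
#' @return n x 3 matrix of unit normals.
#' @export
surface_normal_at <- function(m, p) {
  p <- rbind(p)
  switch(m$kind,
    plane = matrix(m$normal, nrow(p), 3, byrow = TRUE),
    sphere = ,
    hemisphere_shell = {
      d <- sweep(p, 2, m$center)
      d / sqrt(rowSums(d^2))
    },
    bumpy = {
      g <- .bumpy_grad(m, p[, 1], p[, 2])
      n <- cbind(-g[, 1], -g[, 2], 1)
      n / sqrt(rowSums(n^2))
    },
    stop("unknown surface kind"))
}

#' Sample points exactly on a surface, with analytic normals
#'
#' @param m `surface_model`.
#' @param n number of points.
#' @param region list with `center` (3-vector) and `radius` (mm) bounding the
#'   sampled patch around the projection of `center` onto the surface.
#' @param seed RNG seed; sampling is reproducible and does not disturb the
#'   caller's RNG.
#' @return list with `cloud` (n x 3 matrix on the surface) and `normals`
#'   (n x 3 analytic unit normals).
#' @export
sample_surface <- function(m, n, region = list(center = c(0, 0, 0), radius = 10),
                           seed = 1L) {
  .with_seed(seed, {
    ctr <- as.numeric(region$center); rad <- region$radius
    pts <- switch(m$kind,
      plane = {
        # orthobasis in the plane around the projected centre
        nrm <- m$normal
        c0 <- ctr - (sum(nrm * ctr) - m$offset) * nrm
        a <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        u <- .unitize(a - sum(a * nrm) * nrm)
        v <- c(nrm[2] * u[3] - nrm[3] * u[2], nrm[3] * u[1] - nrm[1] * u[3],
               nrm[1] * u[2] - nrm[2] * u[1])
        rr <- rad * sqrt(stats::runif(n)); th <- stats::runif(n, 0, 2 * pi)
        sweep(outer(rr * cos(th), u) + outer(rr * sin(th), v), 2, c0, "+")
      },
      sphere = ,
      hemisphere_shell = {
        axis <- ctr - m$center
        axis <- if (sqrt(sum(axis^2)) < 1e-12) c(0, 0, 1) else .unitize(axis)
        alpha <- min(pi, rad / m$radius)   # angular radius of the cap
        out <- matrix(0, 0, 3)
        while (nrow(out) < n) {
          k <- max(n - nrow(out), 16)
          cu <- stats::runif(k, cos(alpha), 1)
          ps <- stats::runif(k, 0, 2 * pi)
          su <- sqrt(1 - cu^2)
          a <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
          u <- .unitize(a - sum(a * axis) * axis)
          v <- c(axis[2] * u[3] - axis[3] * u[2],
                 axis[3] * u[1] - axis[1] * u[3],
                 axis[1] * u[2] - axis[2] * u[1])
          dirs <- outer(su * cos(ps), u) + outer(su * sin(ps), v) + outer(cu, axis)
          cand <- sweep(m$radius * dirs, 2, m$center, "+")
          if (m$kind == "hemisphere_shell") cand <- cand[cand[, 3] >= 0, , drop = FALSE]
          out <- rbind(out, cand)
        }
        out[seq_len(n), , drop = FALSE]
      },
      bumpy = {
        rr <- rad * sqrt(stats::runif(n)); th <- stats::runif(n, 0, 2 * pi)
        x <- ctr[1] + rr * cos(th); y <- ctr[2] + rr * sin(th)
        cbind(x, y, .bumpy_height(m, x, y))
      },
      stop("unknown surface kind"))
    if (nrow(pts) == 0) stop("region does not intersect the surface")
    list(cloud = pts, normals = surface_normal_at(m, pts))
  })
}

# First positive ray-surface intersection; origins o (n x 3), unit dirs d
# (n x 3).  Returns n x 3 points with NA rows for misses.
.ray_intersect <- function(m, o, d) {
  n <- nrow(o)
  hit <- matrix(NA_real_, n, 3)
  if (m$kind == "plane") {
    denom <- d %*% m$normal
    tt <- (m$offset - o %*% m$normal) / denom
    ok <- abs(denom) > 1e-12 & tt > 1e-9
    ok <- as.vector(ok)
    hit[ok, ] <- o[ok, , drop = FALSE] + d[ok, , drop = FALSE] * tt[ok]
  } else if (m$kind %in% c("sphere", "hemisphere_shell")) {
    oc <- sweep(o, 2, m$center)
    b <- rowSums(oc * d)
    cc <- rowSums(oc^2) - m$radius^2
    disc <- b^2 - cc
    ok <- disc >= 0
    sq <- sqrt(pmax(disc, 0))
    t1 <- -b - sq; t2 <- -b + sq
    tt <- ifelse(t1 > 1e-9, t1, ifelse(t2 > 1e-9, t2, NA))
    if (m$kind == "hemisphere_shell") {
      # prefer the nearer intersection that lies on the shell (z >= 0)
      z1 <- o[, 3] + t1 * d[, 3]; z2 <- o[, 3] + t2 * d[, 3]
      tt <- ifelse(t1 > 1e-9 & z1 >= 0, t1,
            ifelse(t2 > 1e-9 & z2 >= 0, t2, NA))
    }
    ok <- ok & !is.na(tt)
    hit[ok, ] <- o[ok, , drop = FALSE] + d[ok, , drop = FALSE] * tt[ok]
  } else if (m$kind == "bumpy") {
    # height-field intersection by damped fixed-point iteration; valid for
    # gentle slopes and rays with a dominant z component
    tt <- (m$base_z - o[, 3]) / d[, 3]
    for (i in 1:60) {
      x <- o[, 1] + tt * d[, 1]; y <- o[, 2] + tt * d[, 2]
      tt_new <- (.bumpy_height(m, x, y) - o[, 3]) / d[, 3]
      tt <- tt + 0.8 * (tt_new - tt)
    }
    x <- o[, 1] + tt * d[, 1]; y <- o[, 2] + tt * d[, 2]
    z <- o[, 3] + tt * d[, 3]
    ok <- tt > 1e-9 & abs(z - .bumpy_height(m, x, y)) < 1e-6
    hit[ok, ] <- cbind(x, y, z)[ok, , drop = FALSE]
  } else stop("unknown surface kind")
  hit
}

#' Speckle projector configuration
#'
#' @param n_dots number of projected random dots (default 5000, matching the
#'   speckle illuminator's dot count).
#' @param dot_sigma_px Gaussian splat radius in pixels (default 0.8) — dots
#'   are splatted as small Gaussians so the census matcher sees realistic
#'   multi-pixel support.
#' @param seed RNG seed for the dot pattern.
#' @param background_level,dot_level 8-bit intensities.
#' @param cone_half_angle_deg half-angle of the projector's dot cone.
#' @return object of class `speckle_config`.
#' @export
speckle_config <- function(n_dots = 5000, dot_sigma_px = 0.8, seed = 1L,
                           background_level = 20, dot_level = 235,
                           cone_half_angle_deg = 20) {
  stopifnot(n_dots > 0, background_level >= 0, background_level <= 255,
            dot_level >= 0, dot_level <= 255)
  structure(list(n_dots = as.integer(n_dots), dot_sigma_px = dot_sigma_px,
                 seed = as.integer(seed), background_level = background_level,
                 dot_level = dot_level,
                 cone_half_angle_deg = cone_half_angle_deg),
            class = "speckle_config")
}

#' A plausible synthetic endoscope rig
#'
#' Two identical pinhole cameras side by side with parallel optical axes and
#' mild radial/tangential distortion.  The baseline defaults to 4 mm — the
#' physical illuminator and cameras share a 7.40 mm tip circle, which bounds
#' the baseline; the true value is configurable.
#'
#' @param width,height image size in pixels (desk-scale default 320 x 240).
#' @param fov_deg horizontal field of view of the rendered cameras.
#' @param baseline_mm stereo baseline.
#' @param k1,k2,p1,p2 distortion coefficients applied to both cameras.
#' @return a `stereo_rig`.
#' @export
synthetic_rig <- function(width = 320, height = 240, fov_deg = 60,
                          baseline_mm = 4, k1 = -0.08, k2 = 0.01,
                          p1 = 5e-4, p2 = -5e-4) {
  f <- (width / 2) / tan(fov_deg * pi / 360)
  cam <- function() camera_model(f, f, (width - 1) / 2, (height - 1) / 2,
                                 width, height, k1, k2, p1, p2)
  stereo_rig(cam(), cam(), diag(3), c(-baseline_mm, 0, 0))
}

# splat Gaussian dots into an image matrix (0-based uv pixel coords)
.splat_dots <- function(uv, h, w, sigma, bg, amp) {
  img <- matrix(bg, h, w)
  keep <- is.finite(uv[, 1]) & is.finite(uv[, 2]) &
    uv[, 1] > -3 & uv[, 1] < w + 2 & uv[, 2] > -3 & uv[, 2] < h + 2
  uv <- uv[keep, , drop = FALSE]
  if (nrow(uv) == 0) return(img)
  r <- 3L
  off <- as.matrix(expand.grid(du = -r:r, dv = -r:r))
  nd <- nrow(uv); no <- nrow(off)
  ui <- rep(round(uv[, 1]), each = no) + rep(off[, 1], nd)
  vi <- rep(round(uv[, 2]), each = no) + rep(off[, 2], nd)
  uc <- rep(uv[, 1], each = no); vc <- rep(uv[, 2], each = no)
  val <- amp * exp(-((ui - uc)^2 + (vi - vc)^2) / (2 * sigma^2))
  inb <- ui >= 0 & ui < w & vi >= 0 & vi < h
  lin <- vi[inb] + 1 + h * ui[inb]
  agg <- rowsum(val[inb], lin)
  idx <- as.integer(rownames(agg))
  img[idx] <- img[idx] + agg[, 1]
  pmin(img, 255)
}

#' Render a speckle-illuminated stereo pair with ground truth
#'
#' Random dots are cast from a projector (by default midway between the two
#' cameras, mimicking the illuminator inside the endoscope tip) onto the
#' surface, then splatted into both raw camera images through the full
#' pinhole + distortion forward model; dots on back-facing surface patches
#' are discarded per camera.  Per-pixel ground-truth depth and disparity are
#' computed analytically in the rectified geometry of the rig.
#'
#' @param m `surface_model` in the left-camera frame (camera at the origin
#'   looking along +z).
#' @param rig `stereo_rig` (raw, possibly distorted).
#' @param sc `speckle_config`.
#' @param projector_position 3-vector, projector origin in the left-camera
#'   frame; default midway along the baseline.
#' @param aim 3-vector the projector cone is aimed at.
#' @return list with raw `left`/`right` images, `rig`, `dots` (3D dot
#'   positions), `gt_depth` and `gt_disparity` (matrices in the rectified
#'   left view; NA where the surface is not seen), and `rect` (the
#'   rectification geometry from [rectify_rig()]).
#' @export
render_speckle_stereo <- function(m, rig, sc = speckle_config(),
                                  projector_position = NULL,
                                  aim = c(0, 0, 40)) {
  C2 <- as.numeric(-t(rig$rotation) %*% rig$translation_mm)
  if (is.null(projector_position)) projector_position <- C2 / 2
  axis <- .unitize(as.numeric(aim) - projector_position)
  dots <- .with_seed(sc$seed, {
    alpha <- sc$cone_half_angle_deg * pi / 180
    cu <- stats::runif(sc$n_dots, cos(alpha), 1)
    ps <- stats::runif(sc$n_dots, 0, 2 * pi)
    su <- sqrt(1 - cu^2)
    a <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- .unitize(a - sum(a * axis) * axis)
    v <- c(axis[2] * u[3] - axis[3] * u[2], axis[3] * u[1] - axis[1] * u[3],
           axis[1] * u[2] - axis[2] * u[1])
    d <- outer(su * cos(ps), u) + outer(su * sin(ps), v) + outer(cu, axis)
    o <- matrix(projector_position, sc$n_dots, 3, byrow = TRUE)
    .ray_intersect(m, o, d)
  })
  dots <- dots[stats::complete.cases(dots), , drop = FALSE]
  if (nrow(dots) == 0) stop("no projector dot reaches the surface")
  nrm <- surface_normal_at(m, dots)

  render_view <- function(cam, center, Rw2c) {
    # a dot is visible when it is the first surface point on its camera ray
    rel <- sweep(dots, 2, center)
    dirs <- rel / sqrt(rowSums(rel^2))
    first <- .ray_intersect(m, matrix(center, nrow(dots), 3, byrow = TRUE), dirs)
    vis <- stats::complete.cases(first) &
      rowSums((first - dots)^2) < 1e-10
    pc <- rel[vis, , drop = FALSE] %*% t(Rw2c)
    uv <- project_points(cam, pc)
    .splat_dots(uv, cam$height, cam$width, sc$dot_sigma_px,
                sc$background_level, sc$dot_level - sc$background_level)
  }
  left <- render_view(rig$left, c(0, 0, 0), diag(3))
  right <- render_view(rig$right, C2, rig$rotation)

  # analytic ground truth in the rectified left view
  rect <- rectify_rig(rig)
  cam <- rect$rig$left
  h <- cam$height; w <- cam$width
  uu <- rep(0:(w - 1), each = h); vv <- rep(0:(h - 1), times = w)
  dirs <- cbind((uu - cam$cx) / cam$fx, (vv - cam$cy) / cam$fy, 1) %*% rect$R_left
  dirs <- dirs / sqrt(rowSums(dirs^2))
  hits <- .ray_intersect(m, matrix(0, h * w, 3), dirs)
  z_rect <- hits %*% rect$R_left[3, ]          # depth along the rectified axis
  gt_depth <- matrix(as.numeric(z_rect), h, w)
  gt_disparity <- cam$fx * rect$rig$baseline_mm / gt_depth
  list(left = left, right = right, rig = rig, dots = dots,
       gt_depth = gt_depth, gt_disparity = gt_disparity, rect = rect)
}

#' EM tracker noise model
#'
#' Position noise is isotropic Gaussian per axis; orientation noise composes
#' a rotation about a uniformly random axis by a Gaussian-magnitude angle.
#' Defaults reflect tracker-grade performance: sub-millimetre position
#' (0.55 mm) and 0.1 degree orientation.
#'
#' @param sigma_pos_mm per-axis position noise SD (mm).
#' @param sigma_rot_deg rotation angle noise SD (degrees).
#' @param seed RNG seed.
#' @return object of class `em_noise_model`.
#' @export
em_noise_model <- function(sigma_pos_mm = 0.55, sigma_rot_deg = 0.1,
                           seed = 1L) {
  stopifnot(sigma_pos_mm >= 0, sigma_rot_deg >= 0)
  structure(list(sigma_pos_mm = sigma_pos_mm, sigma_rot_deg = sigma_rot_deg,
                 seed = as.integer(seed)),
            class = "em_noise_model")
}

#' Simulate a noisy EM pose stream
#'
#' @param true_poses list of `rigid_transform`s (sensor -> transmitter).
#' @param noise `em_noise_model`.
#' @return list of perturbed `rigid_transform`s, same length and frames.
#' @export
simulate_em <- function(true_poses, noise) {
  stopifnot(inherits(noise, "em_noise_model"))
  .with_seed(noise$seed, {
    lapply(true_poses, function(tp) {
      t_new <- tp$translation + stats::rnorm(3, 0, noise$sigma_pos_mm)
      R_new <- tp$rotation
      if (noise$sigma_rot_deg > 0) {
        ax <- stats::rnorm(3)
        ang <- stats::rnorm(1, 0, noise$sigma_rot_deg * pi / 180)
        R_new <- rotation_about_axis(ax, ang) %*% R_new
      } else {
        stats::rnorm(4)   # keep the draw count identical across noise levels
      }
      rigid_transform(R_new, t_new, tp$from_frame, tp$to_frame)
    })
  })
}
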