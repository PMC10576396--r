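# Pipeline orchestration: configuration, the reconstruct workflow
# (rectify -> match -> triangulate -> femur frame -> rearrange -> surface)
# and the evaluate workflow (hemisphere tabulation protocol), with file
# outputs and a run log.

#' Default pipeline configuration
#'
#' A plain named list describing one synthetic run end to end; it
#' round-trips losslessly through YAML/JSON via [write_pipeline_config()]
#' and [read_pipeline_config()].  Units: mm and degrees at this boundary.
#'
#' @param scene list: `kind` (`plane`, `sphere`, `hemisphere_shell`,
#'   `bumpy`) plus the surface parameters of the matching constructor in
#'   [surface_models].
#' @param rig list of [synthetic_rig()] arguments.
#' @param speckle list of [speckle_config()] arguments.
#' @param sgm list of [sgm_params()] arguments.
#' @param interval_t_mm voxel grid spacing for rearrangement.
#' @param search_diameter_mm normal-estimation search diameter.
#' @param contact_threshold_mm tip-contact threshold for navigation.
#' @param min_speckle_level intensity below which a rectified-left pixel is
#'   treated as unlit and excluded from triangulation.
#' @param hemisphere list of [hemisphere_config()] arguments.
#' @param tilt_deg instrument tilt from the analytic normal in the
#'   evaluation protocol; NULL means "use the estimated normal" (closure
#'   mode).
#' @param jitter_sd_deg SD of the per-sample pointing jitter added to the
#'   tilt (default 0.1 deg, tracker-grade).
#' @param em_noise list of [em_noise_model()] arguments.
#' @param seed master seed for the run.
#' @param out_dir output directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(scene = list(kind = "sphere",
                                         center = c(0, 0, 60.045),
                                         radius_mm = 40.09 / 2),
                            rig = list(),
                            speckle = list(),
                            sgm = list(d_min = 8L, d_max = 48L),
                            interval_t_mm = 0.3,
                            search_diameter_mm = 0.6,
                            contact_threshold_mm = 1.0,
                            min_speckle_level = 40,
                            hemisphere = list(),
                            tilt_deg = NULL,
                            jitter_sd_deg = 0.1,
                            em_noise = list(sigma_pos_mm = 0,
                                            sigma_rot_deg = 0),
                            seed = 1L,
                            out_dir = tempfile("stereonav_run_")) {
  structure(list(scene = scene, rig = rig, speckle = speckle, sgm = sgm,
                 interval_t_mm = interval_t_mm,
                 search_diameter_mm = search_diameter_mm,
                 contact_threshold_mm = contact_threshold_mm,
                 min_speckle_level = min_speckle_level,
                 hemisphere = hemisphere, tilt_deg = tilt_deg,
                 jitter_sd_deg = jitter_sd_deg, em_noise = em_noise,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- lapply(raw, function(x) if (is.list(x)) lapply(x, unlist1) else x)
  cfg <- do.call(pipeline_config, raw)
  cfg
}

unlist1 <- function(x) if (is.list(x) && all(lengths(x) == 1)) unlist(x) else x

#' @rdname read_pipeline_config
#' @param cfg `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  x <- unclass(cfg)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE, null = "null")
  invisible(path)
}

.build_scene <- function(scene) {
  kind <- scene$kind
  args <- scene[setdiff(names(scene), "kind")]
  fn <- switch(kind,
               plane = surface_plane, sphere = surface_sphere,
               hemisphere_shell = surface_hemisphere_shell,
               bumpy = surface_bumpy,
               stop("unknown scene kind: ", kind))
  do.call(fn, args)
}

# tiny FNV-1a hash of a string, for run-log config fingerprints
# (32-bit arithmetic carried in doubles, split to stay exact)
.fnv1a <- function(s) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(s)) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h_lo <- h %% 65536; h_hi <- (h - h_lo) / 65536
    h <- ((h_lo * p) %% 4294967296 + ((h_hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Simulate one synthetic capture to disk
#'
#' Writes the raw stereo pair (PNG), ground-truth depth (16-bit fixed-point
#' PNG, mm x 256, with a JSON sidecar giving the scale), the true and
#' EM-noise-perturbed pose streams (CSV), the calibration JSON, and the
#' scene description.
#'
#' @param cfg `pipeline_config`.
#' @return invisibly, the list of written paths.
#' @export
run_simulate <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  m <- .build_scene(cfg$scene)
  rig <- do.call(synthetic_rig, cfg$rig)
  sc <- do.call(speckle_config, c(cfg$speckle,
                                  if (is.null(cfg$speckle$seed)) list(seed = cfg$seed)))
  aim <- if (!is.null(cfg$scene$center)) as.numeric(cfg$scene$center) else c(0, 0, 40)
  ren <- .stage("render", render_speckle_stereo(m, rig, sc, aim = aim))

  # endoscope and patient poses: sensor-1 near the camera, sensor-3 on the
  # specimen; both referenced to a transmitter off to the side
  true_poses <- list(
    sensor1 = rigid_transform(rotation_about_axis(c(0, 1, 0), 0.2),
                              c(120, 40, -30), "sensor1", "transmitter"),
    sensor2 = rigid_transform(rotation_about_axis(c(1, 0, 0), -0.15),
                              c(80, -50, 20), "sensor2", "transmitter"),
    sensor3 = rigid_transform(rotation_about_axis(c(1, 1, 0), 0.4),
                              c(-60, 90, 10), "sensor3", "transmitter"))
  noise <- do.call(em_noise_model,
                   c(cfg$em_noise,
                     if (is.null(cfg$em_noise$seed)) list(seed = cfg$seed + 1L)))
  meas <- simulate_em(true_poses, noise)

  p <- function(f) file.path(cfg$out_dir, f)
  write_image_png(ren$left, p("left.png"))
  write_image_png(ren$right, p("right.png"))
  depth <- ren$gt_depth
  depth[!is.finite(depth)] <- 0
  png::writePNG(pmin(depth * 256, 65535) / 65535, p("gt_depth.png"))
  jsonlite::write_json(list(scale = "mm*256 in 16-bit PNG",
                            width = ncol(depth), height = nrow(depth)),
                       p("gt_depth.json"), auto_unbox = TRUE)
  stream <- do.call(rbind, lapply(names(meas), function(id) {
    transform_to_pose_row(meas[[id]], time_s = 0, sensor_id = id)
  }))
  write_pose_stream(stream, p("poses.csv"))
  write_pose_stream(do.call(rbind, lapply(names(true_poses), function(id) {
    transform_to_pose_row(true_poses[[id]], time_s = 0, sensor_id = id)
  })), p("poses_true.csv"))
  write_calibration(hand_eye_calibration(),
                    instrument_calibration(c(0, 0, 0), c(0, 0, 80)),
                    p("calibration.json"))
  jsonlite::write_json(cfg$scene, p("scene.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(dir = cfg$out_dir,
                 files = c("left.png", "right.png", "gt_depth.png",
                           "poses.csv", "calibration.json", "scene.json")))
}

#' Reconstruct a femur-frame surface from one stereo frame
#'
#' The full imaging chain on one synthetic capture: render (or reuse) the
#' speckle pair, rectify, semi-global matching, triangulation to a
#' camera-frame cloud, transformation into the patient (femur) frame through
#' the tracked sensor poses, voxel rearrangement and isosurface extraction.
#' All intermediates are written under `cfg$out_dir` together with a run log
#' recording the configuration fingerprint and seeds.
#'
#' @param cfg `pipeline_config`.
#' @param input_dir directory holding `left.png`, `right.png`, `poses.csv`,
#'   `calibration.json` (as written by [run_simulate()]); NULL renders the
#'   scene in memory and simulates noise-free poses.
#' @return list with `cloud_femur` (`point_cloud`), `mesh`
#'   (`triangle_mesh`), `disparity` (`disparity_map`), `cloud_camera`, and
#'   the paths written.
#' @export
run_reconstruct <- function(cfg, input_dir = NULL) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  rig <- do.call(synthetic_rig, cfg$rig)
  if (is.null(input_dir)) {
    sim <- run_simulate(cfg)
    input_dir <- cfg$out_dir
  }
  pair <- .stage("load", {
    lp <- file.path(input_dir, "left.png"); rp <- file.path(input_dir, "right.png")
    if (!file.exists(lp) || !file.exists(rp)) stop("missing stereo images")
    list(left = read_image_png(lp), right = read_image_png(rp))
  })
  poses <- .stage("frames", {
    pf <- file.path(input_dir, "poses.csv")
    if (!file.exists(pf)) stop("missing pose file ", pf)
    read_pose_stream(pf)
  })
  calib <- .stage("frames", {
    cf <- file.path(input_dir, "calibration.json")
    if (!file.exists(cf)) stop("missing calibration file ", cf)
    read_calibration(cf)
  })
  rect <- .stage("rectify", undistort_rectify(pair, rig))
  sgmp <- do.call(sgm_params, cfg$sgm)
  disp <- .stage("sgm", {
    d <- sgm_disparity(rect[c("left", "right")], sgmp)
    mask_disparity_by_intensity(d, rect$left, cfg$min_speckle_level)
  })
  cloud_cam <- .stage("triangulate", triangulate_disparity(disp, rect$rig))
  cloud_fem <- .stage("frames", {
    s1 <- pose_row_to_transform(poses[poses$sensor_id == "sensor1", ][1, ])
    s3 <- pose_row_to_transform(poses[poses$sensor_id == "sensor3", ][1, ])
    camera_to_femur(cloud_cam, s1, s3, calib$hand_eye)
  })
  grid <- .stage("rearrange", rearrange_points(cloud_fem, cfg$interval_t_mm))
  mesh <- .stage("extract_surface", extract_surface(grid))

  p <- function(f) file.path(cfg$out_dir, f)
  write_disparity_png(disp, p("disparity"))
  write_ply(cloud_fem, p("cloud_femur.ply"))
  write_ply(mesh, p("mesh.ply"))
  cfg_for_hash <- unclass(cfg)
  cfg_for_hash$out_dir <- NULL          # fingerprint the science, not the paths
  cfg_json <- jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE, digits = NA,
                               null = "null")
  jsonlite::write_json(list(config_hash = .fnv1a(as.character(cfg_json)),
                            seed = cfg$seed,
                            n_points_camera = nrow(cloud_cam$points),
                            n_points_femur = nrow(cloud_fem$points),
                            valid_fraction = mean(disp$valid)),
                       p("run_log.json"), auto_unbox = TRUE, digits = NA)
  list(cloud_femur = cloud_fem, cloud_camera = cloud_cam, mesh = mesh,
       disparity = disp, grid = grid, rect = rect,
       paths = c(p("disparity.png"), p("cloud_femur.ply"), p("mesh.ply"),
                 p("run_log.json")))
}

#' Run the hemisphere-tabulation evaluation protocol
#'
#' Reproduces the 30-sample protocol (6 azimuths x 5 markers by default) on
#' a synthetic shell.  At every marker a harvester is simulated in contact
#' with the shell: its tracked sensor poses are built so the tip touches the
#' marker and its axis points along the analytic normal tilted by
#' `cfg$tilt_deg` (plus seeded Gaussian pointing jitter), or along the
#' normal estimated from the shell cloud when `cfg$tilt_deg` is NULL.  The
#' instrument ray is projected to the base plane and converted to the error
#' angle beta; markers without cloud contact are recorded as missing and
#' excluded from the statistics.
#'
#' @param cfg `pipeline_config`.
#' @param cloud optional femur-frame `point_cloud` of the shell; by default
#'   the shell is sampled analytically around each marker.
#' @return a `hemisphere_eval` (records, summary, n_missing); records CSV
#'   and summary JSON are written under `cfg$out_dir`.
#' @export
run_evaluate <- function(cfg, cloud = NULL) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hcfg <- do.call(hemisphere_config, cfg$hemisphere)
  shell <- surface_hemisphere_shell(hcfg$radius_r_mm)
  if (!is.null(cloud) && !inherits(cloud, "point_cloud")) {
    stop("cloud must be a point_cloud in the femur frame")
  }
  n_local <- 400L   # analytic patch sampled around each marker
  jit_seed <- cfg$seed + 17L
  k <- 0L
  eval_dir <- function(P, phi, s) {
    k <<- k + 1L
    local_cloud <- if (is.null(cloud)) {
      point_cloud(sample_surface(shell, n_local,
                                 region = list(center = P, radius = 2),
                                 seed = cfg$seed + 100L + k)$cloud, "femur")
    } else cloud
    true_n <- as.numeric(surface_normal_at(shell, P))
    inward <- -true_n
    dir <- if (is.null(cfg$tilt_deg)) {
      est <- estimate_normal(local_cloud, P, cfg$search_diameter_mm,
                             reference = inward)
      est$normal
    } else {
      tilt <- cfg$tilt_deg * pi / 180 +
        .with_seed(jit_seed + k, stats::rnorm(1, 0, cfg$jitter_sd_deg * pi / 180))
      az <- .with_seed(jit_seed + 1000L + k, stats::runif(1, 0, 2 * pi))
      a <- if (abs(inward[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u <- .unitize(a - sum(a * inward) * inward)
      v <- c(inward[2] * u[3] - inward[3] * u[2],
             inward[3] * u[1] - inward[1] * u[3],
             inward[1] * u[2] - inward[2] * u[1])
      .unitize(cos(tilt) * inward + sin(tilt) * (cos(az) * u + sin(az) * v))
    }
    # simulated harvester: sensor-3 at identity, sensor-2 placed so the
    # calibrated tip lands on the marker with the axis opposite `dir`
    sim <- simulate_instrument_at(P, dir)
    nav <- navigate(local_cloud, sim$sensor2, sim$sensor3, sim$ic,
                    contact_threshold_mm = cfg$contact_threshold_mm,
                    search_diameter_mm = cfg$search_diameter_mm)
    if (is.null(nav)) stop("no contact")   # recorded as missing by the caller
    dir
  }
  ev <- evaluate_hemisphere(hcfg, eval_dir)
  write_eval_outputs(ev, file.path(cfg$out_dir, "eval_records.csv"),
                     file.path(cfg$out_dir, "eval_summary.json"))
  ev
}

#' Simulated tracked harvester touching a surface point
#'
#' Builds sensor poses and an instrument calibration such that the
#' calibrated tip lies exactly at `tip_point` and the instrument axis
#' `c_h = (tip - butt)/|tip - butt|` equals `direction` in the femur frame
#' (sensor-3 is placed at the transmitter origin).
#'
#' @param tip_point 3-vector, desired tip position (femur frame, mm).
#' @param direction 3-vector, desired instrument direction (into the
#'   surface).
#' @param length_mm instrument segment length.
#' @return list with `sensor2`, `sensor3` (`rigid_transform`s) and `ic`
#'   (`instrument_calibration`).
#' @export
simulate_instrument_at <- function(tip_point, direction, length_mm = 80) {
  d <- .unitize(as.numeric(direction))
  # rotation taking +z to -d (axis = z x (-d))
  z <- c(0, 0, 1); tgt <- -d
  cr <- c(z[2] * tgt[3] - z[3] * tgt[2], z[3] * tgt[1] - z[1] * tgt[3],
          z[1] * tgt[2] - z[2] * tgt[1])
  cs <- sum(z * tgt)
  R <- if (sqrt(sum(cr^2)) < 1e-12) {
    if (cs > 0) diag(3) else rotation_about_axis(c(1, 0, 0), pi)
  } else {
    rotation_about_axis(cr, acos(min(1, max(-1, cs))))
  }
  list(sensor2 = rigid_transform(R, as.numeric(tip_point), "sensor2", "transmitter"),
       sensor3 = identity_transform("sensor3", "transmitter"),
       ic = instrument_calibration(c(0, 0, 0), c(0, 0, length_mm)))
}
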