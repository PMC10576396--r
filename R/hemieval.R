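# Hemisphere-tabulation pose-accuracy protocol: markers on a transparent
# hemispherical shell, the instrument's laser ray projected onto the base
# (ECG-paper, z = 0) plane, and a law-of-cosines conversion of the landing
# point into an angular pose error.  The sphere centre O is the coordinate
# origin and the shell rests on the plane, apex at z = r.

#' Hemisphere evaluation configuration
#'
#' @param radius_r_mm shell radius (default 98.0 mm, a femur-scale shell).
#' @param phi_step_rad azimuth increment between evaluated arcs (default
#'   pi/12).
#' @param sections number of equal sections the pole-to-equator arc is
#'   divided into (default 6, giving `sections - 1 = 5` interior markers).
#' @param arcs number of azimuths evaluated (default 6, so the default
#'   protocol has 6 x 5 = 30 measurements).
#' @param phi0_rad azimuth of the first arc (default 0).
#' @return object of class `hemisphere_config`.
#' @export
hemisphere_config <- function(radius_r_mm = 98.0, phi_step_rad = pi / 12,
                              sections = 6L, arcs = 6L, phi0_rad = 0) {
  stopifnot(radius_r_mm > 0, phi_step_rad > 0, phi_step_rad < pi / 2,
            sections >= 2, arcs >= 1)
  structure(list(radius_r_mm = radius_r_mm, phi_step_rad = phi_step_rad,
                 sections = as.integer(sections), arcs = as.integer(arcs),
                 phi0_rad = phi0_rad),
            class = "hemisphere_config")
}

#' Marker points along one arc of the hemisphere
#'
#' The arc from the apex toward the equator is divided into `sections` equal
#' sections by `sections - 1` markers; because a central angle equals its
#' subtended arc over the radius, marker `s` sits at polar angle
#' `theta_s = s * (pi/2) / sections` (with the default 6 sections,
#' `theta_s = s * pi/12`).  In Cartesian coordinates
#' `P_s = r (sin theta_s cos phi, sin theta_s sin phi, cos theta_s)`.
#'
#' @param cfg `hemisphere_config`.
#' @param phi_rad azimuth of the arc (radians).
#' @return (sections - 1) x 3 matrix of marker coordinates (mm).
#' @export
marker_points <- function(cfg, phi_rad) {
  s <- seq_len(cfg$sections - 1L)
  theta <- s * (pi / 2) / cfg$sections
  r <- cfg$radius_r_mm
  cbind(r * sin(theta) * cos(phi_rad),
        r * sin(theta) * sin(phi_rad),
        r * cos(theta))
}

#' Project an instrument ray onto the base plane
#'
#' The ray from `origin_P` along `direction` is intersected with the z = 0
#' (ECG paper) plane; the intersection must lie forward along the ray.
#'
#' @param origin_P 3-vector, ray origin (typically a marker, z > 0).
#' @param direction 3-vector, ray direction (normalised internally; must
#'   point toward the plane, i.e. have dz < 0 when z > 0).
#' @return 2-vector `(x, y)` of the landing point E.
#' @export
project_ray_to_plane <- function(origin_P, direction) {
  p <- as.numeric(origin_P)
  d <- .unitize(as.numeric(direction))
  if (abs(d[3]) < 1e-15) stop("no intersection: ray is parallel to the plane")
  lambda <- -p[3] / d[3]
  if (lambda <= 0) stop("no intersection: ray points away from the plane")
  (p + lambda * d)[1:2]
}

#' Law-of-cosines error angle between estimated and true normal
#'
#' In the triangle formed by the sphere centre O (origin), the marker P on
#' the shell and the landing point E on the base plane, the side OP has
#' length r, so the law of cosines gives the angle at P between the
#' projected ray PE and the true (radial) normal PO:
#' `beta = arccos((|EP|^2 + r^2 - |OE|^2) / (2 r |EP|))`.
#' When E coincides with the along-normal intersection, beta is 0.
#'
#' @param marker_P 3-vector marker on the shell (|P| = r).
#' @param E 2-vector landing point on z = 0 (or 3-vector with z = 0).
#' @param r_mm sphere radius.
#' @return error angle beta in degrees (>= 0).
#' @export
beta_error <- function(marker_P, E, r_mm) {
  p <- as.numeric(marker_P)
  e <- as.numeric(E)
  e3 <- if (length(e) == 2) c(e, 0) else e
  EP <- sqrt(sum((e3 - p)^2))
  if (EP < 1e-12) return(0)
  OE <- sqrt(sum(e3^2))
  arg <- (EP^2 + r_mm^2 - OE^2) / (2 * r_mm * EP)
  if (arg > 1 + 1e-9 || arg < -1 - 1e-9) {
    stop("inconsistent geometry: law-of-cosines argument ", format(arg),
         " outside [-1, 1]")
  }
  acos(min(1, max(-1, arg))) * 180 / pi
}

#' Run the hemisphere tabulation protocol
#'
#' For every azimuth and marker, a ray is fired from the marker along the
#' supplied instrument direction, projected to the base plane and converted
#' into the error angle beta.  `direction_fn(P, phi, s)` supplies the ray
#' direction at marker `P` — e.g. the estimated normal flipped inward, or a
#' deliberately tilted direction when characterising the protocol itself.
#' Markers whose ray misses the plane are recorded with `beta_deg = NA` and
#' excluded from the summary.
#'
#' @param cfg `hemisphere_config`.
#' @param direction_fn function of `(P, phi, s)` returning a 3-vector ray
#'   direction.
#' @return object of class `hemisphere_eval`: a data.frame `records` with
#'   columns `arc, s, phi_rad, px, py, pz, ex, ey, beta_deg`, plus
#'   `summary` from [summarize_eval()] and `n_missing`.
#' @export
evaluate_hemisphere <- function(cfg, direction_fn) {
  stopifnot(inherits(cfg, "hemisphere_config"))
  recs <- NULL
  for (a in seq_len(cfg$arcs)) {
    phi <- cfg$phi0_rad + (a - 1) * cfg$phi_step_rad
    P <- marker_points(cfg, phi)
    for (s in seq_len(nrow(P))) {
      rec <- data.frame(arc = a, s = s, phi_rad = phi,
                        px = P[s, 1], py = P[s, 2], pz = P[s, 3],
                        ex = NA_real_, ey = NA_real_, beta_deg = NA_real_)
      ok <- tryCatch({
        dir <- direction_fn(P[s, ], phi, s)
        E <- project_ray_to_plane(P[s, ], dir)
        rec$ex <- E[1]; rec$ey <- E[2]
        rec$beta_deg <- beta_error(P[s, ], E, cfg$radius_r_mm)
        TRUE
      }, error = function(e) FALSE)
      recs <- rbind(recs, rec)
    }
  }
  betas <- recs$beta_deg[!is.na(recs$beta_deg)]
  structure(list(records = recs,
                 summary = summarize_eval(betas),
                 n_missing = sum(is.na(recs$beta_deg))),
            class = "hemisphere_eval")
}

#' Summary statistics of the protocol's error angles
#'
#' @param beta_deg numeric vector of error angles (degrees), n >= 1.
#' @return list with `mean_deg`, `sd_deg` (sample SD, n - 1 denominator; 0
#'   with `sd_defined = FALSE` when n = 1), `min_deg`, `max_deg`, `n`.
#' @export
summarize_eval <- function(beta_deg) {
  beta_deg <- as.numeric(beta_deg)
  if (length(beta_deg) == 0) stop("cannot summarise an empty record set")
  n <- length(beta_deg)
  list(mean_deg = mean(beta_deg),
       sd_deg = if (n > 1) stats::sd(beta_deg) else 0,
       sd_defined = n > 1,
       min_deg = min(beta_deg), max_deg = max(beta_deg), n = n)
}

#' Write protocol outputs: records CSV and summary JSON
#' @param ev `hemisphere_eval`.
#' @param csv_path,json_path output paths.
#' @export
write_eval_outputs <- function(ev, csv_path, json_path) {
  utils::write.csv(ev$records, csv_path, row.names = FALSE, quote = FALSE)
  s <- ev$summary
  jsonlite::write_json(list(mean_deg = s$mean_deg, sd_deg = s$sd_deg,
                            min_deg = s$min_deg, max_deg = s$max_deg,
                            n = s$n, n_missing = ev$n_missing),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(ev)
}
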