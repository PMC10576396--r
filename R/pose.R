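# Instrument pose support: surface-normal estimation from inscribed
# triangles in a small neighbourhood of the reconstructed cloud, and the
# AngDif angle between the instrument axis and the estimated normal.

.unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

#' Estimate the surface normal at a query point
#'
#' Candidate triangles are drawn from the cloud points inside a small search
#' region around the query (a diameter, default 0.6 mm).  Bounding the
#' neighbourhood keeps the triangle small (high local fidelity) while the
#' maximum-area triangle inside it is the most robust to point noise, so the
#' winner is the largest-area non-degenerate triangle; the normal is the
#' normalised cross product of its two edge vectors.  The search is
#' exhaustive over all point triples when the neighbourhood holds at most
#' `max_neighbors` points, otherwise over the `max_neighbors` nearest.
#'
#' @param cloud `point_cloud` (femur frame) or n x 3 matrix.
#' @param query 3-vector (mm).
#' @param search_diameter_mm diameter of the search region (default 0.6 mm).
#' @param reference optional 3-vector: the returned normal is flipped so its
#'   dot product with `reference` is non-negative.  When NULL the normal is
#'   oriented deterministically (positive z component, then y, then x).
#' @param max_neighbors neighbourhood cap for the exhaustive triple search.
#' @return object of class `normal_estimate`: `position` (the query),
#'   `normal` (unit 3-vector), `support_triangle` (indices into the cloud),
#'   `triangle_area` (mm^2), `n_neighbors`.
#' @export
estimate_normal <- function(cloud, query, search_diameter_mm = 0.6,
                            reference = NULL, max_neighbors = 30L) {
  pts <- if (inherits(cloud, "point_cloud")) cloud$points else as.matrix(cloud)
  query <- as.numeric(query)
  r <- search_diameter_mm / 2
  d2 <- (pts[, 1] - query[1])^2 + (pts[, 2] - query[2])^2 +
        (pts[, 3] - query[3])^2
  nb <- which(d2 <= r^2)
  if (length(nb) < 3) {
    stop("insufficient support: only ", length(nb),
         " cloud points within the search region", call. = FALSE)
  }
  if (length(nb) > max_neighbors) {
    nb <- nb[order(d2[nb])[seq_len(max_neighbors)]]
  }
  P <- pts[nb, , drop = FALSE]
  n <- nrow(P)
  trips <- utils::combn(n, 3)
  a <- P[trips[2, ], , drop = FALSE] - P[trips[1, ], , drop = FALSE]
  b <- P[trips[3, ], , drop = FALSE] - P[trips[1, ], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  areas <- 0.5 * sqrt(rowSums(cr^2))
  best <- which.max(areas)
  if (areas[best] < 1e-9) {
    stop("degenerate neighbourhood: all candidate triangles are collinear",
         call. = FALSE)
  }
  normal <- .unitize(cr[best, ])
  if (!is.null(reference)) {
    if (sum(normal * as.numeric(reference)) < 0) normal <- -normal
  } else {
    key <- c(normal[3], normal[2], normal[1])
    first <- key[which(abs(key) > 1e-12)[1]]
    if (!is.na(first) && first < 0) normal <- -normal
  }
  structure(list(position = query, normal = normal,
                 support_triangle = nb[trips[, best]],
                 triangle_area = areas[best], n_neighbors = n),
            class = "normal_estimate")
}

#' Angle between the instrument axis and the estimated normal (degrees)
#'
#' Both vectors are normalised internally; the result is the arc cosine of
#' their clamped dot product, in `[0, 180]` degrees.
#'
#' @param ch instrument direction, non-zero 3-vector.
#' @param ne estimated normal, non-zero 3-vector.
#' @return angle in degrees.
#' @export
ang_dif <- function(ch, ne) {
  u <- .unitize(as.numeric(ch))
  v <- .unitize(as.numeric(ne))
  acos(min(1, max(-1, sum(u * v)))) * 180 / pi
}

#' One navigation sample: contact point, instrument axis, normal, AngDif
#'
#' The instrument tip and butt are chained into the femur frame; when the
#' tip is within `contact_threshold_mm` of the reconstructed cloud the
#' nearest cloud point becomes the contact point, the surface normal is
#' estimated there, and the angle between the instrument axis `c_h`
#' (butt-to-tip, pointing into the surface) and the estimated normal `n_e`
#' is reported.  The normal sign is chosen so the reported angle lies in
#' `[0, 90]` degrees: zero means the harvester is perpendicular to the
#' surface.
#'
#' @param cloud `point_cloud` in the femur frame.
#' @param sensor2,sensor3 tracked sensor -> transmitter poses.
#' @param ic `instrument_calibration`.
#' @param contact_threshold_mm maximum tip-to-cloud distance that counts as
#'   contact (default 1.0 mm).
#' @param search_diameter_mm passed to [estimate_normal()].
#' @param time_s timestamp carried into the sample.
#' @return a `navigation_sample` (list with `contact_point`,
#'   `instrument_dir_ch`, `estimated_normal_ne`, `ang_dif_deg`, `tip`,
#'   `time_s`), or NULL when the tip is not in contact.
#' @export
navigate <- function(cloud, sensor2, sensor3, ic,
                     contact_threshold_mm = 1.0, search_diameter_mm = 0.6,
                     time_s = 0) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!.frames_equivalent(cloud$frame, "femur")) {
    stop("navigation requires a femur-frame cloud, got '", cloud$frame, "'")
  }
  seg <- instrument_axis_in_femur(sensor2, sensor3, ic)
  pts <- cloud$points
  d2 <- (pts[, 1] - seg$tip[1])^2 + (pts[, 2] - seg$tip[2])^2 +
        (pts[, 3] - seg$tip[3])^2
  i <- which.min(d2)
  if (sqrt(d2[i]) > contact_threshold_mm) return(NULL)
  contact <- pts[i, ]
  ch <- .unitize(seg$tip - seg$butt)
  est <- estimate_normal(cloud, contact, search_diameter_mm,
                         reference = ch)
  structure(list(contact_point = contact, instrument_dir_ch = ch,
                 estimated_normal_ne = est$normal,
                 ang_dif_deg = ang_dif(ch, est$normal),
                 tip = seg$tip, time_s = time_s),
            class = "navigation_sample")
}

#' Append navigation samples to a CSV log
#' @param samples list of `navigation_sample` objects.
#' @param path CSV path (created with a header if absent).
#' @export
write_navigation_csv <- function(samples, path) {
  rows <- do.call(rbind, lapply(samples, function(s) {
    data.frame(time_s = s$time_s,
               contact_x = s$contact_point[1], contact_y = s$contact_point[2],
               contact_z = s$contact_point[3],
               ch_x = s$instrument_dir_ch[1], ch_y = s$instrument_dir_ch[2],
               ch_z = s$instrument_dir_ch[3],
               ne_x = s$estimated_normal_ne[1], ne_y = s$estimated_normal_ne[2],
               ne_z = s$estimated_normal_ne[3],
               ang_dif_deg = s$ang_dif_deg)
  }))
  utils::write.table(rows, path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path),
                     quote = FALSE)
  invisible(path)
}
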