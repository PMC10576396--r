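# File formats at the package boundary: tracked-pose CSV streams,
# calibration JSON, ASCII PLY clouds/meshes, and fixed-point disparity PNGs.

#' Read a tracked pose stream
#'
#' CSV with columns `time_s, sensor_id, x_mm, y_mm, z_mm, qw, qx, qy, qz`;
#' every pose is sensor -> transmitter.
#'
#' @param path CSV file path.
#' @return data.frame with the columns above.
#' @export
read_pose_stream <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "sensor_id", "x_mm", "y_mm", "z_mm", "qw", "qx", "qy", "qz")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("pose stream missing columns: ",
                            paste(missing, collapse = ", "))
  df
}

#' Write a tracked pose stream
#' @param df data.frame as returned by [read_pose_stream()].
#' @param path output CSV path.
#' @export
write_pose_stream <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert one pose-stream row to a rigid transform
#' @param row single-row data.frame from a pose stream.
#' @param from_frame frame id of the sensor (defaults to the `sensor_id` column).
#' @return `rigid_transform` sensor -> transmitter.
#' @export
pose_row_to_transform <- function(row, from_frame = row$sensor_id) {
  rigid_transform(c(row$qw, row$qx, row$qy, row$qz),
                  c(row$x_mm, row$y_mm, row$z_mm),
                  from_frame = from_frame, to_frame = "transmitter")
}

#' Transform to pose-stream row
#' @param t `rigid_transform` sensor -> transmitter.
#' @param time_s timestamp (s).
#' @param sensor_id sensor frame id.
#' @return single-row data.frame.
#' @export
transform_to_pose_row <- function(t, time_s = 0, sensor_id = t$from_frame) {
  q <- rotmat_to_quat(t$rotation)
  data.frame(time_s = time_s, sensor_id = sensor_id,
             x_mm = t$translation[1], y_mm = t$translation[2],
             z_mm = t$translation[3],
             qw = q[1], qx = q[2], qy = q[3], qz = q[4])
}

#' Read hand-eye and instrument calibration constants from JSON
#'
#' Expected layout:
#' ```
#' {"hand_eye": {"quaternion": [qw,qx,qy,qz], "offset_mm": [x,y,z]},
#'  "instrument": {"tip_mm": [x,y,z], "axis_mm": [x,y,z]}}
#' ```
#' `rotation` (a 3x3 row-major matrix) may be given instead of `quaternion`.
#'
#' @param path JSON file path.
#' @return list with `hand_eye` ([hand_eye_calibration()]) and
#'   `instrument` ([instrument_calibration()]), each NULL when absent.
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  he <- NULL
  if (!is.null(j$hand_eye)) {
    rot <- if (!is.null(j$hand_eye$quaternion)) as.numeric(j$hand_eye$quaternion)
           else matrix(as.numeric(unlist(j$hand_eye$rotation)), 3, 3, byrow = TRUE)
    he <- hand_eye_calibration(rot, as.numeric(j$hand_eye$offset_mm))
  }
  ic <- NULL
  if (!is.null(j$instrument)) {
    ic <- instrument_calibration(as.numeric(j$instrument$tip_mm),
                                 as.numeric(j$instrument$axis_mm))
  }
  list(hand_eye = he, instrument = ic)
}

#' Write calibration constants to JSON
#' @param he `hand_eye_calibration` or NULL.
#' @param ic `instrument_calibration` or NULL.
#' @param path output path.
#' @export
write_calibration <- function(he, ic, path) {
  j <- list()
  if (!is.null(he)) {
    j$hand_eye <- list(quaternion = rotmat_to_quat(he$rotation),
                       offset_mm = he$offset_mm)
  }
  if (!is.null(ic)) {
    j$instrument <- list(tip_mm = ic$tip_mm, axis_mm = ic$axis_mm)
  }
  jsonlite::write_json(j, path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a point cloud or triangle mesh as ASCII PLY
#'
#' @param x a `point_cloud`, a bare n x 3 matrix, or a `triangle_mesh`.
#' @param path output path.
#' @export
write_ply <- function(x, path) {
  if (inherits(x, "point_cloud")) x <- x$points
  if (inherits(x, "triangle_mesh")) {
    v <- x$vertices; f <- x$faces
  } else {
    v <- as.matrix(x); f <- NULL
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z"),
             con)
  if (!is.null(f)) {
    writeLines(c(sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices"), con)
  }
  writeLines("end_header", con)
  if (nrow(v)) {
    writeLines(sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
  }
  if (!is.null(f) && nrow(f)) {
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
  invisible(path)
}

#' Read an ASCII PLY file
#'
#' Supports the vertex/face layout written by [write_ply()].
#'
#' @param path PLY file path.
#' @return a `triangle_mesh` when faces are present, else an n x 3 matrix.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop("not a PLY file: ", path)
  end <- match("end_header", lines)
  if (is.na(end)) stop("PLY header not terminated")
  header <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", header, value = TRUE)))
  nf_line <- grep("^element face", header, value = TRUE)
  nf <- if (length(nf_line)) as.integer(sub("element face ", "", nf_line)) else 0L
  body <- lines[-seq_len(end)]
  v <- if (nv > 0) {
    do.call(rbind, lapply(strsplit(body[seq_len(nv)], " "),
                          function(x) as.numeric(x[1:3])))
  } else matrix(0, 0, 3)
  if (nf > 0) {
    f <- do.call(rbind, lapply(strsplit(body[nv + seq_len(nf)], " "),
                               function(x) as.integer(x[2:4]) + 1L))
    triangle_mesh(v, f)
  } else v
}

#' Write a disparity map as 16-bit fixed-point PNG plus validity mask
#'
#' Disparities are stored as `round(d * 16)` split into high/low bytes in
#' the first two channels of an RGB PNG (`<stem>.png`); the validity mask is
#' an 8-bit PNG (`<stem>_mask.png`, 255 = valid).  Invalid pixels are
#' written as 0 but carry no meaning.
#'
#' @param d a `disparity_map`.
#' @param stem output path without extension.
#' @return the disparity PNG path.
#' @export
write_disparity_png <- function(d, stem) {
  stopifnot(inherits(d, "disparity_map"))
  disp <- d$disparity
  disp[!d$valid] <- 0
  disp <- pmin(pmax(round(disp * 16), 0), 65535)
  img <- array(0, c(nrow(disp), ncol(disp), 3))
  img[, , 1] <- (disp %/% 256) / 255
  img[, , 2] <- (disp %% 256) / 255
  png::writePNG(img, paste0(stem, ".png"))
  png::writePNG(ifelse(d$valid, 1, 0), paste0(stem, "_mask.png"))
  invisible(paste0(stem, ".png"))
}

#' Read a disparity map written by [write_disparity_png()]
#' @param stem path stem used when writing.
#' @return a `disparity_map`.
#' @export
read_disparity_png <- function(stem) {
  img <- png::readPNG(paste0(stem, ".png"))
  disp <- (round(img[, , 1] * 255) * 256 + round(img[, , 2] * 255)) / 16
  mask <- png::readPNG(paste0(stem, "_mask.png")) > 0.5
  disparity_map(disp, mask)
}

#' Write an 8-bit grayscale image matrix as PNG
#' @param img numeric matrix, values 0-255.
#' @param path output path.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 255) / 255, path)
  invisible(path)
}

#' Read a PNG into an 8-bit grayscale matrix (0-255)
#' @param path PNG path.
#' @return numeric matrix.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img * 255
}
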