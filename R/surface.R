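# Point-cloud rearrangement onto a uniform cubic grid and non-interpolating
# isosurface extraction, plus the plane/sphere least-squares metrology used
# to grade reconstruction accuracy.

#' Triangle mesh
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.  Zero-area
#'   faces are dropped at construction.
#' @return object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0) {
    if (min(faces) < 1 || max(faces) > nrow(vertices)) {
      stop("face indices out of range")
    }
    a <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
    b <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    area2 <- sqrt(rowSums(cr^2))
    faces <- faces[area2 > 1e-12, , drop = FALSE]
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Rearrange a point cloud onto a uniform voxel-vertex grid
#'
#' Three families of axis-aligned slicing planes with common spacing `t`
#' form a cubic grid anchored at the per-axis minima of the cloud and
#' expanded by one cell on every side.  Each point is snapped per axis to the
#' nearer grid vertex: a projection distance of less than half the interval
#' keeps the lower vertex, otherwise the point moves to the next vertex;
#' exact half-distance ties snap to the lower vertex (deterministic).  Every
#' point is assigned to exactly one vertex.
#'
#' @param cloud `point_cloud` (or bare n x 3 matrix), non-empty.
#' @param interval_t grid spacing in mm (> 0).  The default 0.3 mm is half
#'   the 0.6 mm normal-search diameter used downstream.
#' @return object of class `voxel_grid` with fields `origin`, `interval_t`,
#'   `dims` (vertices per axis), `counts` (per-vertex point tally) and
#'   `occupancy` (logical, `counts >= 1`), plus the cloud's `frame`.
#' @export
rearrange_points <- function(cloud, interval_t = 0.3) {
  frame <- if (inherits(cloud, "point_cloud")) cloud$frame else "camera"
  pts <- if (inherits(cloud, "point_cloud")) cloud$points else as.matrix(cloud)
  if (nrow(pts) == 0) stop("cannot rearrange an empty point cloud")
  if (!(is.numeric(interval_t) && length(interval_t) == 1 && interval_t > 0)) {
    stop("interval_t must be a positive scalar (mm)")
  }
  t <- interval_t
  mins <- apply(pts, 2, min)
  maxs <- apply(pts, 2, max)
  origin <- mins - t
  dims <- as.integer(ceiling((maxs - origin) / t)) + 2L  # vertices per axis
  # nearest-vertex snap, exact halves to the lower vertex
  idx <- sapply(1:3, function(a) {
    as.integer(ceiling((pts[, a] - origin[a]) / t - 0.5))
  })
  idx <- matrix(idx, ncol = 3)
  if (min(idx) < 0 || any(idx >= rep(dims, each = nrow(idx)))) {
    stop("internal error: snapped index outside grid")  # cannot happen
  }
  lin <- idx[, 1] + dims[1] * (idx[, 2] + dims[2] * idx[, 3]) + 1L
  counts <- array(0L, dim = dims)
  tab <- tabulate(lin, nbins = prod(dims))
  counts[] <- tab
  structure(list(origin = origin, interval_t = t, dims = dims,
                 counts = counts, occupancy = counts >= 1L,
                 frame = frame, n_points = nrow(pts)),
            class = "voxel_grid")
}

#' Grid vertex coordinates of occupied vertices
#' @param grid `voxel_grid`.
#' @return n x 3 matrix of occupied vertex positions (mm).
#' @export
occupied_vertices <- function(grid) {
  idx <- which(grid$occupancy, arr.ind = TRUE) - 1L
  sweep(idx * grid$interval_t, 2, grid$origin, "+")
}

# --- case-table generation -------------------------------------------------
# The 256-entry cube case table is generated once per session from first
# principles rather than transcribed: for every corner-occupancy byte the cut
# edges (edges with one occupied endpoint) are linked into closed polygons by
# walking the cube faces, ambiguous faces (two diagonal corners occupied) are
# resolved by always keeping diagonal corners separated, and each polygon is
# fan-triangulated with its normal oriented from the occupied side to the
# empty side.  Surface vertices sit at edge midpoints (no interpolation).

.mc_env <- new.env(parent = emptyenv())

.mc_geometry <- function() {
  corners <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))[, 1:3]
  # edges between corners differing in exactly one coordinate
  edges <- NULL
  for (i in 1:7) for (j in (i + 1):8) {
    if (sum(abs(corners[i, ] - corners[j, ])) == 1) edges <- rbind(edges, c(i, j))
  }
  # faces: corners with a fixed coordinate, ordered counter-clockwise as
  # seen from outside the cube (so every shared edge is traversed in
  # opposite directions by its two faces)
  faces <- list()
  for (axis in 1:3) for (val in 0:1) {
    ids <- which(corners[, axis] == val)
    rest <- setdiff(1:3, axis)
    if (axis == 2) rest <- rev(rest)   # keep (u, v, axis) right-handed
    ang <- atan2(corners[ids, rest[2]] - 0.5, corners[ids, rest[1]] - 0.5)
    cyc <- ids[order(ang)]
    if (val == 0) cyc <- rev(cyc)
    faces[[length(faces) + 1]] <- cyc
  }
  list(corners = corners, edges = edges, faces = faces)
}

.mc_case <- function(occ, geo) {
  edges <- geo$edges; corners <- geo$corners
  cut <- which(occ[edges[, 1]] != occ[edges[, 2]])
  if (length(cut) == 0) return(list())
  edge_key <- function(i, j) which(edges[, 1] == min(i, j) & edges[, 2] == max(i, j))
  # Directed boundary walk: on every face (corners CCW from outside) each
  # maximal cyclic run of occupied corners contributes one directed crossing
  # from the cut edge where the run ends to the cut edge where it begins.
  # Diagonal (ambiguous) faces split into two runs, keeping diagonally
  # occupied corners separated; opposite traversal of shared edges makes the
  # directed segments close into consistently oriented cycles with the
  # occupied side behind the surface.
  nxt <- integer(nrow(edges))
  for (f in geo$faces) {
    fo <- occ[f]
    if (sum(fo) %in% c(0L, 4L)) next
    fedges <- sapply(1:4, function(k) edge_key(f[k], f[k %% 4 + 1]))
    for (k in which(fo == 1 & fo[c(4, 1:3)] == 0)) {   # run starts at k
      j <- k
      while (fo[j %% 4 + 1] == 1) j <- j %% 4 + 1      # run ends at j
      nxt[fedges[j]] <- fedges[(k - 2) %% 4 + 1]
    }
  }
  midpts <- (corners[edges[, 1], ] + corners[edges[, 2], ]) / 2
  unvisited <- cut
  tris <- NULL
  while (length(unvisited)) {
    start <- unvisited[1]
    cyc <- start
    cur <- nxt[start]
    while (cur != start) {
      cyc <- c(cyc, cur)
      cur <- nxt[cur]
    }
    unvisited <- setdiff(unvisited, cyc)
    for (k in 2:(length(cyc) - 1)) {
      tris <- rbind(tris, c(cyc[1], cyc[k + 1], cyc[k]))
    }
  }
  lapply(seq_len(nrow(tris)), function(i) tris[i, ])
}

.mc_table <- function() {
  if (!is.null(.mc_env$table)) return(.mc_env$table)
  geo <- .mc_geometry()
  table <- vector("list", 256)
  for (byte in 0:255) {
    occ <- as.integer(bitwAnd(bitwShiftR(byte, 0:7), 1L))
    table[[byte + 1]] <- .mc_case(occ, geo)
  }
  .mc_env$table <- table
  .mc_env$geo <- geo
  table
}

#' Extract the isosurface of an occupancy grid
#'
#' For every grid cube the eight corner occupancies form a byte indexing a
#' 256-case lookup table; surface vertices are placed at the midpoints of cut
#' cube edges (non-interpolating, so no per-vertex scalar field is needed)
#' and shared between neighbouring cubes.  Empty and full cubes emit nothing.
#'
#' @param grid `voxel_grid` from [rearrange_points()].
#' @return a `triangle_mesh` in the grid's frame (may be empty).
#' @export
extract_surface <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  tab <- .mc_table()
  geo <- .mc_env$geo
  occ <- grid$occupancy
  d <- grid$dims
  nc <- d - 1L                          # cubes per axis
  if (any(nc < 1L)) return(triangle_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  sub <- function(dx, dy, dz) {
    occ[(1 + dx):(nc[1] + dx), (1 + dy):(nc[2] + dy), (1 + dz):(nc[3] + dz)]
  }
  cfg <- array(0L, dim = nc)
  for (b in 0:7) {
    cr <- geo$corners[b + 1, ]
    cfg <- cfg + bitwShiftL(1L, b) * (sub(cr[1], cr[2], cr[3]) + 0L)
  }
  active <- which(cfg > 0L & cfg < 255L)
  if (length(active) == 0) {
    return(triangle_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  }
  ai <- arrayInd(active, nc) - 1L       # 0-based cube coords
  midpts <- (geo$corners[geo$edges[, 1], ] + geo$corners[geo$edges[, 2], ]) / 2
  tri_per_case <- lengths(tab)
  ntri <- tri_per_case[cfg[active] + 1L]
  vert_keys <- matrix(0L, sum(ntri) * 3, 3)
  row_at <- 0L
  for (k in seq_along(active)) {
    tris <- tab[[cfg[active[k]] + 1L]]
    if (length(tris) == 0) next
    base2 <- 2L * ai[k, ]               # cube origin on the half-index lattice
    for (tr in tris) {
      vert_keys[row_at + 1:3, ] <- sweep(matrix(as.integer(2 * midpts[tr, ]),
                                                ncol = 3), 2, base2, "+")
      row_at <- row_at + 3L
    }
  }
  key <- paste(vert_keys[, 1], vert_keys[, 2], vert_keys[, 3])
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  verts <- sweep(vert_keys[uk, , drop = FALSE] / 2 * grid$interval_t, 2,
                 grid$origin, "+")
  faces <- matrix(vid, ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces)
}

#' Least-squares plane fit
#'
#' Total least squares via the singular value decomposition of the centred
#' points: the plane normal is the direction of least variance and the RMSE
#' is the root-mean-square orthogonal point-to-plane distance.  R^2 is
#' computed on the depth (z) residuals of the regression `z ~ x + y`, the
#' quantity conventionally reported for depth-map metrology.
#'
#' @param cloud `point_cloud` or n x 3 matrix with at least 3 non-collinear
#'   points.
#' @return list with `normal` (unit 3-vector), `offset` (so that
#'   `normal . x = offset` on the plane), `rmse_mm`, `r2`.
#' @export
fit_plane <- function(cloud) {
  pts <- if (inherits(cloud, "point_cloud")) cloud$points else as.matrix(cloud)
  if (nrow(pts) < 3) stop("plane fit needs at least 3 points")
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  sv <- svd(X)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300)) {
    stop("degenerate plane fit: points are collinear")
  }
  normal <- sv$v[, 3]
  dist <- as.numeric(X %*% normal)
  rmse <- sqrt(mean(dist^2))
  r2 <- tryCatch(suppressWarnings({
    # exact planes trip lm's perfect-fit warning; R^2 = 1 is the right answer
    fit <- stats::lm(pts[, 3] ~ pts[, 1] + pts[, 2])
    summary(fit)$r.squared
  }), error = function(e) NA_real_)
  list(normal = normal, offset = sum(normal * ctr), rmse_mm = rmse, r2 = r2)
}

#' Least-squares sphere fit
#'
#' Algebraic initialisation (linear least squares on
#' `|p|^2 = 2 c . p + (r^2 - |c|^2)`) refined by Gauss-Newton minimisation of
#' the geometric radial residuals `||p - c|| - r`.
#'
#' @param cloud `point_cloud` or n x 3 matrix with at least 4 non-coplanar
#'   points.
#' @return list with `center` (3-vector, mm), `radius_mm`, `diameter_mm`,
#'   `rmse_mm` (RMS radial residual).
#' @export
fit_sphere <- function(cloud) {
  pts <- if (inherits(cloud, "point_cloud")) cloud$points else as.matrix(cloud)
  if (nrow(pts) < 4) stop("sphere fit needs at least 4 points")
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  sv <- svd(X)
  if (sv$d[3] < 1e-9 * max(sv$d[1], 1e-300)) {
    stop("degenerate sphere fit: points are coplanar")
  }
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  sol <- qr.solve(A, b)
  c0 <- sol[1:3]
  r0 <- sqrt(max(sol[4] + sum(c0^2), 0))
  theta <- c(c0, r0)
  for (it in 1:50) {
    diff <- sweep(pts, 2, theta[1:3])
    dist <- sqrt(rowSums(diff^2))
    res <- dist - theta[4]
    J <- cbind(-diff / dist, -1)
    step <- tryCatch(qr.solve(J, res), error = function(e) rep(0, 4))
    theta <- theta - step
    if (max(abs(step)) < 1e-12) break
  }
  diff <- sweep(pts, 2, theta[1:3])
  res <- sqrt(rowSums(diff^2)) - theta[4]
  list(center = unname(theta[1:3]), radius_mm = unname(theta[4]),
       diameter_mm = unname(2 * theta[4]), rmse_mm = sqrt(mean(res^2)))
}
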