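# Shared fixtures: random rigid transforms, random-dot stereograms, and an
# independent (loop-based) re-implementation of the path-aggregation
# recurrence used as the matching oracle.

random_rotation <- function() {
  rotation_about_axis(stats::rnorm(3), stats::runif(1, 0, pi))
}

random_rigid <- function(from, to, scale = 100) {
  rigid_transform(random_rotation(), stats::rnorm(3, 0, scale), from, to)
}

# wrap-free random-dot stereogram: right image is the left shifted so that
# left pixel x matches right pixel x - shift (positive disparity)
make_rds <- function(h, w, shift, density = 0.25, seed = 1) {
  set.seed(seed)
  base <- matrix(ifelse(stats::runif(h * (w + shift)) < density, 230, 20),
                 h, w + shift)
  list(left = base[, 1:w, drop = FALSE],
       right = base[, (shift + 1):(w + shift), drop = FALSE])
}

# --- independent SGM oracle (direct loops, integer arithmetic) -------------

oracle_census <- function(img, window = 7) {
  h <- nrow(img); w <- ncol(img); r <- window %/% 2
  codes <- vector("list", h * w)
  for (x in 1:w) for (y in 1:h) {
    bits <- integer(0)
    for (dy in -r:r) for (dx in -r:r) {
      if (dx == 0 && dy == 0) next
      yy <- min(max(y + dy, 1), h); xx <- min(max(x + dx, 1), w)
      bits <- c(bits, as.integer(img[yy, xx] < img[y, x]))
    }
    codes[[(x - 1) * h + y]] <- bits
  }
  codes
}

oracle_cost_volume <- function(left, right, dmin, dmax, window = 7) {
  h <- nrow(left); w <- ncol(left); D <- dmax - dmin + 1
  cl <- oracle_census(left, window); cr <- oracle_census(right, window)
  C <- array(0L, c(D, h, w))
  for (x in 1:w) for (y in 1:h) for (di in 1:D) {
    xr <- x - (dmin + di - 1)
    C[di, y, x] <- if (xr < 1 || xr > w) 0L else
      sum(cl[[(x - 1) * h + y]] != cr[[(xr - 1) * h + y]])
  }
  C
}

oracle_aggregate <- function(C, P1, P2, paths = 8) {
  D <- dim(C)[1]; h <- dim(C)[2]; w <- dim(C)[3]
  dirs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
               c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))[seq_len(paths)]
  S <- array(0L, c(D, h, w))
  for (dir in dirs) {
    dx <- dir[1]; dy <- dir[2]
    L <- array(0L, c(D, h, w))
    xs <- if (dx >= 0) 1:w else w:1
    ys <- if (dy >= 0) 1:h else h:1
    for (x in xs) for (y in ys) {
      xp <- x - dx; yp <- y - dy
      if (xp < 1 || xp > w || yp < 1 || yp > h) {
        L[, y, x] <- C[, y, x]
      } else {
        prev <- L[, yp, xp]
        minprev <- min(prev)
        for (d in 1:D) {
          cand <- prev[d]
          if (d > 1) cand <- min(cand, prev[d - 1] + P1)
          if (d < D) cand <- min(cand, prev[d + 1] + P1)
          cand <- min(cand, minprev + P2)
          L[d, y, x] <- C[d, y, x] + cand - minprev
        }
      }
    }
    S <- S + L
  }
  S
}

oracle_wta <- function(S, dmin) {
  D <- dim(S)[1]; h <- dim(S)[2]; w <- dim(S)[3]
  out <- matrix(0L, h, w)
  for (x in 1:w) for (y in 1:h) {
    out[y, x] <- dmin + which.min(S[, y, x]) - 1L
  }
  out
}

.unitize_test <- function(v) v / sqrt(sum(v^2))
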