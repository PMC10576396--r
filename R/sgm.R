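#' Default semi-global matching parameters
#'
#' The matching cost is a 7x7 census transform compared by Hamming distance —
#' a standard deterministic surrogate for mutual information in the SGM
#' literature.  Penalties apply to the path-aggregated costs: `P1` for a
#' one-pixel disparity step along a path, `P2` for larger jumps.
#'
#' @param d_min,d_max disparity search range in pixels (inclusive).
#' @param P1,P2 smoothness penalties on 8-bit census costs (`P1 < P2`).
#' @param window census window side length (odd, `window^2 - 1 <= 64`).
#' @param paths number of aggregation directions, 4 or 8.
#' @param lr_tol left-right consistency tolerance in pixels.
#' @param subpixel logical, parabolic refinement of valid disparities.
#' @return list of parameters for [sgm_disparity()].
#' @export
sgm_params <- function(d_min = 0, d_max = 64, P1 = 10, P2 = 120,
                       window = 7, paths = 8, lr_tol = 1, subpixel = TRUE) {
  stopifnot(d_min >= 0, d_min < d_max, P1 > 0, P2 >= P1,
            window %% 2 == 1, window^2 - 1 <= 64, paths %in% c(4, 8))
  list(d_min = as.integer(d_min), d_max = as.integer(d_max),
       P1 = as.integer(P1), P2 = as.integer(P2),
       window = as.integer(window), paths = as.integer(paths),
       lr_tol = lr_tol, subpixel = isTRUE(subpixel))
}

#' Semi-global matching disparity from a rectified stereo pair
#'
#' Census-cost semi-global matching: per-pixel Hamming costs over the
#' disparity search range are aggregated along 4 or 8 one-dimensional paths
#' with the standard `P1`/`P2` smoothness recurrence, followed by
#' winner-take-all selection.  A left-right consistency check (the right
#' disparity volume is derived from the same costs and aggregated
#' identically) marks inconsistent pixels invalid, as are pixels whose
#' aggregated minimum recurs at a non-adjacent disparity (featureless,
#' ambiguous matches).  Valid pixels get parabolic subpixel refinement.
#'
#' @param pair list with rectified `left` and `right` image matrices
#'   (0..255 grayscale).
#' @param params parameter list from [sgm_params()].
#' @return a `disparity_map` (disparities in pixels, left-image referenced).
#' @export
sgm_disparity <- function(pair, params = sgm_params()) {
  left <- pair$left; right <- pair$right
  stopifnot(is.matrix(left), is.matrix(right), all(dim(left) == dim(right)))
  if (params$d_max >= ncol(left)) {
    stop("d_max (", params$d_max, ") must be smaller than the image width (",
         ncol(left), ")")
  }
  costL <- .sgm_cost_volume_cpp(left, right, params$d_min, params$d_max,
                                params$window)
  costR <- .sgm_right_cost_cpp(costL, params$d_min)
  SL <- .sgm_aggregate_cpp(costL, params$P1, params$P2, params$paths)
  SR <- .sgm_aggregate_cpp(costR, params$P1, params$P2, params$paths)
  wL <- .sgm_wta_cpp(SL, params$d_min, params$subpixel)
  wR <- .sgm_wta_cpp(SR, params$d_min, FALSE)

  h <- nrow(left); w <- ncol(left)
  dL <- wL$d_int
  # left-right consistency: the right-image pixel x - d must map back within
  # lr_tol of the left disparity
  col0 <- matrix(rep(0:(w - 1), each = h), nrow = h)
  xr <- col0 - dL
  inb <- xr >= 0
  xr_c <- pmax(xr, 0)
  dR_at <- matrix(wR$d_int[cbind(as.vector(row(dL)), as.vector(xr_c) + 1L)],
                  nrow = h)
  valid <- inb & abs(dL - dR_at) <= params$lr_tol & !wL$tie
  disparity_map(wL$d_sub, valid, d_range = c(params$d_min, params$d_max))
}

#' Restrict a disparity map to speckle-covered pixels
#'
#' Only pixels actually lit by the speckle projector carry matching signal;
#' unlit background next to the speckle field can lock onto the dots of a
#' neighbouring surface and survive the consistency check.  This mask keeps
#' a pixel valid only when its (rectified left) image intensity exceeds
#' `min_level`.
#'
#' @param d `disparity_map`.
#' @param image rectified left image matrix (0..255).
#' @param min_level minimum intensity counting as speckle-covered.
#' @return a `disparity_map` with the tightened validity mask.
#' @export
mask_disparity_by_intensity <- function(d, image, min_level = 40) {
  stopifnot(inherits(d, "disparity_map"), all(dim(image) == dim(d$disparity)))
  disparity_map(d$disparity, d$valid & image > min_level, d$d_range)
}
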