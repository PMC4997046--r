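# Trilinear interpolation of a 3D array at physical points (n x 3, um).
# Points outside the volume evaluate to 0.
interp3 <- function(a, pts, voxel_size) {
  d <- dim(a)
  g <- sweep(pts, 2, voxel_size, "/")  # fractional 0-based indices
  i0 <- floor(g)
  w <- g - i0
  val <- numeric(nrow(pts))
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    iz <- i0[, 1] + cz
    iy <- i0[, 2] + cy
    ix <- i0[, 3] + cx
    wt <- (if (cz == 1) w[, 1] else 1 - w[, 1]) *
      (if (cy == 1) w[, 2] else 1 - w[, 2]) *
      (if (cx == 1) w[, 3] else 1 - w[, 3])
    ok <- iz >= 0 & iz < d[1] & iy >= 0 & iy < d[2] & ix >= 0 & ix < d[3] &
      wt > 0
    if (any(ok)) {
      lin <- iz[ok] + 1 + d[1] * iy[ok] + d[1] * d[2] * ix[ok]
      val[ok] <- val[ok] + wt[ok] * a[lin]
    }
  }
  val
}

# Intensity profile along a line: center +/- half_extent um in direction v.
profile_line <- function(a, voxel_size, center, v, half_extent, step) {
  t <- seq(-half_extent, half_extent, by = step)
  pts <- outer(t, v) + matrix(center, length(t), 3, byrow = TRUE)
  list(t = t, intensity = interp3(a, pts, voxel_size))
}

# Full width at half maximum of a sampled profile, with linear
# interpolation of the two outermost half-max crossings (scanning from the
# ends inward, robust to interior dips). NA if the profile never reaches
# half max from both sides.
fwhm <- function(t, intensity) {
  m <- max(intensity)
  if (m <= 0) return(NA_real_)
  half <- m / 2
  above <- intensity >= half
  if (!any(above)) return(NA_real_)
  i1 <- which(above)[1]
  i2 <- rev(which(above))[1]
  t_left <- if (i1 == 1) t[1] else {
    f <- (half - intensity[i1 - 1]) / (intensity[i1] - intensity[i1 - 1])
    t[i1 - 1] + f * (t[i1] - t[i1 - 1])
  }
  t_right <- if (i2 == length(t)) t[i2] else {
    f <- (half - intensity[i2 + 1]) / (intensity[i2] - intensity[i2 + 1])
    t[i2 + 1] + f * (t[i2] - t[i2 + 1])
  }
  t_right - t_left
}

# Unit directions spanning 180 degrees in the plane orthogonal to axis.
in_plane_directions <- function(axis, n_directions) {
  p1 <- if (abs(axis[2]) < 0.9) c(0, 1, 0) else c(0, 0, 1)
  p1 <- unit_vector(p1 - sum(p1 * axis) * axis)
  p2 <- c(axis[2] * p1[3] - axis[3] * p1[2],
          axis[3] * p1[1] - axis[1] * p1[3],
          axis[1] * p1[2] - axis[2] * p1[1])
  th <- (seq_len(n_directions) - 1) * pi / n_directions
  lapply(th, function(a) cos(a) * p1 + sin(a) * p2)
}

# Width of a channel's intensity cross-section at a point: FWHM of the
# profile along in-plane directions, maximized over directions.
cross_section_width <- function(a, voxel_size, center, axis, half_extent,
                                step, n_directions = 12L) {
  dirs <- in_plane_directions(axis, n_directions)
  widths <- vapply(dirs, function(v) {
    pr <- profile_line(a, voxel_size, center, v, half_extent, step)
    fwhm(pr$t, pr$intensity)
  }, numeric(1))
  if (all(is.na(widths))) return(NA_real_)
  max(widths, na.rm = TRUE)
}

#' Estimate the spindle axis and metaphase plate
#'
#' The axis is the principal eigenvector of the intensity-weighted second
#' moments (in physical um coordinates) of the tubulin channel within its
#' segmentation mask. The plate centre is the intensity-weighted centroid
#' of the DNA channel within its mask, and the plate normal is taken equal
#' to the axis. The axis sign is fixed deterministically (positive
#' component on the first non-degenerate coordinate), giving the two
#' half-spindles stable ids: 1 on the positive side, 2 on the negative.
#'
#' @param stack an \code{\link{image_stack}} (3D).
#' @param seg a \code{\link{segment_stack}} result (or list with
#'   segmentations for \code{tubulin} and \code{dna}).
#' @param anisotropy_tol if the two leading moment eigenvalues differ by
#'   less than this fraction the direction is ill-defined and an
#'   anisotropy error is signalled.
#' @return list with \code{axis} (unit 3-vector, (z,y,x)),
#'   \code{plate_center} (um), \code{plate_normal}, and the moment
#'   \code{eigenvalues}.
#' @export
estimate_axis_and_plate <- function(stack, seg, anisotropy_tol = 0.05) {
  tub_seg <- get_segmentation(seg, "tubulin")
  dna_seg <- get_segmentation(seg, "dna")
  tub <- stack$channels$tubulin
  if (!any(tub_seg$mask))
    stop_with_class("spindlemorph_degenerate_error", "empty tubulin mask")
  idx <- which(tub_seg$mask)
  w <- tub[idx]
  xyz <- voxel_coordinates(dim(tub), stack$voxel_size, idx)
  ctr <- colSums(xyz * w) / sum(w)
  u <- sweep(xyz, 2, ctr)
  cov <- crossprod(u * sqrt(w / sum(w)))
  ev <- eigen(cov, symmetric = TRUE)
  lam <- ev$values
  if ((lam[1] - lam[2]) / lam[1] < anisotropy_tol)
    stop_with_class("spindlemorph_anisotropy_error",
                    paste("tubulin distribution is near-isotropic",
                          "(leading moment eigenvalues within %.0f%%):",
                          "no principal axis"), 100 * anisotropy_tol)
  axis <- ev$vectors[, 1]
  # deterministic sign: largest-magnitude component made positive
  k <- which.max(abs(axis))
  if (axis[k] < 0) axis <- -axis

  dna <- stack$channels$dna
  if (!any(dna_seg$mask))
    stop_with_class("spindlemorph_degenerate_error", "empty dna mask")
  di <- which(dna_seg$mask)
  dw <- dna[di]
  dxyz <- voxel_coordinates(dim(dna), stack$voxel_size, di)
  plate <- colSums(dxyz * dw) / sum(dw)

  list(axis = axis, plate_center = plate, plate_normal = axis,
       eigenvalues = lam)
}
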