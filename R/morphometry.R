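#' Measure one half-spindle
#'
#' Computes the spindle-shape statistics used to quantify pole focus:
#' \itemize{
#'   \item \code{W_C}: metaphase plate width — FWHM of the DNA-channel
#'     intensity profile through the plate centre, perpendicular to the
#'     axis, maximized over in-plane directions (set
#'     \code{width_channel = "tubulin"} to measure the tubulin signal at
#'     the plate instead);
#'   \item \code{L}: half-spindle length — distance along the axis from
#'     the plate centre to the pole point, the farthest masked tubulin
#'     voxel on the requested side projected onto the axis;
#'   \item \code{W_S}: spindle width — FWHM of the tubulin cross-section
#'     in the plane at axial distance \code{fraction * L} from the plate;
#'   \item \code{focus_ratio = W_S / W_C}: near 1 for divergent,
#'     unfocused poles; near 0 for tightly focused poles.
#' }
#' All geometry is computed in physical micrometres, so anisotropic voxels
#' are handled transparently.
#'
#' @param stack an \code{\link{image_stack}} (3D).
#' @param seg a \code{\link{segment_stack}} result.
#' @param axis,plate_center from \code{\link{estimate_axis_and_plate}}.
#' @param fraction axial position of the width measurement as a fraction
#'   of L (default 0.75).
#' @param half_spindle_id 1 = positive side of the axis, 2 = negative.
#' @param width_channel channel carrying the plate-width signal
#'   (\code{"dna"} default).
#' @param width_method \code{"fwhm"} (default) or \code{"mask"}
#'   (extent of the segmentation mask along the profile).
#' @param n_directions in-plane directions scanned for the width maxima.
#' @return An object of class \code{"spindle_measurement"}: list with
#'   \code{W_C}, \code{L}, \code{W_S}, \code{focus_ratio}, \code{axis},
#'   \code{plate_center}, \code{pole_point}, \code{half_spindle_id},
#'   \code{fraction}.
#' @export
measure_half_spindle <- function(stack, seg, axis, plate_center,
                                 fraction = 0.75, half_spindle_id = 1L,
                                 width_channel = c("dna", "tubulin"),
                                 width_method = c("fwhm", "mask"),
                                 n_directions = 12L) {
  width_channel <- match.arg(width_channel)
  width_method <- match.arg(width_method)
  check_scalar_num(fraction, "fraction", 0, 1)
  if (fraction <= 0 || fraction >= 1)
    stopf("'fraction' must lie strictly inside (0, 1)")
  if (!half_spindle_id %in% c(1L, 2L))
    stopf("'half_spindle_id' must be 1 or 2")
  axis <- unit_vector(axis)
  sgn <- if (half_spindle_id == 1L) 1 else -1

  tub_seg <- get_segmentation(seg, "tubulin")
  tub <- stack$channels$tubulin
  vs <- stack$voxel_size
  idx <- which(tub_seg$mask)
  xyz <- voxel_coordinates(dim(tub), vs, idx)
  proj <- as.numeric(sweep(xyz, 2, plate_center) %*% axis) * sgn
  side <- proj > 0
  if (!any(side))
    stop_with_class("spindlemorph_missing_pole_error",
                    "no masked tubulin voxels on half-spindle side %d",
                    half_spindle_id)
  L <- max(proj[side])
  # tie-break the pole voxel: intensity first, then lowest (z,y,x) index
  at_max <- which(side & proj >= L - 1e-12)
  if (length(at_max) > 1L) {
    best <- order(-tub[idx[at_max]], idx[at_max])[1]
    at_max <- at_max[best]
  }
  pole_point <- plate_center + sgn * L * axis

  step <- min(vs[2:3]) / 2
  half_extent <- max(row_norms(sweep(xyz, 2, plate_center))) + 1

  wc_img <- stack$channels[[width_channel]]
  if (width_method == "fwhm") {
    W_C <- cross_section_width(wc_img, vs, plate_center, axis, half_extent,
                               step, n_directions)
    ws_center <- plate_center + sgn * fraction * L * axis
    W_S <- cross_section_width(tub, vs, ws_center, axis, half_extent,
                               step, n_directions)
  } else {
    wc_mask <- get_segmentation(seg, width_channel)$mask * 1
    W_C <- cross_section_width(wc_mask, vs, plate_center, axis, half_extent,
                               step, n_directions)
    ws_center <- plate_center + sgn * fraction * L * axis
    W_S <- cross_section_width(tub_seg$mask * 1, vs, ws_center, axis,
                               half_extent, step, n_directions)
  }
  if (is.na(W_C) || W_C <= 0)
    stop_with_class("spindlemorph_degenerate_error",
                    "could not measure plate width (empty %s profile)",
                    width_channel)
  structure(list(W_C = W_C, L = L, W_S = W_S,
                 focus_ratio = W_S / W_C,
                 axis = axis, plate_center = plate_center,
                 pole_point = pole_point,
                 half_spindle_id = as.integer(half_spindle_id),
                 fraction = fraction),
            class = "spindle_measurement")
}

#' @export
print.spindle_measurement <- function(x, ...) {
  cat(sprintf(
    "<spindle_measurement> half-spindle %d: W_C=%.2f um, L=%.2f um, W_S=%.2f um, W_S/W_C=%.3f\n",
    x$half_spindle_id, x$W_C, x$L, x$W_S, x$focus_ratio))
  invisible(x)
}

#' Measure a whole cell: both half-spindles plus a cell-level summary
#'
#' Runs segmentation, axis estimation and \code{\link{measure_half_spindle}}
#' for both sides, returning one row per half-spindle and the per-cell
#' means (the two sides averaged).
#'
#' @param stack an \code{\link{image_stack}} (3D).
#' @param seg optional precomputed \code{\link{segment_stack}} result.
#' @param ... passed to \code{\link{measure_half_spindle}}.
#' @return list with \code{halves} (data.frame, one row per half-spindle),
#'   \code{cell} (one-row data.frame of means), \code{axis},
#'   \code{plate_center}.
#' @export
measure_spindle <- function(stack, seg = NULL, ...) {
  if (is.null(seg)) seg <- segment_stack(stack)
  ap <- estimate_axis_and_plate(stack, seg)
  halves <- lapply(1:2, function(id)
    measure_half_spindle(stack, seg, ap$axis, ap$plate_center,
                         half_spindle_id = id, ...))
  hdf <- do.call(rbind, lapply(halves, function(h)
    data.frame(half_spindle_id = h$half_spindle_id, W_C = h$W_C, L = h$L,
               W_S = h$W_S, focus_ratio = h$focus_ratio)))
  cell <- data.frame(W_C = mean(hdf$W_C), L = mean(hdf$L),
                     W_S = mean(hdf$W_S),
                     focus_ratio = mean(hdf$focus_ratio))
  list(halves = hdf, cell = cell, axis = ap$axis,
       plate_center = ap$plate_center, measurements = halves)
}

#' Count spindles and poles in a segmented stack
#'
#' Spindles are 26-connected components of the tubulin mask, with
#' components whose gap is smaller than \code{min_gap} um merged (two
#' spindles separated by at least \code{min_gap} of clear space stay
#' distinct). Poles of a component are found as radial-extent peaks: the
#' connected clusters of mask voxels whose distance from the component's
#' intensity centroid (or a supplied \code{plate_center}) exceeds
#' \code{pole_frac} of the component's maximal radius.
#'
#' @param seg a \code{\link{segment_stack}} result (or a tubulin
#'   \code{"segmentation"}).
#' @param stack the \code{\link{image_stack}} the segmentation came from
#'   (for voxel size and intensities).
#' @param min_gap um; smaller gaps between mask components are bridged.
#' @param pole_frac fraction of the maximal centre-to-voxel distance a
#'   voxel must exceed to count as pole material.
#' @param min_pole_voxels pole clusters smaller than this are ignored.
#' @param plate_center optional reference point for radial distance.
#' @return An object of class \code{"topology_result"}: list with
#'   \code{n_spindle_components}, \code{components} (data.frame with voxel
#'   counts, centroids and \code{n_poles}), and \code{labels} (the merged
#'   label array).
#' @export
detect_topology <- function(seg, stack, min_gap = 2, pole_frac = 0.7,
                            min_pole_voxels = 5L, plate_center = NULL) {
  tub_seg <- get_segmentation(seg, "tubulin")
  mask <- tub_seg$mask
  vs <- stack$voxel_size
  if (!any(mask))
    return(structure(list(n_spindle_components = 0L,
                          components = data.frame(), labels = array(0L, dim(mask))),
                     class = "topology_result"))
  # bridge sub-min_gap separations: box dilation by min_gap/2 per axis,
  # then component labels of the dilated mask carried back to the mask
  dil <- mask * 1
  for (i in 1:3) {
    r <- floor((min_gap / 2) / vs[i])
    if (r >= 1) {
      n <- dim(dil)[i]
      B <- outer(seq_len(n), seq_len(n), function(a, b) abs(a - b) <= r) * 1
      perm <- c(i, setdiff(1:3, i))
      ap <- aperm(dil, perm)
      m <- matrix(ap, nrow = dim(dil)[i])
      dil <- aperm(array(B %*% m, dim(dil)[perm]), order(perm))
    }
  }
  lab_d <- label_components(dil > 0)
  lab <- array(0L, dim(mask))
  lab[mask] <- lab_d[mask]
  ids <- sort(unique(lab[lab > 0L]))

  tub <- stack$channels$tubulin
  comps <- do.call(rbind, lapply(ids, function(id) {
    idx <- which(lab == id)
    w <- tub[idx]
    xyz <- voxel_coordinates(dim(mask), vs, idx)
    ctr <- if (is.null(plate_center)) colSums(xyz * w) / sum(w) else plate_center
    r <- row_norms(sweep(xyz, 2, ctr))
    rmax <- max(r)
    far <- r >= pole_frac * rmax
    far_mask <- array(FALSE, dim(mask))
    far_mask[idx[far]] <- TRUE
    pl <- label_components(far_mask)
    sizes <- tabulate(pl[pl > 0L])
    n_poles <- max(1L, sum(sizes >= min_pole_voxels))
    data.frame(component = id, n_voxels = length(idx),
               centroid_z = ctr[1], centroid_y = ctr[2], centroid_x = ctr[3],
               max_radius = rmax, n_poles = n_poles)
  }))
  structure(list(n_spindle_components = length(ids), components = comps,
                 labels = lab),
            class = "topology_result")
}

#' @export
print.topology_result <- function(x, ...) {
  cat(sprintf("<topology_result> %d spindle component(s); poles: %s\n",
              x$n_spindle_components,
              paste(x$components$n_poles, collapse = ", ")))
  invisible(x)
}
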