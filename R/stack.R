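#' Multi-channel image stack
#'
#' Container for a two-channel fluorescence stack: channel \code{"tubulin"}
#' (microtubules) and channel \code{"dna"} (chromosomes). Each channel is a
#' 3D \code{(z, y, x)} or 4D \code{(t, z, y, x)} array of non-negative
#' intensities. All geometry in this package is computed in physical
#' micrometres: voxel index \code{(i, j, k)} (0-based) maps to
#' \code{(i*dz, j*dy, k*dx)} um, measured at voxel centres.
#'
#' @param channels named list of numeric arrays, all the same shape; names
#'   are the channel labels (conventionally \code{tubulin} and \code{dna}).
#' @param voxel_size numeric length-3 vector \code{(dz, dy, dx)} in um.
#' @param time_step frame interval in minutes; required for 4D stacks.
#'
#' @return An object of class \code{"image_stack"}: a list with elements
#'   \code{channels}, \code{voxel_size}, \code{time_step}, \code{ndim}.
#' @export
image_stack <- function(channels, voxel_size, time_step = NULL) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stopf("'channels' must be a named list of arrays")
  dims <- lapply(channels, dim)
  nd <- unique(vapply(dims, length, 1L))
  if (length(nd) != 1L || !nd %in% c(3L, 4L))
    stopf("all channels must be 3D (z,y,x) or 4D (t,z,y,x) arrays")
  if (length(unique(lapply(dims, identity))) != 1L)
    stopf("all channels must share the same shape")
  for (ch in names(channels)) {
    v <- channels[[ch]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0))
      stopf("channel '%s' must be non-negative and free of NA", ch)
  }
  if (!is.numeric(voxel_size) || length(voxel_size) != 3L ||
      any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stopf("'voxel_size' must be 3 positive numbers (dz, dy, dx) in um")
  if (nd == 4L) {
    if (is.null(time_step))
      stopf("4D stacks require 'time_step' (minutes)")
    check_scalar_num(time_step, "time_step", 0, strict_lower = TRUE)
  }
  structure(
    list(channels = channels,
         voxel_size = as.numeric(voxel_size),
         time_step = if (nd == 4L) as.numeric(time_step) else NULL,
         ndim = as.integer(nd)),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_stack> %s, channels: %s\n",
              paste(d, collapse = " x "),
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  voxel size (dz,dy,dx): %s um%s\n",
              paste(format(x$voxel_size), collapse = ", "),
              if (!is.null(x$time_step))
                sprintf("; time step %g min", x$time_step) else ""))
  invisible(x)
}

#' Number of time points of a stack (1 for 3D stacks)
#' @param stack an \code{image_stack}.
#' @export
n_frames <- function(stack) {
  if (stack$ndim == 3L) 1L else dim(stack$channels[[1]])[1]
}

#' Extract one time point of a 4D stack as a 3D stack
#' @param stack an \code{image_stack}.
#' @param t frame index (1-based).
#' @export
stack_frame <- function(stack, t) {
  if (stack$ndim == 3L) {
    if (t != 1L) stopf("3D stack has a single frame")
    return(stack)
  }
  nt <- dim(stack$channels[[1]])[1]
  if (t < 1L || t > nt) stopf("frame %d out of range 1..%d", t, nt)
  ch <- lapply(stack$channels, function(a) {
    d <- dim(a)
    array(a[t, , , ], dim = d[-1])
  })
  image_stack(ch, stack$voxel_size)
}

# Physical coordinates (um) of every voxel centre of a 3D array, as an
# n x 3 matrix in (z, y, x) order, matching a flattened logical mask
# (column-major, i.e. which(mask)).
voxel_coordinates <- function(dim3, voxel_size, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(prod(dim3))
  ai <- arrayInd(idx, dim3)
  cbind(z = (ai[, 1] - 1) * voxel_size[1],
        y = (ai[, 2] - 1) * voxel_size[2],
        x = (ai[, 3] - 1) * voxel_size[3])
}
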