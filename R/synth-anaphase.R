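#' Render a synthetic anaphase time-lapse series
#'
#' Emulates live imaging of a dividing meiocyte: a 4D two-channel stack at
#' \code{time_step}-minute intervals in which two chromosome masses move
#' apart along the spindle axis at \code{speed} um/min each (one per pole)
#' from \code{anaphase_onset} onward. The tubulin channel renders the
#' (static) spindle of \code{truth}; the DNA channel renders the two
#' moving masses as uniform balls. Ground-truth centroids are returned per
#' frame for recovery tests.
#'
#' @param truth a \code{\link{spindle_truth}} describing the spindle.
#' @param speed poleward speed of each chromosome mass, um/min (>= 0).
#' @param n_timepoints number of frames (>= 2).
#' @param time_step frame interval, minutes (default 5, as in 5-min
#'   interval live acquisitions).
#' @param optics an \code{\link{optics}} model.
#' @param anaphase_onset minutes; masses are stationary before this time.
#' @param mass_diameter diameter (um) of each chromosome mass.
#' @param initial_separation centre-to-centre distance (um) of the two
#'   masses at t = 0.
#' @param voxel_size (dz, dy, dx) in um.
#' @return list with \code{stack} (4D \code{\link{image_stack}}) and
#'   \code{truth}: a list of class \code{"anaphase_truth"} with
#'   \code{time} (minutes), \code{chromosome_mass_centroids} (array
#'   t x 2 x 3, (z,y,x) um), \code{spindle_centroid} (t x 3),
#'   \code{poleward_speed_true}, \code{anaphase_onset}, and the spindle
#'   \code{truth}.
#' @export
generate_anaphase_series <- function(truth, speed, n_timepoints,
                                     time_step = 5, optics = NULL,
                                     anaphase_onset = 0,
                                     mass_diameter = 5,
                                     initial_separation = 8,
                                     voxel_size = c(1, 0.2, 0.2)) {
  stopifnot(inherits(truth, "spindle_truth"))
  if (is.null(optics)) optics <- default_optics()
  check_scalar_num(speed, "speed", 0)
  if (n_timepoints < 2L) stopf("'n_timepoints' must be >= 2")
  check_scalar_num(time_step, "time_step", 0, strict_lower = TRUE)
  check_scalar_num(anaphase_onset, "anaphase_onset", 0)

  axis <- truth$plate_normal
  c0 <- truth$plate_center
  tt <- (seq_len(n_timepoints) - 1) * time_step
  excursion <- pmax(0, tt - anaphase_onset) * speed
  half_sep <- initial_separation / 2 + excursion
  centroids <- array(NA_real_, c(n_timepoints, 2, 3))
  for (i in seq_len(n_timepoints)) {
    centroids[i, 1, ] <- c0 + axis * half_sep[i]
    centroids[i, 2, ] <- c0 - axis * half_sep[i]
  }
  spindle_centroid <- matrix(c0, n_timepoints, 3, byrow = TRUE)

  # volume must hold the spindle and the farthest mass positions
  max_reach <- max(half_sep) + mass_diameter / 2
  pts <- rbind(truth$pole_positions,
               c0 + axis * max_reach, c0 - axis * max_reach)
  lo <- apply(pts, 2, min) - truth$plate_width_true / 2 -
    3 * optics$psf_sigma - voxel_size
  if (any(lo < 0)) {
    shift <- pmax(0, -lo)
    truth <- shift_truth(truth, shift)
    c0 <- truth$plate_center
    for (i in seq_len(n_timepoints)) {
      centroids[i, 1, ] <- centroids[i, 1, ] + shift
      centroids[i, 2, ] <- centroids[i, 2, ] + shift
    }
    spindle_centroid <- sweep(spindle_centroid, 2, shift, "+")
    pts <- sweep(pts, 2, shift, "+")
  }
  hi <- apply(pts, 2, max) + truth$plate_width_true / 2 +
    3 * optics$psf_sigma + voxel_size
  shape <- as.integer(ceiling(hi / voxel_size) + 1L)

  R <- mass_diameter / 2
  with_seed(truth$rng_seed, {
    dens <- render_density(truth, shape, voxel_size)
    tub0 <- psf_blur(dens$tubulin, optics$psf_sigma, voxel_size)
    coords <- voxel_coordinates(shape, voxel_size)
    tub <- array(0, c(n_timepoints, shape))
    dna <- array(0, c(n_timepoints, shape))
    for (i in seq_len(n_timepoints)) {
      d0 <- array(0, shape)
      for (m in 1:2) {
        u <- sweep(coords, 2, centroids[i, m, ])
        d0[rowSums(u^2) <= R^2] <- 1
      }
      d0 <- psf_blur(d0, optics$psf_sigma, voxel_size)
      tub[i, , , ] <- apply_noise(tub0, optics)
      dna[i, , , ] <- apply_noise(d0, optics)
    }
    stk <- image_stack(list(tubulin = tub, dna = dna),
                       voxel_size = voxel_size, time_step = time_step)
  })
  at <- structure(
    list(time = tt,
         chromosome_mass_centroids = centroids,
         spindle_centroid = spindle_centroid,
         poleward_speed_true = speed,
         anaphase_onset = anaphase_onset,
         mass_diameter = mass_diameter,
         initial_separation = initial_separation,
         spindle_truth = truth),
    class = "anaphase_truth")
  list(stack = stk, truth = at)
}

# translate a spindle_truth rigidly by a (z,y,x) um vector
shift_truth <- function(truth, shift) {
  truth$pole_positions <- sweep(truth$pole_positions, 2, shift, "+")
  truth$plate_centers <- sweep(truth$plate_centers, 2, shift, "+")
  truth$plate_center <- truth$plate_center + shift
  truth
}
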