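#' Ground-truth description of a synthetic meiotic spindle
#'
#' Parameterizes the phantom generator. The central dial is
#' \code{divergence}: 0 renders fibers that converge linearly from the
#' metaphase plate to a point pole (a tightly focused, wild-type-like
#' spindle); 1 renders fibers that never converge, a uniform cylinder of
#' plate width (a fully divergent, mutant-like spindle). Intermediate values
#' interpolate the fiber envelope linearly. Multipolar and multi-spindle
#' configurations are supported through \code{n_poles_per_spindle} and
#' \code{n_spindles}.
#'
#' @param plate_width_true diameter (um) of the chromosome mass at the
#'   metaphase plate; the fiber bundle has the same diameter at the plate.
#' @param half_length_true plate-to-pole distance L (um).
#' @param divergence dimensionless in \[0, 1\]; see Description.
#' @param n_spindles number of separate spindles in the cell (parallel,
#'   offset laterally by \code{spindle_gap} plus one plate width).
#' @param n_poles_per_spindle 2 for a bipolar spindle; 3 adds a third pole
#'   at right angles to the main axis (tripolar).
#' @param fiber_count number of rendered fibers per half-spindle. The
#'   default is high enough that individual fibers are not resolved at the
#'   default optics, as in real tubulin immunostains.
#' @param plate_center 3D point (z, y, x) in um; default places the (first)
#'   spindle at the centre of the default rendering volume.
#' @param axis unit 3-vector (z, y, x), the spindle axis; default +x.
#' @param plate_thickness full thickness (um) of the chromosome mass along
#'   the axis.
#' @param spindle_gap clear space (um) between the envelopes of adjacent
#'   spindles when \code{n_spindles > 1}.
#' @param chromosome_shift 3D vector (um) displacing the chromosome mass
#'   from the plate centre (used to emulate poor congression).
#' @param rng_seed integer seed controlling fiber sampling and noise.
#'
#' @return An object of class \code{"spindle_truth"}; a list carrying the
#'   parameters plus derived \code{pole_positions} (one row per pole, in
#'   (z, y, x) um), \code{plate_centers} (one row per spindle) and
#'   \code{plate_normal}.
#' @export
spindle_truth <- function(plate_width_true = 10,
                          half_length_true = 12,
                          divergence = 0,
                          n_spindles = 1L,
                          n_poles_per_spindle = 2L,
                          fiber_count = 2000L,
                          plate_center = NULL,
                          axis = c(0, 0, 1),
                          plate_thickness = 3,
                          spindle_gap = 5,
                          chromosome_shift = c(0, 0, 0),
                          rng_seed = 1L) {
  check_scalar_num(plate_width_true, "plate_width_true", 0, strict_lower = TRUE)
  check_scalar_num(half_length_true, "half_length_true", 0, strict_lower = TRUE)
  check_scalar_num(divergence, "divergence", 0, 1)
  check_scalar_num(plate_thickness, "plate_thickness", 0, strict_lower = TRUE)
  if (n_spindles < 1L || n_poles_per_spindle < 2L || fiber_count < 1L)
    stopf("n_spindles >= 1, n_poles_per_spindle >= 2, fiber_count >= 1 required")
  axis <- unit_vector(as.numeric(axis))

  # lateral direction perpendicular to the axis, used to offset extra
  # spindles and to place a third pole
  perp <- if (abs(axis[2]) < 0.9) c(0, 1, 0) else c(0, 0, 1)
  perp <- unit_vector(perp - sum(perp * axis) * axis)

  pitch <- plate_width_true + spindle_gap
  plate_offsets <- t(vapply(seq_len(n_spindles), function(s) {
    perp * (s - 1 - (n_spindles - 1) / 2) * pitch
  }, numeric(3)))

  pole_offsets <- do.call(rbind, lapply(seq_len(n_spindles), function(s) {
    c0 <- plate_offsets[s, ]
    p <- rbind(c0 + axis * half_length_true,
               c0 - axis * half_length_true)
    if (n_poles_per_spindle >= 3L) {
      extra <- t(vapply(seq_len(n_poles_per_spindle - 2L), function(k) {
        c0 + perp * half_length_true * (-1)^(k - 1)
      }, numeric(3)))
      p <- rbind(p, extra)
    }
    p
  }))

  if (is.null(plate_center)) {
    # auto-place so the whole geometry sits >= 3 um from the volume origin
    lo <- apply(rbind(pole_offsets, plate_offsets), 2, min) -
      plate_width_true / 2
    plate_center <- 3 - lo
  }
  plate_center <- as.numeric(plate_center)
  plate_centers <- sweep(plate_offsets, 2, plate_center, "+")
  poles <- sweep(pole_offsets, 2, plate_center, "+")

  structure(
    list(pole_positions = poles,
         plate_center = plate_centers[1, ],
         plate_centers = plate_centers,
         plate_normal = axis,
         plate_width_true = plate_width_true,
         half_length_true = half_length_true,
         divergence = divergence,
         n_spindles = as.integer(n_spindles),
         n_poles_per_spindle = as.integer(n_poles_per_spindle),
         fiber_count = as.integer(fiber_count),
         plate_thickness = plate_thickness,
         chromosome_shift = as.numeric(chromosome_shift),
         rng_seed = as.integer(rng_seed)),
    class = "spindle_truth")
}

#' Optical model for the synthetic microscope
#'
#' The rendering pipeline blurs the noiseless fluorophore-density image
#' with an anisotropic Gaussian point-spread function, scales it to photon
#' counts, applies Poisson shot noise, and adds Gaussian read noise.
#'
#' @param psf_sigma Gaussian PSF sigma per axis (dz, dy, dx) in um.
#' @param background mean background photon level added before shot noise.
#' @param photon_scale photons per unit of rendered fluorophore density.
#' @param read_noise_sd standard deviation of additive Gaussian camera
#'   noise (intensity units); negative excursions are clipped at zero.
#' @param shot_noise logical; apply Poisson shot noise?
#' @export
optics <- function(psf_sigma = c(0.6, 0.25, 0.25), background = 2,
                   photon_scale = 2000, read_noise_sd = 2,
                   shot_noise = TRUE) {
  if (length(psf_sigma) != 3L || any(psf_sigma < 0))
    stopf("'psf_sigma' must be 3 non-negative sigmas (dz, dy, dx)")
  check_scalar_num(background, "background", 0)
  check_scalar_num(photon_scale, "photon_scale", 0)
  check_scalar_num(read_noise_sd, "read_noise_sd", 0)
  list(psf_sigma = as.numeric(psf_sigma), background = background,
       photon_scale = photon_scale, read_noise_sd = read_noise_sd,
       shot_noise = isTRUE(shot_noise))
}

default_optics <- function() optics()

#' Noise-free optics (PSF blur only)
#' @param psf_sigma Gaussian PSF sigma per axis (dz, dy, dx) in um.
#' @export
optics_noiseless <- function(psf_sigma = c(0.6, 0.25, 0.25)) {
  optics(psf_sigma = psf_sigma, background = 0, photon_scale = 1,
         read_noise_sd = 0, shot_noise = FALSE)
}

# Default rendering volume for a truth object: tight box around poles and
# plate envelope plus a margin of 3 PSF sigma (and one voxel of slack).
default_shape <- function(truth, voxel_size, psf_sigma) {
  pts <- rbind(truth$pole_positions, truth$plate_centers)
  r <- truth$plate_width_true / 2
  lo <- apply(pts, 2, min) - r - 3 * psf_sigma - voxel_size
  hi <- apply(pts, 2, max) + r + 3 * psf_sigma + voxel_size
  lo <- pmin(lo, 0)
  ceiling(hi / voxel_size) + 1L
}

# Separable Gaussian blur along one array dimension, sigma in voxels.
# Zero-padded borders; kernel normalized to unit sum.
conv_dim <- function(a, sigma_vox, dim_i) {
  if (sigma_vox <= 1e-8) return(a)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
  k <- k / sum(k)
  d <- dim(a)
  perm <- c(dim_i, setdiff(seq_along(d), dim_i))
  ap <- aperm(a, perm)
  n <- d[dim_i]
  m <- matrix(ap, nrow = n)
  # banded convolution matrix
  B <- matrix(0, n, n)
  idx <- outer(seq_len(n), seq_len(n), function(i, j) i - j)
  sel <- abs(idx) <= r
  B[sel] <- k[idx[sel] + r + 1]
  res <- B %*% m
  out <- array(res, dim = d[perm])
  aperm(out, order(perm))
}

psf_blur <- function(a, psf_sigma, voxel_size) {
  for (i in 1:3) a <- conv_dim(a, psf_sigma[i] / voxel_size[i], i)
  a
}

apply_noise <- function(signal, opt) {
  mean_photons <- opt$photon_scale * signal + opt$background
  img <- if (opt$shot_noise) {
    array(rpois(length(mean_photons), lambda = mean_photons),
          dim = dim(mean_photons))
  } else mean_photons
  if (opt$read_noise_sd > 0)
    img <- img + array(rnorm(length(img), sd = opt$read_noise_sd), dim(img))
  img[img < 0] <- 0
  img
}

# Deposit unit weights at physical points (n x 3, (z,y,x) um) into a voxel
# grid by nearest-voxel binning. Errors if any point falls outside.
splat_points <- function(pts, dim3, voxel_size, weights = NULL) {
  ijk <- round(sweep(pts, 2, voxel_size, "/")) + 1
  if (any(ijk < 1) || any(ijk[, 1] > dim3[1]) || any(ijk[, 2] > dim3[2]) ||
      any(ijk[, 3] > dim3[3]))
    stopf(paste("rendering volume too small: fiber or mass points fall",
                "outside the stack; enlarge 'shape' (poles plus a 3 sigma",
                "PSF margin must fit)"))
  lin <- ijk[, 1] + dim3[1] * (ijk[, 2] - 1) + dim3[1] * dim3[2] * (ijk[, 3] - 1)
  if (is.null(weights)) weights <- rep(1, nrow(pts))
  acc <- rep(0, prod(dim3))
  tab <- rowsum(weights, group = lin)
  acc[as.numeric(rownames(tab))] <- tab[, 1]
  array(acc, dim = dim3)
}

# Render the noiseless fluorophore-density channels for a truth object.
render_density <- function(truth, dim3, voxel_size) {
  axis <- truth$plate_normal
  R <- truth$plate_width_true / 2
  d <- truth$divergence
  # orthonormal in-plane basis of the plate disc
  perp1 <- if (abs(axis[2]) < 0.9) c(0, 1, 0) else c(0, 0, 1)
  perp1 <- unit_vector(perp1 - sum(perp1 * axis) * axis)
  perp2 <- c(axis[2] * perp1[3] - axis[3] * perp1[2],
             axis[3] * perp1[1] - axis[1] * perp1[3],
             axis[1] * perp1[2] - axis[2] * perp1[1])

  step <- 0.5 * min(voxel_size[2:3])
  tub_pts <- vector("list", nrow(truth$pole_positions) * 1L)
  pole_of_spindle <- rep(seq_len(truth$n_spindles),
                         each = truth$n_poles_per_spindle)
  li <- 0L
  for (p_i in seq_len(nrow(truth$pole_positions))) {
    s <- pole_of_spindle[p_i]
    c0 <- truth$plate_centers[s, ]
    pole <- truth$pole_positions[p_i, ]
    # fiber starting points: uniform over the plate disc
    u <- stats::runif(truth$fiber_count)
    th <- stats::runif(truth$fiber_count, 0, 2 * pi)
    rr <- R * sqrt(u)
    offs <- outer(rr * cos(th), perp1) + outer(rr * sin(th), perp2)
    axl <- sqrt(sum((pole - c0)^2))
    nstep <- max(2L, ceiling(axl / step))
    f <- (seq_len(nstep) - 0.5) / nstep
    # position(fiber i, fraction f) = c0 + f*(pole - c0) + offs_i*((1-f) + f*d)
    base <- outer(f, pole - c0)           # nstep x 3
    shrink <- (1 - f) + f * d             # nstep
    # expand: for all fibers x steps
    n_fib <- truth$fiber_count
    pts <- matrix(0, n_fib * nstep, 3)
    for (k in 1:3) {
      pts[, k] <- rep(offs[, k], times = nstep) *
        rep(shrink, each = n_fib) +
        rep(base[, k], each = n_fib) + c0[k]
    }
    li <- li + 1L
    tub_pts[[li]] <- pts
  }
  tub_pts <- do.call(rbind, tub_pts)
  tubulin <- splat_points(tub_pts, dim3, voxel_size)

  # chromosome mass: uniform ellipsoid per plate, optionally displaced
  dna <- array(0, dim3)
  coords <- voxel_coordinates(dim3, voxel_size)
  a_ax <- truth$plate_thickness / 2
  for (s in seq_len(truth$n_spindles)) {
    c0 <- truth$plate_centers[s, ] + truth$chromosome_shift
    u <- sweep(coords, 2, c0)
    ax_comp <- as.numeric(u %*% axis)
    lat2 <- rowSums(u^2) - ax_comp^2
    inside <- (ax_comp / a_ax)^2 + lat2 / R^2 <= 1
    dna[inside] <- 1
  }
  list(tubulin = tubulin, dna = dna)
}

#' Render a synthetic metaphase meiocyte stack
#'
#' Produces a two-channel 3D stack from a \code{\link{spindle_truth}}:
#' the tubulin channel renders \code{fiber_count} fibers per half-spindle
#' running from points sampled uniformly on the metaphase-plate disc toward
#' each pole, with lateral spread at axial fraction \code{f} equal to the
#' plate radius times \code{(1 - f) + f * divergence}; the DNA channel
#' renders a uniform ellipsoidal chromosome mass of diameter
#' \code{plate_width_true} at the plate. Both channels are PSF-blurred and
#' noised according to \code{optics}. Identical inputs and seed give
#' bitwise-identical output.
#'
#' @param truth a \code{\link{spindle_truth}}.
#' @param optics an \code{\link{optics}} model.
#' @param shape voxel dimensions (nz, ny, nx); default is a tight box
#'   around the geometry plus a 3-sigma PSF margin.
#' @param voxel_size (dz, dy, dx) in um.
#' @return list with elements \code{stack} (an \code{\link{image_stack}})
#'   and \code{truth} (the ground truth, echoed for recovery tests).
#' @export
generate_spindle_stack <- function(truth,
                                   optics = NULL,
                                   shape = NULL,
                                   voxel_size = c(1, 0.2, 0.2)) {
  stopifnot(inherits(truth, "spindle_truth"))
  if (is.null(optics)) optics <- default_optics()
  voxel_size <- as.numeric(voxel_size)
  if (is.null(shape))
    shape <- default_shape(truth, voxel_size, optics$psf_sigma)
  shape <- as.integer(shape)

  with_seed(truth$rng_seed, {
    dens <- render_density(truth, shape, voxel_size)
    tub <- psf_blur(dens$tubulin, optics$psf_sigma, voxel_size)
    dna <- psf_blur(dens$dna, optics$psf_sigma, voxel_size)
    stk <- image_stack(
      list(tubulin = apply_noise(tub, optics),
           dna = apply_noise(dna, optics)),
      voxel_size = voxel_size)
  })
  list(stack = stk, truth = truth)
}
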