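test_that("segmentation rejects degenerate images and recovers exact two-level masks", {
  z <- image_stack(list(tubulin = array(0, c(6, 6, 6)),
                        dna = array(0, c(6, 6, 6))), c(1, 1, 1))
  expect_error(segment_channel(z, "tubulin"),
               class = "spindlemorph_degenerate_error")

  a <- array(0, c(8, 8, 8))
  a[3:6, 3:6, 3:6] <- 100
  st <- image_stack(list(tubulin = a), c(1, 0.5, 0.5))
  sg <- segment_channel(st, "tubulin")
  expect_identical(sg$mask, a == 100)
  expect_true(sg$threshold > 0 && sg$threshold < 100)
})

test_that("the default mask covers the ground-truth fiber envelope", {
  g <- noiseless_spindle(0)
  seg <- segment_stack(g$stack)
  dens <- withr::with_seed(g$truth$rng_seed,
    spindlemorph:::render_density(g$truth, dim(seg$tubulin$mask),
                                  g$stack$voxel_size))
  expect_gte(mean(seg$tubulin$mask[dens$tubulin > 0]), 0.9)
})

test_that("axis estimation recovers the generating axis, also under rotation", {
  m <- measured_phantom(0.3, seed = 13)
  expect_gte(abs(sum(m$ap$axis * m$gen$truth$plate_normal)), 0.99)

  ax <- unit_axis <- c(0.15, 0.4, 0.9) / sqrt(sum(c(0.15, 0.4, 0.9)^2))
  tr <- spindle_truth(divergence = 0.3, axis = ax, rng_seed = 13)
  g <- generate_spindle_stack(tr, optics_noiseless())
  ap <- estimate_axis_and_plate(g$stack, segment_stack(g$stack))
  expect_gte(abs(sum(ap$axis * ax)), cos(2 * pi / 180))
})

test_that("an isotropic intensity ball has no principal axis", {
  d <- c(13, 61, 61)
  vs <- c(1, 0.2, 0.2)
  ctr <- c(6, 6, 6)
  co <- spindlemorph:::voxel_coordinates(d, vs)
  ball <- array(as.numeric(sqrt(rowSums(sweep(co, 2, ctr)^2)) <= 5), d)
  st <- image_stack(list(tubulin = ball, dna = ball), vs)
  seg <- segment_stack(st, method = "fixed", threshold = 0.5, min_size = 1)
  expect_error(estimate_axis_and_plate(st, seg),
               class = "spindlemorph_anisotropy_error")
})

test_that("focus ratio hits the analytic limits: cylinder near 1, cone near (1 - f)", {
  cyl <- measured_phantom(1)
  m <- measure_half_spindle(cyl$gen$stack, cyl$seg, cyl$ap$axis,
                            cyl$ap$plate_center)
  expect_equal(m$focus_ratio, 1, tolerance = 0.05)
  expect_equal(m$focus_ratio, m$W_S / m$W_C)  # exact by construction

  cone <- measured_phantom(0)
  for (id in 1:2) {
    mc <- measure_half_spindle(cone$gen$stack, cone$seg, cone$ap$axis,
                               cone$ap$plate_center, half_spindle_id = id)
    expect_lt(abs(mc$focus_ratio - 0.25), 0.05)
  }
  # at a different fraction the cone follows W(f) = (1 - f) * W_C
  m6 <- measure_half_spindle(cone$gen$stack, cone$seg, cone$ap$axis,
                             cone$ap$plate_center, fraction = 0.5)
  expect_lt(abs(m6$focus_ratio - 0.5), 0.06)
})

test_that("plate width and half-length are recovered within the sampling tolerance", {
  tol <- 1  # coarsest voxel dimension (dz = 1 um) dominates PSF sigma
  for (d in c(0, 1)) {
    ph <- measured_phantom(d)
    m <- measure_half_spindle(ph$gen$stack, ph$seg, ph$ap$axis,
                              ph$ap$plate_center)
    expect_lt(abs(m$W_C - ph$gen$truth$plate_width_true), tol)
    expect_lt(abs(m$L - ph$gen$truth$half_length_true), tol)
    # pole point sits on the axis ray at distance L
    expect_equal(sqrt(sum((m$pole_point - m$plate_center)^2)), m$L,
                 tolerance = 1e-9)
  }
})

test_that("FWHM widths agree with a brute-force per-plane profile scan", {
  # scan a single in-plane direction (the y axis for an x-aligned
  # spindle) and compare against direct voxel indexing in that plane
  ph <- measured_phantom(1)
  g <- ph$gen
  tub <- g$stack$channels$tubulin
  vs <- g$stack$voxel_size
  c0 <- g$truth$plate_center
  m <- measure_half_spindle(g$stack, ph$seg, ph$ap$axis,
                            ph$ap$plate_center, n_directions = 1L)
  ix <- round((c0[3] + 0.75 * m$L) / vs[3]) + 1
  iz <- round(c0[1] / vs[1]) + 1
  prof <- tub[iz, , ix]
  w_brute <- brute_fwhm((seq_along(prof) - 1) * vs[2], prof)
  expect_equal(m$W_S, w_brute, tolerance = vs[2] / w_brute)
})

test_that("measurements are scale-equivariant and the ratio is scale-free", {
  m1 <- measure_spindle(noiseless_spindle(0.4, seed = 5)$stack)$cell
  tr2 <- spindle_truth(divergence = 0.4, plate_width_true = 15,
                       half_length_true = 18, rng_seed = 5)
  g2 <- generate_spindle_stack(
    tr2, optics_noiseless(psf_sigma = 1.5 * c(0.6, 0.25, 0.25)),
    voxel_size = 1.5 * c(1, 0.2, 0.2))
  m2 <- measure_spindle(g2$stack)$cell
  s <- 1.5
  expect_equal(m2$W_C / m1$W_C, s, tolerance = 0.02)
  expect_equal(m2$L / m1$L, s, tolerance = 0.02)
  expect_equal(m2$W_S / m1$W_S, s, tolerance = 0.02)
  expect_equal(m2$focus_ratio / m1$focus_ratio, 1, tolerance = 0.02)
})

test_that("measurements are invariant to rigid rotation of the spindle", {
  base <- measure_spindle(noiseless_spindle(0.3, seed = 13)$stack)$cell
  ax <- c(0.15, 0.4, 0.9) / sqrt(sum(c(0.15, 0.4, 0.9)^2))
  tr <- spindle_truth(divergence = 0.3, axis = ax, rng_seed = 13)
  rot <- measure_spindle(
    generate_spindle_stack(tr, optics_noiseless())$stack)$cell
  for (f in c("W_C", "L", "W_S", "focus_ratio"))
    expect_equal(rot[[f]] / base[[f]], 1, tolerance = 0.05)
})

test_that("measured focus ratio increases strictly with the divergence parameter", {
  ratios <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(d)
    measure_spindle(noiseless_spindle(d)$stack)$cell$focus_ratio,
    numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("topology counts spindles and poles across configurations", {
  ph <- measured_phantom(0, seed = 9)
  tp <- detect_topology(ph$seg, ph$gen$stack)
  expect_equal(tp$n_spindle_components, 1L)
  expect_equal(tp$components$n_poles, 2L)

  tr2 <- spindle_truth(n_spindles = 2, rng_seed = 9)
  g2 <- generate_spindle_stack(tr2, optics_noiseless())
  tp2 <- detect_topology(segment_stack(g2$stack), g2$stack)
  expect_equal(tp2$n_spindle_components, 2L)

  tr3 <- spindle_truth(n_poles_per_spindle = 3, rng_seed = 9)
  g3 <- generate_spindle_stack(tr3, optics_noiseless())
  tp3 <- detect_topology(segment_stack(g3$stack), g3$stack)
  expect_equal(tp3$n_spindle_components, 1L)
  expect_equal(tp3$components$n_poles, 3L)

  # empty mask: zero components, no error
  empty <- structure(list(mask = array(FALSE, c(4, 4, 4)),
                          channel = "tubulin", method = "fixed",
                          threshold = 1),
                     class = "segmentation")
  st <- image_stack(list(tubulin = array(0, c(4, 4, 4))), c(1, 1, 1))
  expect_equal(detect_topology(empty, st)$n_spindle_components, 0L)
})

test_that("missing half-spindles raise a classed error", {
  ph <- measured_phantom(0)
  # move the plate centre beyond the pole: nothing on the positive side
  far <- ph$ap$plate_center + ph$ap$axis * 30
  expect_error(
    measure_half_spindle(ph$gen$stack, ph$seg, ph$ap$axis, far,
                         half_spindle_id = 1L),
    class = "spindlemorph_missing_pole_error")
})
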