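test_that("spindle stack generation is a pure function of parameters and seed", {
  tr <- spindle_truth(divergence = 0.5, fiber_count = 300, rng_seed = 42)
  a <- generate_spindle_stack(tr)
  b <- generate_spindle_stack(tr)
  expect_identical(a$stack$channels, b$stack$channels)
  # and a different seed changes the draw
  tr2 <- spindle_truth(divergence = 0.5, fiber_count = 300, rng_seed = 43)
  c <- generate_spindle_stack(tr2)
  expect_false(identical(a$stack$channels$tubulin, c$stack$channels$tubulin))
})

test_that("zero photon scale, background and read noise give an all-zero stack", {
  tr <- spindle_truth(divergence = 0.5, fiber_count = 100, rng_seed = 1)
  g <- generate_spindle_stack(
    tr, optics(photon_scale = 0, background = 0, read_noise_sd = 0))
  expect_true(all(g$stack$channels$tubulin == 0))
  expect_true(all(g$stack$channels$dna == 0))
})

test_that("parameter validation rejects bad divergence and too-small volumes", {
  expect_error(spindle_truth(divergence = 1.2), "divergence")
  expect_error(spindle_truth(divergence = -0.1), "divergence")
  tr <- spindle_truth(divergence = 0.5, fiber_count = 50, rng_seed = 1)
  expect_error(generate_spindle_stack(tr, optics_noiseless(),
                                      shape = c(5, 5, 5)),
               "volume too small")
})

test_that("a noiseless cylinder phantom has constant cross-sectional FWHM along its axis", {
  g <- noiseless_spindle(1)
  tub <- g$stack$channels$tubulin
  vs <- g$stack$voxel_size
  c0 <- g$truth$plate_center
  L <- g$truth$half_length_true
  # brute-force per-plane scan: y-profiles through the axis at x planes
  # covering the middle 80% of each half-spindle
  xs <- seq(c0[3] - 0.8 * L, c0[3] + 0.8 * L, by = 1)
  iz <- round(c0[1] / vs[1]) + 1
  widths <- vapply(xs, function(x0) {
    ix <- round(x0 / vs[3]) + 1
    prof <- tub[iz, , ix]
    brute_fwhm((seq_along(prof) - 1) * vs[2], prof)
  }, numeric(1))
  expect_true(all(abs(widths - mean(widths)) <= vs[2]))
  # and the width tracks the plate width (single-plane chords read
  # slightly narrow under the 3D PSF, so allow a coarse-voxel margin)
  expect_lt(abs(mean(widths) - g$truth$plate_width_true), 1)
})

test_that("noiseless axial intensity is conserved for cylinders and non-increasing for cones", {
  for (d in c(0.5, 1)) {
    g <- noiseless_spindle(d)
    tub <- g$stack$channels$tubulin
    vs <- g$stack$voxel_size
    c0 <- g$truth$plate_center
    L <- g$truth$half_length_true
    # slab sums from plate to pole, clear of the blur margins
    xs <- seq(c0[3] + 1, c0[3] + L - 1, by = 0.4)
    slab <- vapply(xs, function(x0) sum(tub[, , round(x0 / vs[3]) + 1]),
                   numeric(1))
    rel <- slab / slab[1]
    if (d == 1) {
      expect_true(all(abs(rel - 1) < 0.05))
    } else {
      # non-increasing within a 5% discretization tolerance
      expect_true(all(diff(rel) < 0.05))
    }
  }
})

test_that("anaphase ground truth obeys the prescribed kinematics", {
  tr <- spindle_truth(fiber_count = 100, rng_seed = 3)
  still <- generate_anaphase_series(tr, speed = 0, n_timepoints = 4,
                                    time_step = 5)
  ctr <- still$truth$chromosome_mass_centroids
  for (m in 1:2)
    for (i in 2:4) expect_equal(ctr[i, m, ], ctr[1, m, ])

  mov <- generate_anaphase_series(tr, speed = 0.5, n_timepoints = 4,
                                  time_step = 5)
  ctr <- mov$truth$chromosome_mass_centroids
  sep <- vapply(1:4, function(i) sqrt(sum((ctr[i, 1, ] - ctr[i, 2, ])^2)),
                numeric(1))
  expect_equal(diff(sep), rep(5, 3))  # 2 masses x 0.5 um/min x 5 min

  expect_error(generate_anaphase_series(tr, speed = -1, n_timepoints = 4),
               "speed")
  expect_error(generate_anaphase_series(tr, speed = 1, n_timepoints = 1),
               "n_timepoints")
})

test_that("rendered anaphase frames put DNA intensity centroids on the ground truth", {
  tr <- spindle_truth(fiber_count = 400, rng_seed = 11)
  sim <- generate_anaphase_series(tr, speed = 0.4, n_timepoints = 5)
  vs <- sim$stack$voxel_size
  for (i in seq_len(5)) {
    fr <- stack_frame(sim$stack, i)
    sg <- segment_channel(fr, "dna")
    lab <- spindlemorph:::label_components(sg$mask)
    expect_gte(max(lab), 2)
    got <- t(vapply(1:2, function(j) {
      idx <- which(lab == j)
      w <- fr$channels$dna[idx]
      colSums(spindlemorph:::voxel_coordinates(dim(sg$mask), vs, idx) * w) /
        sum(w)
    }, numeric(3)))
    truth <- sim$truth$chromosome_mass_centroids[i, , ]
    # match each labeled mass to its nearest ground-truth mass
    err <- vapply(1:2, function(j)
      min(sqrt(rowSums(sweep(truth, 2, got[j, ])^2))), numeric(1))
    expect_true(all(err < 0.5))
  }
})

test_that("noiseless Ct tables encode relative expression exactly", {
  ct <- generate_ct_table(c("WT", "mut"), c(1, 1), n_replicates = 3,
                          noise_sd = 0)
  ex <- ddct(ct, "WT")
  expect_equal(ex$samples$ddct, rep(0, 6))
  expect_equal(ex$samples$relative_expression, rep(1, 6))

  ct2 <- generate_ct_table(c("WT", "half"), c(1, 0.5), n_replicates = 2,
                           noise_sd = 0)
  tgt <- function(g) ct2$ct[ct2$genotype == g & ct2$gene_role == "target"][1]
  expect_equal(tgt("half") - tgt("WT"), 1)  # log2(0.5) = -1 cycle

  expect_error(generate_ct_table("WT", 0), "relative_expression")
})

test_that("count tables are seeded binomial draws with exact edge cases", {
  all_pos <- generate_count_table(c("a"), 1, n_scored = 50, n_plants = 4)
  expect_true(all(all_pos$n_positive == all_pos$n_scored))
  none <- generate_count_table(c("a"), 0, n_scored = 50, n_plants = 4)
  expect_true(all(none$n_positive == 0))
  expect_identical(generate_count_table("a", 0.5, seed = 2),
                   generate_count_table("a", 0.5, seed = 2))
})

test_that("pooled count-table estimates fall inside the binomial 99% CI of the truth", {
  p <- 0.977
  tab <- generate_count_table("WT", p, n_scored = 500, n_plants = 10,
                              seed = 8)
  pool_n <- sum(tab$n_scored)
  ci <- suppressWarnings(
    prop.test(round(p * pool_n), pool_n, conf.level = 0.99,
              correct = FALSE)$conf.int)
  est <- sum(tab$n_positive) / pool_n
  expect_gte(est, ci[1])
  expect_lte(est, ci[2])
})

test_that("generated amplicons carry exactly the requested cut sites", {
  asy <- dv1_assays()
  am <- generate_amplicons(asy[["dv1-1"]], "cut", cut_positions = 152,
                           seed = 3)
  expect_equal(nchar(am$sequence), 235)
  # brute-force substring scan oracle
  scan_sites <- function(s, site) {
    n <- nchar(s); k <- nchar(site)
    which(vapply(seq_len(n - k + 1),
                 function(i) substr(s, i, i + k - 1) == site, logical(1)))
  }
  expect_equal(scan_sites(am$sequence, "TTAA"), 152)  # 1-based start 152 -> cut 152
  am0 <- generate_amplicons(asy[["dv1-IG"]], "uncut", seed = 4)
  expect_equal(nchar(am0$sequence), 533)
  expect_length(scan_sites(am0$sequence, "ATGCAT"), 0)
  # multiple sites
  am2 <- generate_amplicons(enzyme = enzyme("MseI"), allele = "cut",
                            cut_positions = c(50, 120), length = 300,
                            seed = 5)
  expect_length(scan_sites(am2$sequence, "TTAA"), 2)
  expect_error(generate_amplicons(enzyme = enzyme("MseI"), allele = "cut",
                                  cut_positions = c(50, 52), length = 300),
               "overlap")
  expect_error(generate_amplicons(asy[["dv1-1"]], "uncut",
                                  cut_positions = 10),
               "empty")
})
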