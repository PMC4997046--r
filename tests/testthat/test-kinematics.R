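make_track <- function(df) {
  class(df) <- c("centroid_track", class(df))
  df
}

test_that("centroids of point objects are exact in physical coordinates", {
  d <- c(6, 8, 10)
  a <- array(0, c(2, d))  # 2 frames
  a[1, 3, 4, 5] <- 10     # 0-based index (2, 3, 4)
  a[2, 3, 4, 5] <- 10
  st <- image_stack(list(dna = a), voxel_size = c(1, 0.2, 0.2),
                    time_step = 5)
  tr <- extract_centroids(st, channels = "dna", min_size = 1L)
  expect_equal(unlist(tr[1, c("z", "y", "x")], use.names = FALSE),
               c(2.0, 0.6, 0.8))
  # the object keeps its id across frames
  expect_equal(tr$object_id, c(1L, 1L))

  # symmetric two-voxel object: centroid at the midpoint
  b <- array(0, c(2, d))
  b[, 3, 4, 5] <- 7
  b[, 3, 4, 6] <- 7
  st2 <- image_stack(list(dna = b), voxel_size = c(1, 0.2, 0.2),
                     time_step = 5)
  tr2 <- extract_centroids(st2, channels = "dna", min_size = 1L)
  expect_equal(unlist(tr2[1, c("z", "y", "x")], use.names = FALSE),
               c(2.0, 0.6, 0.9))
})

test_that("chromosome offset is the Euclidean 3D distance and a metric", {
  expect_equal(chromosome_offset(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(chromosome_offset(c(0, 0, 0), c(0, 3, 4)), 5)
  withr::with_seed(99, {
    for (i in 1:25) {
      p <- rnorm(3); q <- rnorm(3); r <- rnorm(3)
      expect_equal(chromosome_offset(p, q), chromosome_offset(q, p))
      expect_gte(chromosome_offset(p, q), 0)
      expect_lte(chromosome_offset(p, r),
                 chromosome_offset(p, q) + chromosome_offset(q, r) + 1e-12)
    }
  })
  expect_error(chromosome_offset(c(1, 2), c(1, 2, 3)), "length-3")
})

test_that("anaphase metrics follow distance / time exactly on ideal tracks", {
  tr <- make_track(data.frame(
    t = rep(c(0, 20), each = 2), frame = rep(1:2, each = 2),
    channel = "dna", object_id = rep(1:2, 2),
    z = 0, y = 0, x = c(0, 1, 10, -9),
    total_intensity = 1))
  km <- anaphase_metrics(tr, t_start = 0, t_end = 20)
  expect_equal(km$per_mass$distance, c(10, 10))
  expect_equal(km$anaphase_distance, 10)
  expect_equal(km$anaphase_rate, 0.5)
  expect_equal(km$anaphase_rate,
               km$anaphase_distance / (km$t_end - km$t_start))

  still <- make_track(data.frame(
    t = rep(c(0, 20), each = 2), frame = rep(1:2, each = 2),
    channel = "dna", object_id = rep(1:2, 2),
    z = 1, y = 2, x = c(0, 5, 0, 5), total_intensity = 1))
  km0 <- anaphase_metrics(still, t_start = 0, t_end = 20)
  expect_equal(km0$anaphase_distance, 0)
  expect_equal(km0$anaphase_rate, 0)
})

test_that("anaphase metrics are translation invariant", {
  base <- make_track(data.frame(
    t = rep(c(0, 10, 20), each = 2), frame = rep(1:3, each = 2),
    channel = "dna", object_id = rep(1:2, 3),
    z = rnorm(6), y = rnorm(6), x = c(0, 6, 2, 8, 9, 15),
    total_intensity = 1))
  shifted <- base
  shifted$z <- shifted$z + 3; shifted$y <- shifted$y - 7
  shifted$x <- shifted$x + 11
  a <- anaphase_metrics(base, t_start = 0, t_end = 20)
  b <- anaphase_metrics(shifted, t_start = 0, t_end = 20)
  expect_equal(a$per_mass$distance, b$per_mass$distance)
  expect_equal(a$anaphase_rate, b$anaphase_rate)
})

test_that("objects missing at an endpoint are skipped, not fatal", {
  tr <- make_track(data.frame(
    t = c(0, 0, 20), frame = c(1, 1, 2), channel = "dna",
    object_id = c(1, 2, 1), z = 0, y = 0, x = c(0, 1, 8),
    total_intensity = 1))
  km <- anaphase_metrics(tr, t_start = 0, t_end = 20)
  expect_equal(nrow(km$per_mass), 1L)
  expect_match(km$errors, "object 2")
})

test_that("the full pipeline recovers a simulated anaphase rate", {
  sim <- cached("anaphase_04", function() {
    tr <- spindle_truth(rng_seed = 11)
    generate_anaphase_series(tr, speed = 0.4, n_timepoints = 9,
                             time_step = 5)
  })
  track <- extract_centroids(sim$stack)
  km <- anaphase_metrics(track)
  expect_equal(km$anaphase_rate, 0.4, tolerance = 0.05 / 0.4)
  # per-frame extracted centroids sit on the ground truth
  dna <- track[track$channel == "dna", ]
  for (fi in unique(dna$frame)) {
    got <- as.matrix(dna[dna$frame == fi, c("z", "y", "x")])
    truth <- sim$truth$chromosome_mass_centroids[fi, , ]
    err <- vapply(seq_len(nrow(got)), function(j)
      min(sqrt(rowSums(sweep(truth, 2, got[j, ])^2))), numeric(1))
    expect_true(all(err < 0.5))
  }
})

test_that("rate estimates do not depend on the window within constant motion", {
  sim <- cached("anaphase_04", function() {
    tr <- spindle_truth(rng_seed = 11)
    generate_anaphase_series(tr, speed = 0.4, n_timepoints = 9,
                             time_step = 5)
  })
  track <- extract_centroids(sim$stack)
  r1 <- anaphase_metrics(track, t_start = 5, t_end = 40)$anaphase_rate
  r2 <- anaphase_metrics(track, t_start = 10, t_end = 30)$anaphase_rate
  r3 <- anaphase_metrics(track, t_start = 5, t_end = 25)$anaphase_rate
  expect_equal(r2 / r1, 1, tolerance = 0.1)
  expect_equal(r3 / r1, 1, tolerance = 0.1)
})

test_that("a displaced chromosome mass is recovered through the image pipeline", {
  trs <- spindle_truth(divergence = 0.2, chromosome_shift = c(0, 0, 2),
                       rng_seed = 21)
  gs <- generate_spindle_stack(trs)
  seg <- segment_stack(gs$stack)
  vs <- gs$stack$voxel_size
  wctr <- function(img, mask) {
    idx <- which(mask)
    w <- img[idx]
    colSums(spindlemorph:::voxel_coordinates(dim(img), vs, idx) * w) / sum(w)
  }
  off <- chromosome_offset(
    wctr(gs$stack$channels$dna, seg$dna$mask),
    wctr(gs$stack$channels$tubulin, seg$tubulin$mask))
  expect_equal(off, 2, tolerance = 0.3 / 2)
})
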