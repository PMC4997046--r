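#' Extract labeled object centroids from a 4D stack
#'
#' For each frame and channel, labels 26-connected components of the
#' segmentation mask and computes intensity-weighted centroids in physical
#' um. Objects are linked across frames by nearest-centroid matching
#' subject to a maximum per-frame displacement; ties are broken by total
#' intensity similarity. Frames with no objects in a channel are flagged
#' in the \code{warnings} attribute, not fatal.
#'
#' @param stack a 4D \code{\link{image_stack}}.
#' @param seg optional list of per-frame \code{\link{segment_stack}}
#'   results; segmented with defaults when omitted.
#' @param channels channels to track (default \code{"dna"} and
#'   \code{"tubulin"}).
#' @param max_displacement maximum linking displacement per frame, um.
#' @param min_size minimum object size in voxels (passed to segmentation).
#' @return A data.frame of class \code{"centroid_track"} with columns
#'   \code{t} (minutes), \code{frame}, \code{channel}, \code{object_id},
#'   \code{z}, \code{y}, \code{x} (um), \code{total_intensity}.
#' @export
extract_centroids <- function(stack, seg = NULL,
                              channels = c("dna", "tubulin"),
                              max_displacement = 5, min_size = 27L) {
  if (stack$ndim != 4L) stopf("extract_centroids needs a 4D stack")
  nt <- n_frames(stack)
  tt <- (seq_len(nt) - 1) * stack$time_step
  warn <- character(0)
  rows <- list()
  for (ch in channels) {
    prev <- NULL  # data.frame: object_id, z, y, x, total_intensity
    next_id <- 1L
    for (fi in seq_len(nt)) {
      fr <- stack_frame(stack, fi)
      sg <- if (is.null(seg)) segment_channel(fr, ch, min_size = min_size)
            else get_segmentation(seg[[fi]], ch)
      lab <- label_components(sg$mask)
      k <- max(lab)
      if (k == 0L) {
        warn <- c(warn, sprintf("frame %d: no '%s' objects", fi, ch))
        prev <- NULL
        next
      }
      img <- fr$channels[[ch]]
      obj <- do.call(rbind, lapply(seq_len(k), function(j) {
        idx <- which(lab == j)
        w <- img[idx]
        xyz <- voxel_coordinates(dim(img), stack$voxel_size, idx)
        ctr <- colSums(xyz * w) / sum(w)
        data.frame(z = ctr[1], y = ctr[2], x = ctr[3],
                   total_intensity = sum(w))
      }))
      # link to previous frame
      ids <- integer(k)
      if (!is.null(prev)) {
        dmat <- outer(seq_len(k), seq_len(nrow(prev)),
                      Vectorize(function(a, b)
                        sqrt(sum((unlist(obj[a, c("z", "y", "x")]) -
                                    unlist(prev[b, c("z", "y", "x")]))^2))))
        # greedy matching, closest pairs first; intensity similarity
        # breaks distance ties
        cand <- which(dmat <= max_displacement, arr.ind = TRUE)
        if (nrow(cand) > 0L) {
          dsim <- abs(obj$total_intensity[cand[, 1]] -
                        prev$total_intensity[cand[, 2]])
          ord <- order(dmat[cand], dsim)
          used_o <- logical(k); used_p <- logical(nrow(prev))
          for (r in ord) {
            a <- cand[r, 1]; b <- cand[r, 2]
            if (!used_o[a] && !used_p[b]) {
              ids[a] <- prev$object_id[b]
              used_o[a] <- TRUE; used_p[b] <- TRUE
            }
          }
        }
      }
      for (a in seq_len(k)) if (ids[a] == 0L) {
        ids[a] <- next_id
        next_id <- next_id + 1L
      }
      obj$object_id <- ids
      obj$frame <- fi
      obj$t <- tt[fi]
      obj$channel <- ch
      rows[[length(rows) + 1L]] <- obj
      prev <- obj
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("t", "frame", "channel", "object_id", "z", "y", "x",
                 "total_intensity")]
  rownames(out) <- NULL
  attr(out, "warnings") <- warn
  class(out) <- c("centroid_track", class(out))
  out
}

#' Chromosome offset: distance between chromosome and spindle centroids
#'
#' The congression metric: Euclidean 3D distance (um) between the centroid
#' of the chromosome mass and the centroid of the spindle at metaphase.
#'
#' @param chromosome_centroid,spindle_centroid length-3 numeric (z, y, x)
#'   positions in um.
#' @export
chromosome_offset <- function(chromosome_centroid, spindle_centroid) {
  a <- as.numeric(chromosome_centroid)
  b <- as.numeric(spindle_centroid)
  if (length(a) != 3L || length(b) != 3L || any(!is.finite(c(a, b))))
    stopf("centroids must be finite length-3 (z, y, x) vectors")
  sqrt(sum((a - b)^2))
}

#' Anaphase A distance and rate from a centroid track
#'
#' For each chromosome mass, the anaphase distance is the 3D distance
#' between its centroid at \code{t_start} and at \code{t_end}, and the
#' anaphase rate is that distance divided by the elapsed time. Defaults:
#' \code{t_start} is the first time at which the distance between the two
#' chromosome masses exceeds its baseline (the value at the first frame
#' with two masses) by \code{onset_excess} um; \code{t_end} is the last
#' frame. Results are reported per mass plus the cell mean.
#'
#' @param track a \code{\link{extract_centroids}} result (or data.frame
#'   with the same columns); only the \code{dna} channel rows are used.
#' @param t_start,t_end window bounds in minutes; both must be present in
#'   the track when given.
#' @param onset_excess um above the metaphase baseline separation that
#'   marks anaphase onset for the automatic window.
#' @return An object of class \code{"kinematics_result"}: list with
#'   \code{per_mass} (data.frame: object_id, distance, rate),
#'   \code{anaphase_distance} and \code{anaphase_rate} (cell means),
#'   \code{t_start}, \code{t_end}, and \code{errors} (per-object
#'   messages for masses missing at an endpoint).
#' @export
anaphase_metrics <- function(track, t_start = NULL, t_end = NULL,
                             onset_excess = 2) {
  dna <- track[track$channel == "dna", , drop = FALSE]
  if (nrow(dna) == 0L) stopf("track has no 'dna' rows")
  times <- sort(unique(dna$t))
  sep_at <- function(t0) {
    m <- dna[dna$t == t0, , drop = FALSE]
    if (nrow(m) != 2L) return(NA_real_)
    sqrt(sum((unlist(m[1, c("z", "y", "x")]) -
                unlist(m[2, c("z", "y", "x")]))^2))
  }
  sep <- vapply(times, sep_at, numeric(1))
  if (is.null(t_start)) {
    ok <- which(!is.na(sep))
    if (length(ok) == 0L) stopf("no frame resolves two chromosome masses")
    baseline <- sep[ok[1]]
    hit <- ok[sep[ok] > baseline + onset_excess]
    t_start <- if (length(hit) > 0L) times[hit[1]] else times[ok[1]]
  }
  if (is.null(t_end)) t_end <- max(times[!is.na(sep)])
  if (!t_start %in% times || !t_end %in% times)
    stopf("t_start and t_end must be time points present in the track")
  if (t_start >= t_end) stopf("t_start must be < t_end")

  m0 <- dna[dna$t == t_start, , drop = FALSE]
  m1 <- dna[dna$t == t_end, , drop = FALSE]
  errors <- character(0)
  per <- list()
  for (id in unique(m0$object_id)) {
    a <- m0[m0$object_id == id, , drop = FALSE]
    b <- m1[m1$object_id == id, , drop = FALSE]
    if (nrow(b) != 1L) {
      errors <- c(errors,
                  sprintf("object %d missing at t_end=%g; skipped", id, t_end))
      next
    }
    d <- sqrt(sum((unlist(a[1, c("z", "y", "x")]) -
                     unlist(b[1, c("z", "y", "x")]))^2))
    per[[length(per) + 1L]] <-
      data.frame(object_id = id, distance = d,
                 rate = d / (t_end - t_start))
  }
  if (length(per) == 0L)
    stopf("no chromosome mass present at both window endpoints")
  per <- do.call(rbind, per)
  structure(list(per_mass = per,
                 anaphase_distance = mean(per$distance),
                 anaphase_rate = mean(per$distance) / (t_end - t_start),
                 t_start = t_start, t_end = t_end, errors = errors),
            class = "kinematics_result")
}

#' @export
print.kinematics_result <- function(x, ...) {
  cat(sprintf(
    "<kinematics_result> window %g-%g min: distance %.2f um, rate %.3f um/min (%d mass(es))\n",
    x$t_start, x$t_end, x$anaphase_distance, x$anaphase_rate,
    nrow(x$per_mass)))
  invisible(x)
}
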