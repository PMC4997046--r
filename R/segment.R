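# Error conditions with classes so callers and tests can catch them
stop_with_class <- function(cls, fmt, ...) {
  stop(structure(class = c(cls, "spindlemorph_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

# Otsu's histogram threshold on a numeric array: maximizes between-class
# variance over 256 equal-width bins spanning the data range.
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0)
    stop_with_class("spindlemorph_degenerate_error",
                    "constant-intensity image: no threshold separates it")
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  mids[which.max(sigma_b)]
}

# Label 26-connected components of a 3D logical mask. Returns an integer
# array (0 = background, 1..k component ids, largest first).
label_components <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (length(idx) == 0L) return(lab)
  ai <- arrayInd(idx, d)
  # map linear voxel index -> position in idx
  pos <- integer(prod(d))
  pos[idx] <- seq_along(idx)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  # forward half of the 26-neighbourhood suffices for an undirected graph
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
               drop = FALSE]
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    ni <- ai[, 1] + offs[k, 1]
    nj <- ai[, 2] + offs[k, 2]
    nk <- ai[, 3] + offs[k, 3]
    ok <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
    lin <- ni[ok] + d[1] * (nj[ok] - 1) + d[1] * d[2] * (nk[ok] - 1)
    tgt <- pos[lin]
    src <- which(ok)[tgt > 0]
    edges[[k]] <- cbind(src, tgt[tgt > 0])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  # relabel by decreasing size for a deterministic, size-ranked labelling
  sizes <- tabulate(comp)
  new_id <- integer(length(sizes))
  new_id[order(sizes, decreasing = TRUE)] <- seq_along(sizes)
  lab[idx] <- new_id[comp]
  lab
}

#' Segment one channel of a stack
#'
#' Global histogram threshold (Otsu by default) followed by removal of
#' connected components smaller than \code{min_size} voxels. The threshold
#' used is recorded for provenance.
#'
#' @param stack an \code{\link{image_stack}} (3D; slice 4D stacks with
#'   \code{\link{stack_frame}} first).
#' @param channel channel name, e.g. \code{"tubulin"} or \code{"dna"}.
#' @param method \code{"otsu_log"} (Otsu's threshold computed on
#'   \code{log1p} intensity, the default — robust to the heavy-tailed
#'   histograms of fluorescence stacks), \code{"otsu"} (raw intensity),
#'   or \code{"fixed"} (then give \code{threshold}).
#' @param threshold fixed threshold when \code{method = "fixed"}.
#' @param min_size minimum component size in voxels.
#' @return An object of class \code{"segmentation"}: list with \code{mask}
#'   (logical array), \code{channel}, \code{method}, \code{threshold}.
#' @export
segment_channel <- function(stack, channel = "tubulin",
                            method = c("otsu_log", "otsu", "fixed"),
                            threshold = NULL, min_size = 27L) {
  method <- match.arg(method)
  if (stack$ndim != 3L)
    stopf("segment_channel operates on 3D stacks; use stack_frame() on 4D")
  if (!channel %in% names(stack$channels))
    stopf("channel '%s' not present (have: %s)", channel,
          paste(names(stack$channels), collapse = ", "))
  x <- stack$channels[[channel]]
  thr <- switch(method,
                otsu_log = expm1(otsu_threshold(log1p(x))),
                otsu = otsu_threshold(x),
                fixed = {
                  if (is.null(threshold)) stopf("method 'fixed' needs 'threshold'")
                  threshold
                })
  mask <- x > thr
  if (any(mask) && min_size > 1L) {
    lab <- label_components(mask)
    keep <- which(tabulate(lab[lab > 0L]) >= min_size)
    mask <- array(lab %in% keep, dim(mask))
  }
  structure(list(mask = mask, channel = channel, method = method,
                 threshold = thr),
            class = "segmentation")
}

#' Segment both channels of a stack
#'
#' Convenience wrapper running \code{\link{segment_channel}} on every
#' channel; downstream morphometry takes this object.
#'
#' @inheritParams segment_channel
#' @param channels channel names to segment (default: all).
#' @param ... passed to \code{\link{segment_channel}}.
#' @return A named list of \code{"segmentation"} objects, class
#'   \code{"segmentation_set"}.
#' @export
segment_stack <- function(stack, channels = names(stack$channels), ...) {
  out <- lapply(channels, function(ch) segment_channel(stack, ch, ...))
  names(out) <- channels
  class(out) <- "segmentation_set"
  out
}

# accept either a segmentation_set or a single segmentation for channel ch
get_segmentation <- function(seg, ch) {
  if (inherits(seg, "segmentation")) {
    if (seg$channel != ch)
      stopf("segmentation is for channel '%s', need '%s'", seg$channel, ch)
    return(seg)
  }
  if (!ch %in% names(seg))
    stopf("no segmentation for channel '%s'", ch)
  seg[[ch]]
}
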