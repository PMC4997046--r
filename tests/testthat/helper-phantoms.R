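# Phantom builders shared across test files. Generation is deterministic,
# so phantoms are cached per session to keep the suite fast.

.phantom_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .phantom_cache))
    assign(key, fn(), envir = .phantom_cache)
  get(key, envir = .phantom_cache)
}

noiseless_spindle <- function(divergence, seed = 7, ...) {
  key <- paste0("nl_", divergence, "_", seed, "_",
                paste(deparse(substitute(list(...))), collapse = ""))
  cached(key, function() {
    tr <- spindle_truth(divergence = divergence, rng_seed = seed, ...)
    generate_spindle_stack(tr, optics_noiseless())
  })
}

measured_phantom <- function(divergence, seed = 7, noiseless = TRUE, ...) {
  key <- paste0("m_", divergence, "_", seed, "_", noiseless)
  cached(key, function() {
    tr <- spindle_truth(divergence = divergence, rng_seed = seed, ...)
    opt <- if (noiseless) optics_noiseless() else optics()
    g <- generate_spindle_stack(tr, opt)
    seg <- segment_stack(g$stack)
    ap <- estimate_axis_and_plate(g$stack, seg)
    list(gen = g, seg = seg, ap = ap)
  })
}

# brute-force FWHM of a 1D profile (independent of the package's fwhm):
# outermost half-max crossings by linear scan with interpolation
brute_fwhm <- function(t, v) {
  half <- max(v) / 2
  i <- which(v >= half)
  if (length(i) == 0) return(NA_real_)
  lo <- min(i); hi <- max(i)
  left <- if (lo == 1) t[1] else {
    f <- (half - v[lo - 1]) / (v[lo] - v[lo - 1]); t[lo - 1] + f * (t[lo] - t[lo - 1])
  }
  right <- if (hi == length(v)) t[hi] else {
    f <- (half - v[hi + 1]) / (v[hi] - v[hi + 1]); t[hi + 1] + f * (t[hi] - t[hi + 1])
  }
  right - left
}
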