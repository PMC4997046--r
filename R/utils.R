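#' @importFrom stats rnorm rpois rbinom aov TukeyHSD prop.test qt sd setNames
#' @importFrom utils write.csv read.csv packageVersion
NULL

# Internal validation helpers ------------------------------------------------

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (strict_lower && x <= lower)
    stopf("'%s' must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    stopf("'%s' must be >= %g (got %g)", name, lower, x)
  if (x > upper)
    stopf("'%s' must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

# Run an expression under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Physical coordinates (um) of voxel centres along one axis: index i (1-based
# in R) maps to (i - 1) * step, i.e. 0-based indices times the voxel size.
axis_coords <- function(n, step) (seq_len(n) - 1) * step

# Euclidean norm of rows of a matrix (or of a single vector).
row_norms <- function(m) {
  if (is.null(dim(m))) sqrt(sum(m^2)) else sqrt(rowSums(m^2))
}

unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stopf("cannot normalize a zero vector")
  v / n
}
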