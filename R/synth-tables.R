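#' Generate a synthetic qPCR Ct table
#'
#' Draws one target-gene and one reference-gene Ct row per biological
#' replicate of each genotype. Reference Cts scatter around a fixed
#' baseline; the target Ct of a genotype with true relative expression
#' \code{e} (relative to the calibrator, the genotype with expression 1)
#' is offset by \code{-log2(e)} cycles, so halving expression costs one
#' extra cycle. Gaussian cycle noise of sd \code{noise_sd} is added to
#' every Ct.
#'
#' @param genotypes character vector of genotype labels.
#' @param relative_expression true expression per genotype, relative to
#'   the calibrator (> 0); same length as \code{genotypes}.
#' @param n_replicates biological replicates per genotype.
#' @param noise_sd Gaussian Ct noise, cycles.
#' @param reference_ct,target_ct_calibrator baseline cycle numbers.
#' @param seed RNG seed.
#' @return data.frame with columns \code{sample_id}, \code{genotype},
#'   \code{gene_role}, \code{ct}, \code{replicate}, plus attribute
#'   \code{"true_relative_expression"}.
#' @export
generate_ct_table <- function(genotypes, relative_expression,
                              n_replicates = 3L, noise_sd = 0.2,
                              reference_ct = 20, target_ct_calibrator = 26,
                              seed = 1L) {
  if (length(genotypes) != length(relative_expression))
    stopf("genotypes and relative_expression differ in length")
  if (any(relative_expression <= 0))
    stopf("'relative_expression' must be > 0")
  check_scalar_num(noise_sd, "noise_sd", 0)
  if (n_replicates < 1L) stopf("'n_replicates' must be >= 1")
  with_seed(seed, {
    rows <- list()
    for (gi in seq_along(genotypes)) {
      for (r in seq_len(n_replicates)) {
        sid <- sprintf("%s_rep%d", genotypes[gi], r)
        tgt <- target_ct_calibrator - log2(relative_expression[gi]) +
          rnorm(1, sd = noise_sd)
        ref <- reference_ct + rnorm(1, sd = noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, genotype = genotypes[gi],
          gene_role = c("target", "reference"), ct = c(tgt, ref),
          replicate = r)
      }
    }
    out <- do.call(rbind, rows)
  })
  rownames(out) <- NULL
  attr(out, "true_relative_expression") <-
    setNames(relative_expression, genotypes)
  out
}

#' Generate a synthetic count table
#'
#' Binomial draws per plant: \code{n_scored} units scored (pollen grains
#' or tetrad cells), each positive (viable grain, multinucleate cell)
#' with the genotype's probability.
#'
#' @param genotypes character vector of genotype labels.
#' @param prob_positive per-genotype positive probability in \[0, 1\].
#' @param n_scored units scored per plant (default 500, the usual
#'   per-plant pollen sample).
#' @param n_plants plants per genotype.
#' @param seed RNG seed.
#' @return data.frame with columns \code{plant_id}, \code{genotype},
#'   \code{n_scored}, \code{n_positive}.
#' @export
generate_count_table <- function(genotypes, prob_positive, n_scored = 500L,
                                 n_plants = 10L, seed = 1L) {
  if (length(genotypes) != length(prob_positive))
    stopf("genotypes and prob_positive differ in length")
  if (any(prob_positive < 0 | prob_positive > 1))
    stopf("'prob_positive' must lie in [0, 1]")
  if (n_scored < 1L || n_plants < 1L)
    stopf("'n_scored' and 'n_plants' must be >= 1")
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_along(genotypes), function(gi) {
      data.frame(
        plant_id = sprintf("%s_plant%d", genotypes[gi], seq_len(n_plants)),
        genotype = genotypes[gi],
        n_scored = as.integer(n_scored),
        n_positive = rbinom(n_plants, n_scored, prob_positive[gi]))
    }))
  })
  rownames(out) <- NULL
  out
}
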