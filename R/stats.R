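#' One-way ANOVA with compact letter display
#'
#' Fits a one-way ANOVA and converts post-hoc pairwise comparisons (Tukey
#' HSD by default, unadjusted LSD-style t tests as an option) into the
#' compact letter display used in figure panels: groups that share a
#' letter are not significantly different at \code{alpha}. Letters are
#' the maximal cliques of the pairwise non-significance graph, ordered by
#' group mean (largest mean gets \code{"a"}), which guarantees a valid
#' display: every non-significant pair shares at least one letter and no
#' significant pair shares any.
#'
#' @param values numeric vector of per-observation measurements.
#' @param groups group labels (coerced to factor), same length.
#' @param alpha significance level for the letter grouping.
#' @param method \code{"tukey"} (Tukey HSD, default) or \code{"lsd"}
#'   (pairwise t tests on the pooled variance, unadjusted).
#' @return An object of class \code{"anova_groups"}: list with \code{F},
#'   \code{p}, \code{df}, \code{groups} (data.frame: group, n, mean, sd,
#'   letters), \code{pairwise_p} (matrix), \code{alpha}, \code{method}.
#' @export
anova_letters <- function(values, groups, alpha = 0.05,
                          method = c("tukey", "lsd")) {
  method <- match.arg(method)
  check_scalar_num(alpha, "alpha", 0, 1)
  g <- factor(groups)
  if (length(values) != length(g)) stopf("values and groups differ in length")
  if (nlevels(g) < 2L) stopf("need at least 2 groups")
  n_per <- table(g)
  if (any(n_per < 2L))
    stopf("every group needs >= 2 observations (got: %s)",
          paste(sprintf("%s=%d", names(n_per), n_per), collapse = ", "))
  df <- data.frame(y = as.numeric(values), g = g)
  fit <- aov(y ~ g, data = df)
  s <- summary(fit)[[1]]
  Fval <- s[["F value"]][1]
  pval <- s[["Pr(>F)"]][1]

  lev <- levels(g)
  k <- length(lev)
  pmat <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  if (method == "tukey") {
    tk <- TukeyHSD(fit, "g")$g
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (i in seq_along(pairs)) {
      a <- pairs[[i]][1]; b <- pairs[[i]][2]
      pmat[a, b] <- pmat[b, a] <- tk[i, "p adj"]
    }
  } else {
    pt <- stats::pairwise.t.test(df$y, df$g, p.adjust.method = "none",
                                 pool.sd = TRUE)$p.value
    for (a in rownames(pt)) for (b in colnames(pt)) {
      if (!is.na(pt[a, b])) pmat[a, b] <- pmat[b, a] <- pt[a, b]
    }
  }
  diag(pmat) <- 1

  means <- tapply(df$y, df$g, mean)
  ord <- order(means, decreasing = TRUE)
  # non-significance graph over groups, in mean-descending order
  adj <- pmat[ord, ord, drop = FALSE] >= alpha
  gph <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
  cl <- igraph::max_cliques(gph)
  # order cliques by their best (largest-mean) member for stable lettering
  best <- vapply(cl, function(x) min(as.integer(x)), integer(1))
  cl <- cl[order(best)]
  letter_of <- letters[seq_along(cl)]
  lv_ord <- lev[ord]
  group_letters <- vapply(lv_ord, function(gr) {
    i <- match(gr, lv_ord)
    paste(sort(letter_of[vapply(cl, function(x) i %in% as.integer(x),
                                logical(1))]), collapse = "")
  }, character(1))

  gdf <- data.frame(group = lv_ord,
                    n = as.integer(n_per[lv_ord]),
                    mean = as.numeric(means[lv_ord]),
                    sd = as.numeric(tapply(df$y, df$g, sd)[lv_ord]),
                    letters = group_letters,
                    row.names = NULL)
  structure(list(F = Fval, p = pval,
                 df = c(between = s[["Df"]][1], within = s[["Df"]][2]),
                 groups = gdf, pairwise_p = pmat, alpha = alpha,
                 method = method),
            class = "anova_groups")
}

#' @export
print.anova_groups <- function(x, ...) {
  cat(sprintf("<anova_groups> F(%d,%d) = %.4g, p = %.3g (%s, alpha = %g)\n",
              x$df[1], x$df[2], x$F, x$p, x$method, x$alpha))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Proportion with Wilson binomial confidence interval
#'
#' Scoring of count phenotypes (viable pollen grains, multinucleate tetrad
#' cells): the percentage positive plus a Wilson score interval, which
#' remains stable for the small counts typical of rare phenotypes.
#'
#' @param n_positive,n_scored counts, \code{0 <= n_positive <= n_scored}.
#' @param ci_level confidence level (default 0.95).
#' @return An object of class \code{"proportion_result"}: list with
#'   \code{n_positive}, \code{n_scored}, \code{percent},
#'   \code{ci_percent} (length 2), \code{ci_level}.
#' @export
proportion <- function(n_positive, n_scored, ci_level = 0.95) {
  if (n_scored <= 0) stopf("'n_scored' must be positive")
  if (n_positive < 0 || n_positive > n_scored)
    stopf("need 0 <= n_positive <= n_scored (got %g of %g)",
          n_positive, n_scored)
  check_scalar_num(ci_level, "ci_level", 0, 1)
  ci <- suppressWarnings(
    prop.test(n_positive, n_scored, conf.level = ci_level,
              correct = FALSE)$conf.int)
  structure(list(n_positive = n_positive, n_scored = n_scored,
                 percent = 100 * n_positive / n_scored,
                 ci_percent = 100 * as.numeric(ci),
                 ci_level = ci_level),
            class = "proportion_result")
}

#' @export
print.proportion_result <- function(x, ...) {
  cat(sprintf("<proportion_result> %g of %g = %.3g%% (%g%% CI %.3g-%.3g%%)\n",
              x$n_positive, x$n_scored, x$percent, 100 * x$ci_level,
              x$ci_percent[1], x$ci_percent[2]))
  invisible(x)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, dCt = mean target Ct minus mean reference Ct; ddCt is the
#' sample dCt minus the mean dCt of the calibrator genotype; relative
#' expression is \code{2^-ddCt}. Samples missing either gene are excluded
#' with a logged message rather than aborting the table.
#'
#' @param ct_table data.frame with columns \code{sample_id},
#'   \code{genotype}, \code{gene_role} (\code{"target"} or
#'   \code{"reference"}), \code{ct} (cycles, > 0) and optionally
#'   \code{replicate} (see \code{\link{generate_ct_table}}).
#' @param calibrator genotype label used as the expression baseline.
#' @param ci_level confidence level of per-genotype t intervals.
#' @return An object of class \code{"expression_result"}: list with
#'   \code{samples} (per-sample dCt, ddCt, relative_expression),
#'   \code{genotypes} (per-genotype mean, CI), \code{calibrator},
#'   \code{calibrator_dct}, \code{excluded} (messages).
#' @export
ddct <- function(ct_table, calibrator, ci_level = 0.95) {
  need <- c("sample_id", "genotype", "gene_role", "ct")
  if (!all(need %in% names(ct_table)))
    stopf("ct_table needs columns: %s", paste(need, collapse = ", "))
  if (any(ct_table$ct <= 0)) stopf("Ct values must be positive")
  if (!calibrator %in% ct_table$genotype)
    stopf("calibrator genotype '%s' not present", calibrator)

  excluded <- character(0)
  samples <- unique(ct_table[, c("sample_id", "genotype")])
  rows <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    sub <- ct_table[ct_table$sample_id == sid, , drop = FALSE]
    tgt <- sub$ct[sub$gene_role == "target"]
    ref <- sub$ct[sub$gene_role == "reference"]
    if (length(tgt) == 0L || length(ref) == 0L) {
      excluded <- c(excluded, sprintf(
        "sample '%s' lacks a %s-gene Ct; excluded", sid,
        if (length(tgt) == 0L) "target" else "reference"))
      next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(sample_id = sid, genotype = samples$genotype[i],
                 dct = mean(tgt) - mean(ref))
  }
  if (length(rows) == 0L) stopf("no usable samples in ct_table")
  sm <- do.call(rbind, rows)
  cal_dct <- mean(sm$dct[sm$genotype == calibrator])
  sm$ddct <- sm$dct - cal_dct
  sm$relative_expression <- 2^(-sm$ddct)

  gl <- split(sm, sm$genotype)
  gdf <- do.call(rbind, lapply(gl, function(d) {
    n <- nrow(d)
    m <- mean(d$relative_expression)
    ci <- if (n >= 2L) {
      se <- sd(d$relative_expression) / sqrt(n)
      m + c(-1, 1) * qt(1 - (1 - ci_level) / 2, n - 1) * se
    } else c(NA_real_, NA_real_)
    data.frame(genotype = d$genotype[1], n = n, mean_relative_expression = m,
               ci_lo = ci[1], ci_hi = ci[2])
  }))
  rownames(gdf) <- NULL
  structure(list(samples = sm, genotypes = gdf, calibrator = calibrator,
                 calibrator_dct = cal_dct, ci_level = ci_level,
                 excluded = excluded),
            class = "expression_result")
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf("<expression_result> calibrator '%s' (mean dCt %.3f)\n",
              x$calibrator, x$calibrator_dct))
  print(x$genotypes, row.names = FALSE)
  if (length(x$excluded)) cat("excluded:", length(x$excluded), "sample(s)\n")
  invisible(x)
}
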