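#' Build a pipeline run configuration
#'
#' A fully serializable description of one pipeline run; a config plus
#' its seed reproduces its outputs exactly.
#'
#' @param subcommand one of \code{"simulate"}, \code{"measure"},
#'   \code{"kinematics"}, \code{"stats"}, \code{"genotype"}.
#' @param outdir output directory (created if needed).
#' @param seed integer RNG seed for the run.
#' @param ... subcommand parameters, see \code{\link{run_pipeline}}.
#' @export
run_config <- function(subcommand = c("simulate", "measure", "kinematics",
                                      "stats", "genotype"),
                       outdir, seed = 1L, ...) {
  subcommand <- match.arg(subcommand)
  structure(list(subcommand = subcommand, outdir = outdir,
                 seed = as.integer(seed), params = list(...)),
            class = "run_config")
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tf)
  unname(tools::md5sum(tf))
}

add_provenance <- function(df, config, hash) {
  df$seed <- config$seed
  df$config_hash <- hash
  df$version <- as.character(packageVersion("spindlemorph"))
  df
}

#' Run one pipeline stage
#'
#' Subcommands and their parameters (all given via \code{\link{run_config}}):
#' \describe{
#'   \item{simulate}{\code{genotype_divergence} (named numeric: divergence
#'     per genotype), \code{n_cells} per genotype, \code{noiseless}
#'     (logical, default FALSE), plus optional \code{\link{spindle_truth}}
#'     arguments in \code{truth_args}. Writes one TIFF stack (+ sidecar)
#'     per cell and a \code{manifest.csv}.}
#'   \item{measure}{\code{manifest} (path to a simulate manifest, or a
#'     directory of stacks). Segments and measures every stack; writes
#'     \code{measurements.csv} with one row per half-spindle. Per-file
#'     failures are logged and skipped; the stage errors only if no file
#'     succeeds.}
#'   \item{kinematics}{either \code{input} (a 4D TIFF written by
#'     \code{\link{write_stack}}) or simulation parameters \code{speed},
#'     \code{n_timepoints}, \code{time_step}, \code{chromosome_shift}.
#'     Writes \code{kinematics.csv} (offset, anaphase distance, rate).}
#'   \item{stats}{\code{input} (a measurements CSV), \code{value}
#'     (column, default \code{"focus_ratio"}), \code{group} (column,
#'     default \code{"genotype"}), \code{alpha}. Writes
#'     \code{stats_groups.csv} with the compact letter display.}
#'   \item{genotype}{\code{input} (FASTA of amplicons), \code{assay}
#'     (\code{"dv1-1"} or \code{"dv1-IG"}), \code{size_tolerance}. Writes
#'     \code{genotype_calls.csv}.}
#' }
#' Every run also writes \code{report_<subcommand>.json} carrying the
#' config, seed, package version and collected warnings, and every output
#' table carries provenance columns (seed, config hash, version).
#'
#' @param config a \code{\link{run_config}}.
#' @return list with \code{outputs} (paths), \code{result} (stage-specific
#'   object), \code{warnings}; invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  warnings <- character(0)
  log_warning <- function(msg) warnings <<- c(warnings, msg)

  res <- switch(config$subcommand,
                simulate = pipe_simulate(config, hash, log_warning),
                measure = pipe_measure(config, hash, log_warning),
                kinematics = pipe_kinematics(config, hash, log_warning),
                stats = pipe_stats(config, hash, log_warning),
                genotype = pipe_genotype(config, hash, log_warning))

  report <- list(subcommand = config$subcommand,
                 config = unclass(config),
                 config_hash = hash,
                 version = as.character(packageVersion("spindlemorph")),
                 warnings = warnings,
                 outputs = res$outputs)
  report_path <- file.path(config$outdir,
                           sprintf("report_%s.json", config$subcommand))
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(outputs = c(res$outputs, report = report_path),
                 result = res$result, warnings = warnings))
}

pipe_simulate <- function(config, hash, log_warning) {
  p <- config$params
  gd <- p$genotype_divergence
  if (is.null(gd) || is.null(names(gd)))
    stopf("simulate needs 'genotype_divergence', a named numeric vector")
  n_cells <- if (is.null(p$n_cells)) 5L else as.integer(p$n_cells)
  opt <- if (isTRUE(p$noiseless)) optics_noiseless() else optics()
  truth_args <- if (is.null(p$truth_args)) list() else p$truth_args
  stack_dir <- file.path(config$outdir, "stacks")
  dir.create(stack_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  cell_i <- 0L
  for (gt in names(gd)) {
    for (ci in seq_len(n_cells)) {
      cell_i <- cell_i + 1L
      cell_seed <- config$seed * 10000L + cell_i
      tr <- do.call(spindle_truth,
                    c(list(divergence = gd[[gt]], rng_seed = cell_seed),
                      truth_args))
      g <- generate_spindle_stack(tr, optics = opt)
      f <- file.path(stack_dir, sprintf("%s_cell%02d.tif", gt, ci))
      write_stack(g$stack, f)
      rows[[cell_i]] <- data.frame(file = f, genotype = gt, cell = ci,
                                   divergence = gd[[gt]],
                                   cell_seed = cell_seed)
    }
  }
  manifest <- add_provenance(do.call(rbind, rows), config, hash)
  mf <- file.path(config$outdir, "manifest.csv")
  write.csv(manifest, mf, row.names = FALSE)
  list(outputs = c(manifest = mf), result = manifest)
}

pipe_measure <- function(config, hash, log_warning) {
  p <- config$params
  if (is.null(p$manifest)) stopf("measure needs 'manifest'")
  if (dir.exists(p$manifest)) {
    files <- list.files(p$manifest, pattern = "\\.tiff?$", full.names = TRUE)
    manifest <- data.frame(file = files,
                           genotype = NA_character_,
                           cell = seq_along(files))
  } else {
    manifest <- read.csv(p$manifest)
  }
  fraction <- if (is.null(p$fraction)) 0.75 else p$fraction
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    f <- manifest$file[i]
    m <- tryCatch({
      stk <- read_stack(f)
      measure_spindle(stk, fraction = fraction)
    }, error = function(e) {
      log_warning(sprintf("'%s' failed: %s", basename(f), conditionMessage(e)))
      NULL
    })
    if (is.null(m)) next
    h <- m$halves
    h$file <- basename(f)
    h$genotype <- manifest$genotype[i]
    h$cell <- manifest$cell[i]
    rows[[length(rows) + 1L]] <- h
  }
  if (length(rows) == 0L)
    stopf("measure: no stack could be processed")
  out <- add_provenance(do.call(rbind, rows), config, hash)
  out <- out[, c("file", "genotype", "cell", "half_spindle_id",
                 "W_C", "L", "W_S", "focus_ratio",
                 "seed", "config_hash", "version")]
  of <- file.path(config$outdir, "measurements.csv")
  write.csv(out, of, row.names = FALSE)
  list(outputs = c(measurements = of), result = out)
}

pipe_kinematics <- function(config, hash, log_warning) {
  p <- config$params
  if (!is.null(p$input)) {
    stk <- read_stack(p$input)
    truth <- NULL
  } else {
    speed <- if (is.null(p$speed)) 0.4 else p$speed
    ntp <- if (is.null(p$n_timepoints)) 9L else as.integer(p$n_timepoints)
    ts <- if (is.null(p$time_step)) 5 else p$time_step
    tr <- spindle_truth(rng_seed = config$seed)
    sim <- generate_anaphase_series(tr, speed = speed, n_timepoints = ntp,
                                    time_step = ts)
    stk <- sim$stack
    truth <- sim$truth
  }
  track <- extract_centroids(stk)
  for (w in attr(track, "warnings")) log_warning(w)
  km <- anaphase_metrics(track)
  for (e in km$errors) log_warning(e)
  # chromosome offset at the first frame: dna mass vs tubulin centroid
  f1 <- track[track$frame == 1, , drop = FALSE]
  sp <- f1[f1$channel == "tubulin", , drop = FALSE]
  dn <- f1[f1$channel == "dna", , drop = FALSE]
  offset <- if (nrow(sp) >= 1L && nrow(dn) >= 1L) {
    sp_c <- colSums(sp[, c("z", "y", "x")] * sp$total_intensity) /
      sum(sp$total_intensity)
    dn_c <- colSums(dn[, c("z", "y", "x")] * dn$total_intensity) /
      sum(dn$total_intensity)
    chromosome_offset(dn_c, sp_c)
  } else NA_real_
  out <- add_provenance(
    data.frame(object_id = km$per_mass$object_id,
               anaphase_distance = km$per_mass$distance,
               anaphase_rate = km$per_mass$rate,
               t_start = km$t_start, t_end = km$t_end,
               chromosome_offset = offset), config, hash)
  of <- file.path(config$outdir, "kinematics.csv")
  write.csv(out, of, row.names = FALSE)
  list(outputs = c(kinematics = of),
       result = list(metrics = km, offset = offset, track = track,
                     truth = truth))
}

pipe_stats <- function(config, hash, log_warning) {
  p <- config$params
  if (is.null(p$input)) stopf("stats needs 'input' (a measurements CSV)")
  d <- read.csv(p$input)
  value <- if (is.null(p$value)) "focus_ratio" else p$value
  group <- if (is.null(p$group)) "genotype" else p$group
  alpha <- if (is.null(p$alpha)) 0.05 else p$alpha
  if (!value %in% names(d) || !group %in% names(d))
    stopf("columns '%s' and '%s' must exist in the input", value, group)
  ag <- anova_letters(d[[value]], d[[group]], alpha = alpha)
  out <- add_provenance(cbind(ag$groups,
                              F = ag$F, p = ag$p, alpha = alpha),
                        config, hash)
  of <- file.path(config$outdir, "stats_groups.csv")
  write.csv(out, of, row.names = FALSE)
  list(outputs = c(stats_groups = of), result = ag)
}

pipe_genotype <- function(config, hash, log_warning) {
  p <- config$params
  if (is.null(p$input) || is.null(p$assay))
    stopf("genotype needs 'input' (FASTA) and 'assay'")
  assay <- dv1_assays()[[p$assay]]
  if (is.null(assay)) stopf("unknown assay '%s'", p$assay)
  tol <- if (is.null(p$size_tolerance)) 0 else p$size_tolerance
  seqs <- read_amplicons_fasta(p$input)
  rows <- lapply(seq_along(seqs), function(i) {
    dg <- digest(seqs[[i]], assay$enzyme)
    cl <- call_allele(dg$fragments, assay, size_tolerance = tol)
    data.frame(sequence_id = names(seqs)[i], assay = assay$id,
               fragments = paste(dg$fragments, collapse = "+"),
               call = cl$call, genotype = cl$genotype)
  })
  out <- add_provenance(do.call(rbind, rows), config, hash)
  of <- file.path(config$outdir, "genotype_calls.csv")
  write.csv(out, of, row.names = FALSE)
  list(outputs = c(genotype_calls = of), result = out)
}
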