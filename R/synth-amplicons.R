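#' Generate a synthetic CAPS amplicon
#'
#' Builds a random amplicon of the requested length carrying the assay
#' enzyme's recognition site exactly where requested: a cut allele gets
#' one site per entry of \code{cut_positions} (placed so the top-strand
#' cleavage falls at that 0-based position) and no other occurrence of
#' the site anywhere; an uncut allele (\code{cut_positions = integer(0)})
#' contains no occurrence at all. Accidental occurrences in the random
#' background are mutated away; impossible placements (overlapping
#' sites, sites extending past the ends) raise an error.
#'
#' @param assay a \code{\link{caps_assay}} (its enzyme and length are
#'   used) — or give \code{enzyme} and \code{length} directly.
#' @param allele \code{"cut"} or \code{"uncut"}; checked against
#'   \code{cut_positions}.
#' @param cut_positions 0-based top-strand cut positions, strictly inside
#'   (0, length); empty for the uncut allele.
#' @param length amplicon length in bp (defaults to the assay's).
#' @param enzyme an \code{\link{enzyme_spec}} (defaults to the assay's).
#' @param seed RNG seed.
#' @param max_tries retries before giving up on a clean background.
#' @return An object of class \code{"amplicon_spec"}: list with
#'   \code{sequence} (character), \code{assay}, \code{enzyme},
#'   \code{allele_truth} (\code{"cut-allele"} or \code{"uncut-allele"}),
#'   \code{cut_positions}, \code{length}.
#' @export
generate_amplicons <- function(assay = NULL, allele = c("cut", "uncut"),
                               cut_positions = integer(0), length = NULL,
                               enzyme = NULL, seed = 1L,
                               max_tries = 50L) {
  allele <- match.arg(allele)
  if (is.null(enzyme)) {
    stopifnot(inherits(assay, "caps_assay"))
    enzyme <- assay$enzyme
  }
  if (is.null(length)) {
    stopifnot(inherits(assay, "caps_assay"))
    length <- assay$amplicon_length
  }
  length <- as.integer(length)
  cut_positions <- sort(as.integer(cut_positions))
  if (allele == "uncut" && base::length(cut_positions) > 0L)
    stopf("uncut allele must have empty cut_positions")
  if (allele == "cut" && base::length(cut_positions) == 0L)
    stopf("cut allele needs at least one cut position")
  if (any(cut_positions <= 0L | cut_positions >= length))
    stopf("cut positions must lie strictly inside (0, %d)", length)

  site <- enzyme$site
  sl <- nchar(site)
  starts <- cut_positions - enzyme$cut_offset  # 0-based site starts
  if (any(starts < 0L | starts + sl > length))
    stopf("a recognition site does not fit inside the amplicon at the requested cut position")
  if (base::length(starts) > 1L && any(diff(starts) < sl))
    stopf("impossible placement: recognition sites would overlap")

  site_chars <- strsplit(site, "")[[1]]
  planted <- unlist(lapply(starts, function(s0) s0 + seq_len(sl)))  # 1-based

  with_seed(seed, {
    out <- NULL
    for (try in seq_len(max_tries)) {
      bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
      for (s0 in starts) bases[s0 + seq_len(sl)] <- site_chars
      # mutate away accidental occurrences outside the planted sites
      ok <- FALSE
      for (pass in 1:20) {
        seqstr <- paste(bases, collapse = "")
        occ <- Biostrings::start(
          Biostrings::matchPattern(site, Biostrings::DNAString(seqstr)))
        extra <- setdiff(as.integer(occ), starts + 1L)
        if (base::length(extra) == 0L) { ok <- TRUE; break }
        for (o in extra) {
          pos <- o:(o + sl - 1L)
          free <- setdiff(pos, planted)
          if (base::length(free) == 0L) break  # overlaps a planted site
          p <- free[sample.int(base::length(free), 1L)]
          bases[p] <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1L)
        }
      }
      if (ok) { out <- paste(bases, collapse = ""); break }
    }
  })
  if (is.null(out))
    stopf("could not generate a clean amplicon in %d tries", max_tries)
  structure(list(sequence = out,
                 assay = if (!is.null(assay)) assay$id else NA_character_,
                 enzyme = enzyme,
                 allele_truth = paste0(allele, "-allele"),
                 cut_positions = cut_positions,
                 length = length),
            class = "amplicon_spec")
}

#' Write amplicons to a FASTA file
#' @param amplicons list of \code{"amplicon_spec"} objects (or one).
#' @param path output file.
#' @export
write_amplicons_fasta <- function(amplicons, path) {
  if (inherits(amplicons, "amplicon_spec")) amplicons <- list(amplicons)
  seqs <- vapply(amplicons, function(a) a$sequence, character(1))
  nm <- vapply(seq_along(amplicons), function(i) {
    a <- amplicons[[i]]
    sprintf("amplicon_%d|assay=%s|allele=%s", i, a$assay, a$allele_truth)
  }, character(1))
  x <- Biostrings::DNAStringSet(setNames(seqs, nm))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read amplicon sequences from FASTA
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_amplicons_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
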