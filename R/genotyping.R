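#' Restriction enzyme specification
#'
#' @param name enzyme name.
#' @param site recognition sequence over A/C/G/T (both bundled assay
#'   enzymes have palindromic sites, so forward-strand scanning suffices).
#' @param cut_offset top-strand cut position within the site, in bp from
#'   the site start (0 to site length).
#' @return list of class \code{"enzyme_spec"}.
#' @export
enzyme_spec <- function(name, site, cut_offset) {
  site <- toupper(site)
  if (!grepl("^[ACGT]+$", site))
    stopf("recognition site must be a non-empty A/C/G/T string")
  if (cut_offset < 0 || cut_offset > nchar(site))
    stopf("cut_offset must lie within the site (0..%d)", nchar(site))
  structure(list(name = name, site = site,
                 cut_offset = as.integer(cut_offset)),
            class = "enzyme_spec")
}

#' Bundled restriction enzymes
#'
#' \code{MseI} (T^TAA) and \code{NsiI} (ATGCA^T), the two enzymes of the
#' dv1 CAPS assays.
#'
#' @param name enzyme name.
#' @export
enzyme <- function(name = c("MseI", "NsiI")) {
  name <- match.arg(name)
  switch(name,
         MseI = enzyme_spec("MseI", "TTAA", 1L),
         NsiI = enzyme_spec("NsiI", "ATGCAT", 5L))
}

check_dna <- function(sequence) {
  if (length(sequence) != 1L || !is.character(sequence) ||
      !nzchar(sequence))
    stopf("'sequence' must be a single non-empty string")
  s <- toupper(sequence)
  if (!grepl("^[ACGT]+$", s))
    stopf(paste("sequence contains non-ACGT characters (IUPAC ambiguity",
                "codes are not supported)"))
  s
}

#' Find restriction cut positions on a sequence
#'
#' Scans the forward strand for exact occurrences of the enzyme's
#' recognition site (overlapping occurrences included) and returns the
#' 0-based top-strand cut positions, sorted.
#'
#' @param sequence DNA string over A/C/G/T.
#' @param enzyme an \code{\link{enzyme_spec}}.
#' @return sorted integer vector of cut positions (bp, 0-based: a cut at
#'   position p leaves a 5' fragment of p bp).
#' @export
find_sites <- function(sequence, enzyme) {
  s <- check_dna(sequence)
  stopifnot(inherits(enzyme, "enzyme_spec"))
  hits <- Biostrings::matchPattern(enzyme$site, Biostrings::DNAString(s))
  starts <- Biostrings::start(hits)          # 1-based
  sort(as.integer(starts - 1L + enzyme$cut_offset))
}

#' Digest a linear amplicon in silico
#'
#' Cuts the sequence at every recognition site of the enzyme and returns
#' the fragment lengths between consecutive cuts. Invariants: fragment
#' lengths sum to the amplicon length, and k cuts give k + 1 fragments.
#'
#' @inheritParams find_sites
#' @return An object of class \code{"digest_result"}: list with
#'   \code{fragments} (bp, 5' to 3' order), \code{cut_positions}
#'   (0-based bp), \code{length}.
#' @export
digest <- function(sequence, enzyme) {
  s <- check_dna(sequence)
  cuts <- find_sites(s, enzyme)
  n <- nchar(s)
  frags <- diff(c(0L, cuts, n))
  frags <- frags[frags > 0L]  # cut at 0 or n would create empty fragments
  structure(list(fragments = as.integer(frags),
                 cut_positions = cuts, length = n,
                 enzyme = enzyme$name),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("<digest_result> %s on %d bp: fragments {%s}\n",
              x$enzyme, x$length, paste(x$fragments, collapse = ", ")))
  invisible(x)
}

#' CAPS assay definition
#'
#' Expected fragment patterns for the cut and uncut alleles of one PCR +
#' restriction-digest genotyping assay.
#'
#' @param id assay name.
#' @param enzyme an \code{\link{enzyme_spec}}.
#' @param amplicon_length bp.
#' @param cut_fragments expected fragment sizes (bp) of the allele that
#'   carries the site.
#' @param cut_allele,uncut_allele genotype labels the two patterns imply.
#' @export
caps_assay <- function(id, enzyme, amplicon_length, cut_fragments,
                       cut_allele, uncut_allele) {
  if (sum(cut_fragments) != amplicon_length)
    stopf("cut fragments must sum to the amplicon length")
  structure(list(id = id, enzyme = enzyme,
                 amplicon_length = as.integer(amplicon_length),
                 cut_fragments = as.integer(cut_fragments),
                 uncut_fragments = as.integer(amplicon_length),
                 cut_allele = cut_allele, uncut_allele = uncut_allele),
            class = "caps_assay")
}

#' The two dv1 CAPS assays
#'
#' \code{dv1-1}: a 235-bp amplicon; MseI cleaves the dv1-1 allele into
#' 152 + 83 bp while the wild-type copy remains uncut. \code{dv1-IG}: a
#' 533-bp amplicon; NsiI cleaves the wild-type allele into 272 + 261 bp
#' while dv1-IG remains uncut.
#'
#' @return named list of \code{\link{caps_assay}} objects.
#' @export
dv1_assays <- function() {
  list(
    "dv1-1" = caps_assay("dv1-1", enzyme("MseI"), 235L, c(152L, 83L),
                         cut_allele = "dv1-1", uncut_allele = "wild type"),
    "dv1-IG" = caps_assay("dv1-IG", enzyme("NsiI"), 533L, c(272L, 261L),
                          cut_allele = "wild type", uncut_allele = "dv1-IG"))
}

# multiset match within a per-fragment size tolerance
pattern_matches <- function(observed, expected, tol) {
  if (length(observed) != length(expected)) return(FALSE)
  all(abs(sort(observed) - sort(expected)) <= tol)
}

#' Call an allele from an observed fragment pattern
#'
#' Matches the observed fragment sizes against the assay's expected
#' cut-allele pattern, uncut-allele pattern, and their union (the
#' heterozygote, as seen in segregating F2 material). \code{"unknown"}
#' is returned when nothing matches within tolerance.
#'
#' @param fragments observed fragment sizes, bp.
#' @param assay a \code{\link{caps_assay}}.
#' @param size_tolerance per-fragment size tolerance, bp (gel-resolution
#'   slack; 0 for exact in-silico patterns).
#' @return An object of class \code{"allele_call"}: list with
#'   \code{assay}, \code{call} (\code{"cut-allele"},
#'   \code{"uncut-allele"}, \code{"heterozygous"} or \code{"unknown"}),
#'   \code{genotype} (the assay's label for the call, NA for unknown),
#'   \code{matched_pattern}, \code{observed}.
#' @export
call_allele <- function(fragments, assay, size_tolerance = 0) {
  stopifnot(inherits(assay, "caps_assay"))
  if (length(fragments) == 0L) stopf("empty fragment observation")
  obs <- as.numeric(fragments)
  het <- c(assay$cut_fragments, assay$uncut_fragments)
  res <- if (pattern_matches(obs, assay$cut_fragments, size_tolerance)) {
    list(call = "cut-allele", genotype = assay$cut_allele,
         matched = assay$cut_fragments)
  } else if (pattern_matches(obs, assay$uncut_fragments, size_tolerance)) {
    list(call = "uncut-allele", genotype = assay$uncut_allele,
         matched = assay$uncut_fragments)
  } else if (pattern_matches(obs, het, size_tolerance)) {
    list(call = "heterozygous",
         genotype = sprintf("%s/%s", assay$cut_allele, assay$uncut_allele),
         matched = het)
  } else {
    list(call = "unknown", genotype = NA_character_, matched = NULL)
  }
  structure(list(assay = assay$id, call = res$call,
                 genotype = res$genotype,
                 matched_pattern = res$matched, observed = obs,
                 size_tolerance = size_tolerance),
            class = "allele_call")
}

#' @export
print.allele_call <- function(x, ...) {
  cat(sprintf("<allele_call> %s: {%s} -> %s (%s)\n", x$assay,
              paste(x$observed, collapse = ", "), x$call,
              if (is.na(x$genotype)) "no pattern" else x$genotype))
  invisible(x)
}
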