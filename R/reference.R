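# Kinase-domain reference: codon addressing and the seeded surrogate sequence.
#
# The assay targets ABL1 codons 160-500 of the fusion transcript (1023 coding
# bases). The real NM_005157.6 sequence is not redistributed here; instead a
# synthetic surrogate is generated whose translation honours the catalogue's
# wild-type residues, and a user-supplied FASTA can replace it.

GENETIC_CODE_1 <- Biostrings::GENETIC_CODE
SENSE_CODONS <- names(GENETIC_CODE_1)[GENETIC_CODE_1 != "*"]

translate_codons <- function(codons) unname(GENETIC_CODE_1[codons])

#' Construct a kinase-domain reference object
#'
#' @param kd_sequence In-frame coding sequence for codons
#'   `first_codon..last_codon` (1023 bases for the default 160-500 window).
#' @param label Transcript identifier used as the FASTA/VCF sequence name.
#' @param first_codon,last_codon Codon numbers of the window ends (inclusive).
#' @param catalogue Optional `kd_catalogue`; when given, the translation is
#'   checked against every catalogue wild-type residue.
#' @return A `kd_reference` list: `kd_sequence`, `first_codon`, `last_codon`,
#'   `label`.
#' @export
kd_reference <- function(kd_sequence, label = "KD_surrogate",
                         first_codon = KD_FIRST_CODON, last_codon = KD_LAST_CODON,
                         catalogue = NULL) {
  kd_sequence <- toupper(kd_sequence)
  n_codons <- last_codon - first_codon + 1L
  if (nchar(kd_sequence) != 3L * n_codons) {
    abort_abl1kd(sprintf(
      "kd_sequence must have %d bases (3 x %d codons), got %d",
      3L * n_codons, n_codons, nchar(kd_sequence)
    ), "abl1kd_validation_error")
  }
  if (grepl("[^ACGT]", kd_sequence)) {
    abort_abl1kd("kd_sequence may contain only A/C/G/T", "abl1kd_validation_error")
  }
  aa <- translate_kd(kd_sequence)
  if (any(aa == "*")) {
    abort_abl1kd("kd_sequence contains an in-frame stop codon", "abl1kd_validation_error")
  }
  ref <- structure(
    list(kd_sequence = kd_sequence, first_codon = as.integer(first_codon),
         last_codon = as.integer(last_codon), label = label),
    class = "kd_reference"
  )
  if (!is.null(catalogue)) {
    got <- aa[catalogue$codon - first_codon + 1L]
    bad <- got != catalogue$wt
    if (any(bad)) {
      abort_abl1kd(paste0(
        "reference residue disagrees with catalogue wild type at codon(s): ",
        paste(catalogue$codon[bad], collapse = ", ")
      ), "abl1kd_validation_error")
    }
  }
  ref
}

#' @export
print.kd_reference <- function(x, ...) {
  cat("KD reference '", x$label, "': codons ", x$first_codon, "-", x$last_codon,
      " (", nchar(x$kd_sequence), " bases)\n", sep = "")
  invisible(x)
}

translate_kd <- function(kd_sequence) {
  n <- nchar(kd_sequence) %/% 3L
  starts <- 3L * (seq_len(n) - 1L) + 1L
  translate_codons(substring(kd_sequence, starts, starts + 2L))
}

#' Translate a reference to its residue-per-codon tibble
#'
#' @param ref A `kd_reference`.
#' @return Tibble with `codon` (number) and `residue` (1-letter).
#' @export
kd_translation <- function(ref) {
  tibble(
    codon = seq.int(ref$first_codon, ref$last_codon),
    residue = translate_kd(ref$kd_sequence)
  )
}

# Pick, for each catalogue codon, the wild-type codon that maximises the
# single-base reachability of that codon's catalogued mutant residues,
# weighting each mutation by the number of TKIs it affects so prominent
# resistance mutations (e.g. T315I) stay reachable (ties: lexicographically
# last codon). Deterministic, independent of the seed.
canonical_wt_codon <- function(wt, muts, weights = rep(1, length(muts))) {
  candidates <- sort(SENSE_CODONS[translate_codons(SENSE_CODONS) == wt])
  score <- vapply(candidates, function(cod) {
    sum(weights * vapply(muts, function(m) single_sub_exists(cod, m), logical(1)))
  }, numeric(1))
  best <- candidates[score == max(score)]
  best[length(best)]
}

single_sub_exists <- function(codon, residue) {
  nrow(single_subs_to(codon, residue)) > 0
}

# All single-base substitutions of `codon` translating to `residue`.
single_subs_to <- function(codon, residue) {
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (off in 1:3) {
    for (b in setdiff(bases, substr(codon, off, off))) {
      alt_codon <- codon
      substr(alt_codon, off, off) <- b
      if (GENETIC_CODE_1[[alt_codon]] == residue) {
        out[[length(out) + 1L]] <- tibble(
          offset = off, ref_base = substr(codon, off, off), alt_base = b
        )
      }
    }
  }
  if (length(out) == 0) {
    tibble(offset = integer(), ref_base = character(), alt_base = character())
  } else {
    bind_rows(out)
  }
}

#' Generate a seeded surrogate KD reference
#'
#' Builds a synthetic in-frame coding sequence for the KD window. Catalogue
#' codons receive a deterministic canonical codon: among all codons encoding
#' the catalogue's wild-type residue, the one from which the largest number of
#' that codon's catalogued mutant residues is reachable by a single-base
#' substitution (ties broken to the lexicographically last codon). All other
#' codons are drawn uniformly from the 61 sense codons under `seed`, so the
#' translation never contains a stop.
#'
#' @param catalogue A `kd_catalogue` (defaults to the packaged one).
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @param label Sequence label; the default marks the sequence as synthetic.
#' @return A `kd_reference`.
#' @examples
#' ref <- build_surrogate_reference(seed = 1)
#' kd_translation(ref)[kd_translation(ref)$codon == 315, ]
#' @export
build_surrogate_reference <- function(catalogue = hotspot_catalogue(), seed = 1,
                                      label = "NM_005157.6_surrogate_synthetic") {
  if (any(catalogue$codon < KD_FIRST_CODON | catalogue$codon > KD_LAST_CODON)) {
    abort_abl1kd("catalogue codon outside the KD window", "abl1kd_validation_error")
  }
  codons <- withr::with_seed(seed,
    sample(SENSE_CODONS, KD_N_CODONS, replace = TRUE)
  )
  by_codon <- catalogue |>
    mutate(n_tkis = lengths(strsplit(.data$tkis, ";", fixed = TRUE))) |>
    group_by(.data$codon, .data$wt) |>
    summarise(muts = list(.data$mut), weights = list(.data$n_tkis), .groups = "drop")
  for (i in seq_len(nrow(by_codon))) {
    idx <- by_codon$codon[i] - KD_FIRST_CODON + 1L
    codons[idx] <- canonical_wt_codon(by_codon$wt[i], by_codon$muts[[i]],
                                      by_codon$weights[[i]])
  }
  kd_reference(paste(codons, collapse = ""), label = label, catalogue = catalogue)
}

#' Map a codon number to its KD-local base range
#'
#' Coordinates are KD-local, 0-based, half-open: codon 160 occupies bases
#' `[0, 3)` of the default window.
#'
#' @param codon Integer codon number(s).
#' @param ref A `kd_reference`.
#' @return Tibble with `codon`, `start`, `end` (half-open).
#' @examples
#' ref <- build_surrogate_reference(seed = 1)
#' codon_to_base_range(315, ref)
#' @export
codon_to_base_range <- function(codon, ref) {
  codon <- as.integer(codon)
  if (any(codon < ref$first_codon | codon > ref$last_codon)) {
    abort_abl1kd(sprintf("codon out of range [%d, %d]", ref$first_codon, ref$last_codon),
                 "abl1kd_range_error")
  }
  start <- 3L * (codon - ref$first_codon)
  tibble(codon = codon, start = start, end = start + 3L)
}

#' Map a KD-local base position to its codon number
#'
#' @param pos 0-based KD-local position(s).
#' @param ref A `kd_reference`.
#' @return Integer codon number(s).
#' @export
base_to_codon <- function(pos, ref) {
  pos <- as.integer(pos)
  if (any(pos < 0L | pos >= nchar(ref$kd_sequence))) {
    abort_abl1kd("position outside the KD window", "abl1kd_range_error")
  }
  ref$first_codon + pos %/% 3L
}

#' Write / read a KD reference as FASTA
#'
#' @param ref A `kd_reference`.
#' @param path FASTA path.
#' @return `write_reference_fasta()` returns `path` invisibly;
#'   `read_reference_fasta()` returns a `kd_reference`.
#' @param first_codon,last_codon Codon window of the sequence in `path`.
#' @param catalogue Optional catalogue for wild-type validation.
#' @export
write_reference_fasta <- function(ref, path) {
  x <- Biostrings::DNAStringSet(ref$kd_sequence)
  names(x) <- ref$label
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path, first_codon = KD_FIRST_CODON,
                                 last_codon = KD_LAST_CODON, catalogue = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) != 1) {
    abort_abl1kd("reference FASTA must contain exactly one record", "abl1kd_parse_error")
  }
  kd_reference(as.character(x[[1]]), label = names(x)[1],
               first_codon = first_codon, last_codon = last_codon,
               catalogue = catalogue)
}
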