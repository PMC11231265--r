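# Hotspot catalogue: protein-change notation, per-TKI table ingestion, lookup.

KD_FIRST_CODON <- 160L
KD_LAST_CODON  <- 500L
KD_N_CODONS    <- KD_LAST_CODON - KD_FIRST_CODON + 1L
KD_LENGTH      <- 3L * KD_N_CODONS

#' The five TKIs tracked by the poor-sensitivity catalogue
#' @export
TKIS <- c("imatinib", "dasatinib", "nilotinib", "bosutinib", "ponatinib")

AA1 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")

#' Parse protein-change notation like "T315I"
#'
#' Published hotspot tables occasionally contain stray internal whitespace
#' (including Unicode thin spaces, e.g. "M244 V"); any whitespace is stripped
#' before parsing. The canonical rendering of a parsed change is
#' `paste0(wt, codon, mut)` with no spaces.
#'
#' @param text Character vector of protein-change strings
#'   (`<wt letter><codon><mut letter>`).
#' @return A tibble with columns `protein_change` (canonical string), `wt`,
#'   `codon` (integer) and `mut`.
#' @examples
#' parse_hotspot_notation(c("T315I", "M244 V"))
#' @export
parse_hotspot_notation <- function(text) {
  stopifnot(is.character(text))
  # strip any whitespace, including Unicode thin/no-break spaces seen in print
  clean <- gsub("[[:space:]\u00a0\u2009\u202f]+", "", text, perl = FALSE)
  ok <- grepl("^[A-Z][0-9]+[A-Z]$", clean)
  if (any(!ok)) {
    abort_abl1kd(
      paste0("malformed protein-change token(s): ",
             paste(sQuote(text[!ok]), collapse = ", ")),
      "abl1kd_parse_error"
    )
  }
  wt <- substr(clean, 1L, 1L)
  mut <- substr(clean, nchar(clean), nchar(clean))
  codon <- as.integer(substr(clean, 2L, nchar(clean) - 1L))
  bad_aa <- !(wt %in% AA1) | !(mut %in% AA1)
  if (any(bad_aa)) {
    abort_abl1kd(
      paste0("unknown amino-acid letter in: ",
             paste(sQuote(text[bad_aa]), collapse = ", ")),
      "abl1kd_parse_error"
    )
  }
  if (any(wt == mut)) {
    abort_abl1kd(
      paste0("wild-type residue equals mutant residue in: ",
             paste(sQuote(text[wt == mut]), collapse = ", ")),
      "abl1kd_validation_error"
    )
  }
  tibble(
    protein_change = paste0(wt, codon, mut),
    wt = wt, codon = codon, mut = mut
  )
}

#' Build the hotspot catalogue from per-TKI protein-change lists
#'
#' Takes one character vector of protein-change tokens per TKI (as printed in
#' resistance-mutation tables), parses every token, collapses duplicates, and
#' records for each unique change the set of TKIs to which it confers poor
#' sensitivity (the union over all lists naming it).
#'
#' @param tki_lists Named list; names must be a subset of [TKIS], each element
#'   a character vector of protein-change tokens (whitespace tolerated).
#' @return A `kd_catalogue`: a tibble with columns `protein_change`, `wt`,
#'   `codon`, `mut`, `tkis` (semicolon-joined), one logical column per TKI,
#'   plus attributes `n_tokens` (raw token count before deduplication) and
#'   `n_entries`.
#' @examples
#' load_hotspot_catalogue(list(imatinib = c("T315I"), ponatinib = c("T315M")))
#' @export
load_hotspot_catalogue <- function(tki_lists) {
  stopifnot(is.list(tki_lists))
  if (length(tki_lists) == 0 || all(lengths(tki_lists) == 0)) {
    cat <- tibble(
      protein_change = character(), wt = character(), codon = integer(),
      mut = character(), tkis = character()
    )
    for (t in TKIS) cat[[t]] <- logical()
    return(new_kd_catalogue(cat, n_tokens = 0L))
  }
  unknown <- setdiff(names(tki_lists), TKIS)
  if (length(unknown) > 0) {
    abort_abl1kd(paste0("unknown TKI name(s): ", paste(unknown, collapse = ", ")),
                 "abl1kd_validation_error")
  }
  per_tki <- purrr::imap(tki_lists, function(tokens, tki) {
    if (length(tokens) == 0) return(NULL)
    mutate(parse_hotspot_notation(tokens), tki = tki)
  })
  long <- bind_rows(per_tki)
  # conflicting wild-type residue at one codon means the table is corrupt
  conflicts <- long |>
    distinct(.data$codon, .data$wt) |>
    count(.data$codon) |>
    filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    abort_abl1kd(
      paste0("conflicting wild-type residues at codon(s): ",
             paste(conflicts$codon, collapse = ", ")),
      "abl1kd_validation_error"
    )
  }
  cat <- long |>
    distinct(.data$protein_change, .data$wt, .data$codon, .data$mut, .data$tki) |>
    group_by(.data$protein_change, .data$wt, .data$codon, .data$mut) |>
    summarise(
      tkis = paste(TKIS[TKIS %in% .data$tki], collapse = ";"),
      .groups = "drop"
    ) |>
    arrange(.data$codon, .data$mut)
  for (t in TKIS) {
    cat[[t]] <- vapply(
      strsplit(cat$tkis, ";", fixed = TRUE),
      function(s) t %in% s, logical(1)
    )
  }
  new_kd_catalogue(cat, n_tokens = sum(lengths(tki_lists)))
}

new_kd_catalogue <- function(tbl, n_tokens) {
  structure(tbl,
    class = c("kd_catalogue", class(tbl)),
    n_tokens = as.integer(n_tokens),
    n_entries = nrow(tbl)
  )
}

#' @export
print.kd_catalogue <- function(x, ...) {
  cat("KD hotspot catalogue: ", attr(x, "n_entries"), " unique entries (",
      attr(x, "n_tokens"), " raw tokens)\n", sep = "")
  NextMethod()
}

#' The packaged per-TKI hotspot table (raw tokens)
#'
#' Reads the packaged transcription of the assay's hotspot table: one row per
#' TKI with the comma-separated protein-change tokens exactly as printed
#' (including a duplicated V289I in the imatinib row and a stray internal
#' space in "M244 V").
#'
#' @param path Path to a raw table TSV (columns `tki`, `tokens`); defaults to
#'   the packaged copy.
#' @return Named list of character token vectors, one element per TKI.
#' @export
hotspot_raw_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "hotspot_table_raw.tsv", package = "abl1kd")
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  setNames(
    lapply(strsplit(tbl$tokens, ",", fixed = TRUE), trimws),
    tbl$tki
  )
}

#' The packaged hotspot/TKI poor-sensitivity catalogue
#'
#' Loads the deduplicated catalogue (93 unique protein changes over ABL1 KD
#' codons 160-500) either from the packaged TSV or from a user-supplied file
#' with the same columns.
#'
#' @param path Path to a catalogue TSV (columns `wt`, `codon`, `mut`, `tkis`
#'   with semicolon-separated TKI names); defaults to the packaged copy.
#' @return A `kd_catalogue` tibble; see [load_hotspot_catalogue()].
#' @examples
#' cat <- hotspot_catalogue()
#' dplyr::filter(cat, codon == 315)
#' @export
hotspot_catalogue <- function(path = NULL) {
  path <- path %||% system.file("extdata", "hotspot_catalogue.tsv", package = "abl1kd")
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    wt = readr::col_character(), codon = readr::col_integer(),
    mut = readr::col_character(), tkis = readr::col_character()
  ))
  lists <- lapply(TKIS, function(t) {
    rows <- grepl(t, tbl$tkis, fixed = TRUE)
    paste0(tbl$wt[rows], tbl$codon[rows], tbl$mut[rows])
  })
  out <- load_hotspot_catalogue(setNames(lists, TKIS))
  # token count of the flat TSV is not the printed-table token count
  attr(out, "n_tokens") <- NA_integer_
  out
}

#' Write a catalogue to its TSV interchange form
#'
#' @param catalogue A `kd_catalogue`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hotspot_catalogue <- function(catalogue, path) {
  readr::write_tsv(as_tibble(catalogue)[, c("wt", "codon", "mut", "tkis")], path)
  invisible(path)
}

# TKI set for one protein change; character(0) when absent from the catalogue.
catalogue_tkis <- function(catalogue, protein_change) {
  i <- match(protein_change, catalogue$protein_change)
  lapply(i, function(j) {
    if (is.na(j)) character(0)
    else strsplit(catalogue$tkis[j], ";", fixed = TRUE)[[1]]
  })
}
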