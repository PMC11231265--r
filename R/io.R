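# VCF and flat-table interchange for variant calls and QC reports.

#' Write calls as VCF v4.2
#'
#' CHROM is the reference label, POS is 1-based (KD-local coordinates are
#' 0-based internally), and per-record INFO carries DP (depth), AO (alternate
#' observations), VAF (percent), CODON, PCHG (protein change) and HOTSPOT
#' (catalogue membership flag).
#'
#' @param calls A `kd_calls` tibble.
#' @param ref The `kd_reference` the calls were made against.
#' @param path Output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, ref, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=abl1kd",
    sprintf("##contig=<ID=%s,length=%d>", ref$label, nchar(ref$kd_sequence)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=AO,Number=1,Type=Integer,Description=\"Alternate allele observations\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency, percent\">",
    "##INFO=<ID=CODON,Number=1,Type=Integer,Description=\"ABL1 codon number\">",
    "##INFO=<ID=PCHG,Number=1,Type=String,Description=\"Protein change\">",
    "##INFO=<ID=HOTSPOT,Number=0,Type=Flag,Description=\"Present in the TKI poor-sensitivity catalogue\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  records <- if (nrow(calls) == 0) character(0) else {
    info <- sprintf("DP=%d;AO=%d;VAF=%.6g;CODON=%d;PCHG=%s",
                    as.integer(calls$depth), as.integer(calls$alt_count),
                    calls$vaf, calls$codon, calls$protein_change)
    info <- ifelse(calls$in_catalogue, paste0(info, ";HOTSPOT"), info)
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
            ref$label, calls$kd_pos + 1L, calls$ref_base, calls$alt_base, info)
  }
  readr::write_lines(c(header, records), path)
  invisible(path)
}

#' Read an abl1kd VCF back into a calls tibble
#'
#' Parsing goes through `VariantAnnotation::readVcf()`, so reading also
#' validates VCF syntax.
#'
#' @param path Path to a `.vcf` written by [write_vcf()].
#' @return A `kd_calls`-shaped tibble (without the `synonymous`/`multi_hit`
#'   bookkeeping columns, which are not serialized).
#' @export
read_vcf_calls <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  n <- nrow(vcf)
  if (n == 0) {
    return(new_kd_calls(empty_calls()[, setdiff(names(empty_calls()),
                                                c("synonymous", "multi_hit"))]))
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  alt <- as.character(unlist(rr$ALT))
  out <- tibble(
    kd_pos = GenomicRanges::start(rr) - 1L,
    ref_base = as.character(rr$REF),
    alt_base = alt,
    codon = as.integer(info$CODON),
    protein_change = as.character(info$PCHG),
    vaf = as.numeric(info$VAF),
    depth = as.numeric(info$DP),
    alt_count = as.integer(info$AO),
    passes_lod = TRUE,
    in_catalogue = as.logical(info$HOTSPOT)
  )
  new_kd_calls(out)
}

#' Write / read the flat TSV mirror of a call table
#'
#' @param calls A `kd_calls` tibble.
#' @param path TSV path.
#' @return `write_calls_tsv()` returns `path` invisibly; `read_calls_tsv()`
#'   returns a `kd_calls` tibble.
#' @export
write_calls_tsv <- function(calls, path) {
  readr::write_tsv(as_tibble(calls), path)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path) {
  new_kd_calls(readr::read_tsv(path, col_types = readr::cols(
    kd_pos = readr::col_integer(), ref_base = readr::col_character(),
    alt_base = readr::col_character(), codon = readr::col_integer(),
    protein_change = readr::col_character(), synonymous = readr::col_logical(),
    vaf = readr::col_double(), depth = readr::col_double(),
    alt_count = readr::col_integer(), passes_lod = readr::col_logical(),
    in_catalogue = readr::col_logical(), multi_hit = readr::col_logical(),
    .default = readr::col_guess()
  )))
}

#' Write a QC report as TSV and JSON
#'
#' @param qc A `kd_qc` tibble (one or more rows).
#' @param path Base path; `<path>.tsv` and `<path>.json` are written.
#' @return Written paths, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  readr::write_tsv(as_tibble(qc), tsv)
  jsonlite::write_json(as_tibble(qc), json, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(c(tsv = tsv, json = json))
}
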